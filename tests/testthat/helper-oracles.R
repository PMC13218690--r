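# Independent oracles and small fixture builders shared across tests.
# Each oracle is a deliberately naive, direct computation kept separate
# from the package's implementation path.

# Path graph A - B - C with a transition matrix.
path_network <- function() {
  build_transition_matrix(gene_network(data.frame(
    from = c("A", "B"), to = c("B", "C"), weight = c(800, 800))))
}

# Closed-form RWR steady state: p = r * (I - (1 - r) W)^{-1} p0.
rwr_direct <- function(p0, W, r) {
  n <- nrow(W)
  as.numeric(r * solve(diag(n) - (1 - r) * W, p0))
}

# Position-by-position ssGSEA running sum, written independently of the
# package's vectorized path.
ssgsea_oracle <- function(profile_row, geneset, alpha = 0.25) {
  genes <- names(profile_row)
  n <- length(genes)
  ord <- order(-profile_row, genes)
  sorted <- genes[ord]
  in_set <- sorted %in% intersect(geneset, genes)
  denom_hit <- 0
  for (pos in seq_len(n)) {
    if (in_set[pos]) denom_hit <- denom_hit + (n - pos + 1)^alpha
  }
  running <- 0
  es <- 0
  n_miss <- n - sum(in_set)
  for (pos in seq_len(n)) {
    if (in_set[pos]) {
      running <- running + (n - pos + 1)^alpha / denom_hit
    } else {
      running <- running - 1 / n_miss
    }
    es <- es + running
  }
  es
}

# Brute-force mean silhouette from explicit pairwise distances.
silhouette_oracle <- function(points, labels) {
  points <- as.matrix(points)
  d <- as.matrix(stats::dist(points))
  n <- nrow(points)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(unique(labels[!own]), function(cl) {
      mean(d[i, labels == cl])
    }, 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Exhaustive two-sided rank-sum p-value by enumerating all label
# assignments of the pooled sample.
wilcoxon_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  stats <- apply(combos, 2L, function(idx) sum(r[idx]))
  center <- n1 * (length(pooled) + 1) / 2
  mean(abs(stats - center) >= abs(obs - center) - 1e-9)
}

# Breslow partial log-likelihood for a single covariate, direct sum.
cox_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Per-group exponential MLE hazard: events / total time at risk.
exp_mle_hazard <- function(time, event) sum(event) / sum(time)

# Two well-separated Gaussian blobs posing as an NES matrix.
planted_nes <- function(n = 120, p = 10, sep = 2, seed = 1) {
  set.seed(seed)
  labels <- rep(1:2, length.out = n)
  x <- matrix(rnorm(n * p), n, p) + sep * (labels - 1)
  dimnames(x) <- list(sprintf("S%03d", seq_len(n)),
                      sprintf("SET%02d", seq_len(p)))
  list(nes = x, labels = labels)
}

# Exponential survival table for given hazards.
sim_survival <- function(hazard, censor_rate = 1e-6, seed = 1,
                         ids = sprintf("S%03d", seq_along(hazard))) {
  set.seed(seed)
  death <- rexp(length(hazard), hazard)
  cens <- rexp(length(hazard), censor_rate)
  data.frame(sample_id = ids, time = pmin(death, cens),
             event = as.integer(death <= cens), stringsAsFactors = FALSE)
}
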