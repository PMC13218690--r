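#' Build the restart distribution for one sample
#'
#' The seed p0 puts uniform mass 1/m on the m mutated genes of the sample
#' that are present in the network; mutated genes outside the network are
#' ignored. A sample whose mutated genes all fall outside the network has no
#' valid seed and is reported by [propagate_cohort()] rather than silently
#' dropped.
#'
#' @param mutated_genes Character vector of mutated gene symbols.
#' @param network A `gene_network` with a transition matrix.
#' @return Named numeric vector over network nodes summing to 1, with
#'   attribute `n_seed` = m, or `NULL` when no mutated gene is in the
#'   network.
#' @export
make_seed <- function(mutated_genes, network) {
  stopifnot(inherits(network, "gene_network"))
  nodes <- network$nodes
  hit <- intersect(unique(mutated_genes), nodes)
  if (length(hit) == 0L) {
    return(NULL)
  }
  p0 <- stats::setNames(numeric(length(nodes)), nodes)
  p0[hit] <- 1 / length(hit)
  attr(p0, "n_seed") <- length(hit)
  p0
}

#' Random walk with restart to steady state
#'
#' Iterates the propagation update
#' \deqn{p_{t+1} = (1 - r) W p_t + r p_0}
#' from p = p0 until the L1 residual ||p_{t+1} - p_t||_1 drops below `tol`.
#' W is the column-stochastic transition matrix of the interaction network
#' and r is the restart probability (0.75 here), the weight of returning to
#' the mutated-gene seed at each step. Because (1-r)W has spectral radius
#' at most 1-r, convergence is geometric and probability mass is conserved
#' at every step.
#'
#' @param seed Seed vector from [make_seed()].
#' @param network A `gene_network` with a transition matrix (see
#'   [build_transition_matrix()]).
#' @param r Restart probability in (0, 1]. Default 0.75.
#' @param tol L1 convergence tolerance. Default 1e-6.
#' @param max_iter Iteration cap; exceeding it is an error (the spectral
#'   bound makes this unreachable unless W is mis-built).
#' @return Steady-state probability vector over nodes (sums to 1 within
#'   1e-9) with attributes `iterations` and `residual`.
#' @export
rwr <- function(seed, network, r = 0.75, tol = 1e-6, max_iter = 10000L) {
  stopifnot(inherits(network, "gene_network"))
  if (is.null(network$transition)) {
    stop("network has no transition matrix; call build_transition_matrix()",
         call. = FALSE)
  }
  if (!(r > 0 && r <= 1)) {
    stop("restart probability r must be in (0, 1]", call. = FALSE)
  }
  W <- network$transition
  p0 <- as.numeric(seed)
  p <- p0
  for (it in seq_len(max_iter)) {
    p_new <- (1 - r) * as.numeric(W %*% p) + r * p0
    res <- sum(abs(p_new - p))
    p <- p_new
    if (res < tol) {
      names(p) <- network$nodes
      attr(p, "iterations") <- it
      attr(p, "residual") <- res
      return(p)
    }
  }
  stop("RWR did not converge within ", max_iter,
       " iterations (last L1 residual ", format(res), ")", call. = FALSE)
}

#' Propagate a mutation cohort over the network
#'
#' Applies the random walk with restart to every sample of a (binarized)
#' mutation matrix in one batched iteration: the seed matrix P0 holds one
#' restart distribution per column, and the update
#' P <- (1-r) W P + r P0 runs until every column's L1 residual is below
#' `tol`. Per-sample convergence iteration and final residual are recorded.
#' Samples with an empty seed (no mutated gene in the network) are excluded
#' and listed in the result, never silently dropped.
#'
#' @param mutations Mutation matrix, samples as rows (counts or 0/1; it is
#'   binarized internally).
#' @param network A `gene_network` with a transition matrix.
#' @param r,tol,max_iter As in [rwr()].
#' @return An object of class `propagated_profile`: list with `values`
#'   (samples x nodes steady-state matrix, rows sum to 1 within 1e-9),
#'   `diagnostics` (per-sample seed size, iterations, residual) and
#'   `excluded` (sample IDs with empty seeds).
#' @export
propagate_cohort <- function(mutations, network, r = 0.75, tol = 1e-6,
                             max_iter = 10000L) {
  stopifnot(is.matrix(mutations), inherits(network, "gene_network"))
  if (is.null(network$transition)) {
    stop("network has no transition matrix; call build_transition_matrix()",
         call. = FALSE)
  }
  bin <- binarize_mutations(mutations)
  nodes <- network$nodes
  samples <- rownames(bin)
  common <- intersect(colnames(bin), nodes)
  seed_size <- if (length(common))
    rowSums(bin[, common, drop = FALSE]) else rep(0L, nrow(bin))
  excluded <- samples[seed_size == 0L]
  kept <- samples[seed_size > 0L]
  if (length(kept) == 0L) {
    stop("all samples excluded: no mutated genes overlap the network",
         call. = FALSE)
  }
  P0 <- matrix(0, nrow = length(nodes), ncol = length(kept),
               dimnames = list(nodes, kept))
  P0[common, ] <- t(bin[kept, common, drop = FALSE])
  P0 <- sweep(P0, 2L, colSums(P0), "/")

  W <- network$transition
  P <- P0
  n_iter <- rep(NA_integer_, length(kept))
  final_res <- rep(NA_real_, length(kept))
  active <- rep(TRUE, length(kept))
  for (it in seq_len(max_iter)) {
    P_new <- (1 - r) * (W %*% P) + r * P0
    res <- colSums(abs(P_new - P))
    P <- P_new
    done <- active & res < tol
    n_iter[done] <- it
    final_res[done] <- res[done]
    active[done] <- FALSE
    if (!any(active)) break
  }
  if (any(active)) {
    stop("RWR did not converge within ", max_iter, " iterations for ",
         sum(active), " sample(s); worst L1 residual ",
         format(max(res[active])), call. = FALSE)
  }
  values <- t(P)
  structure(list(
    values = values,
    diagnostics = data.frame(sample = kept,
                             seed_size = as.integer(seed_size[kept]),
                             iterations = n_iter,
                             residual = final_res,
                             stringsAsFactors = FALSE),
    excluded = excluded,
    params = list(r = r, tol = tol)
  ), class = "propagated_profile")
}

#' @export
print.propagated_profile <- function(x, ...) {
  cat("propagated_profile:", nrow(x$values), "samples x", ncol(x$values),
      "genes; r =", x$params$r, "\n")
  if (length(x$excluded)) {
    cat("  excluded (empty seed):", length(x$excluded), "sample(s)\n")
  }
  invisible(x)
}
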