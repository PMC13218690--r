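#' Configuration for a synthetic tumor-ecosystem cohort
#'
#' The generator emulates the statistical structure the subtyping pipeline
#' assumes: a sparse binary mutation matrix over a scale-free interaction
#' network, ecosystem gene sets overlapping planted subtype driver modules,
#' and exponential overall survival with a multiplicative subtype hazard and
#' independent exponential censoring. Defaults are the strong-planted-signal
#' study conditions used throughout the test suite: 300 samples x 300 genes,
#' driver mutation probability 0.8 vs background 0.02, hazard ratio 3.
#'
#' @param n_genes Number of genes (network nodes).
#' @param n_samples Number of patients.
#' @param n_subtypes Number of planted subtypes (>= 1).
#' @param attachment_edges Edges added per node during preferential
#'   attachment growth.
#' @param n_genesets Number of ecosystem gene sets.
#' @param geneset_size_range Integer (min, max) gene-set sizes.
#' @param n_drivers_per_subtype Driver genes per subtype module.
#' @param background_mutation_rate Per-gene, per-sample mutation
#'   probability for non-driver genes.
#' @param driver_mutation_rate Mutation probability of a driver gene in
#'   samples of its own subtype; must exceed the background rate.
#' @param baseline_hazard Exponential death hazard of subtype 1 (per month).
#' @param subtype_hazard_ratio Multiplicative hazard of subtype 2 relative
#'   to subtype 1.
#' @param censoring_rate Independent exponential censoring hazard.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 300, n_samples = 300, n_subtypes = 2,
                             attachment_edges = 3, n_genesets = 20,
                             geneset_size_range = c(10, 25),
                             n_drivers_per_subtype = 10,
                             background_mutation_rate = 0.02,
                             driver_mutation_rate = 0.8,
                             baseline_hazard = 0.02,
                             subtype_hazard_ratio = 3,
                             censoring_rate = 0.01,
                             seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples = as.integer(n_samples),
              n_subtypes = as.integer(n_subtypes),
              attachment_edges = as.integer(attachment_edges),
              n_genesets = as.integer(n_genesets),
              geneset_size_range = as.integer(geneset_size_range),
              n_drivers_per_subtype = as.integer(n_drivers_per_subtype),
              background_mutation_rate = background_mutation_rate,
              driver_mutation_rate = driver_mutation_rate,
              baseline_hazard = baseline_hazard,
              subtype_hazard_ratio = subtype_hazard_ratio,
              censoring_rate = censoring_rate,
              seed = as.integer(seed))
  with(cfg, {
    if (n_genes < 2 || n_samples < 1 || n_subtypes < 1)
      stop("invalid cohort sizes", call. = FALSE)
    if (n_genes < attachment_edges + 1)
      stop("n_genes must exceed attachment_edges", call. = FALSE)
    if (length(geneset_size_range) != 2 ||
        geneset_size_range[1] > geneset_size_range[2] ||
        geneset_size_range[2] > n_genes)
      stop("invalid geneset_size_range", call. = FALSE)
    if (!(background_mutation_rate > 0 && background_mutation_rate < 1) ||
        !(driver_mutation_rate > 0 && driver_mutation_rate <= 1))
      stop("mutation rates must be probabilities in (0, 1)", call. = FALSE)
    if (driver_mutation_rate <= background_mutation_rate)
      stop("driver_mutation_rate must exceed background_mutation_rate",
           call. = FALSE)
    if (baseline_hazard <= 0 || subtype_hazard_ratio <= 0 ||
        censoring_rate <= 0)
      stop("hazards and censoring rate must be positive", call. = FALSE)
    if (n_subtypes * n_drivers_per_subtype > n_genes)
      stop("too many driver genes for n_genes", call. = FALSE)
  })
  structure(cfg, class = "synthetic_config")
}

#' Generate a scale-free interaction network
#'
#' Preferential attachment: a complete seed clique on `attachment_edges + 1`
#' nodes, then each new node attaches to `attachment_edges` distinct
#' existing nodes sampled with probability proportional to current degree.
#' The graph is connected by construction and its degree distribution is
#' heavy-tailed, which matters because random-walk propagation behavior is
#' dominated by hubs. Edge weights (combined scores) are drawn uniformly
#' from [700, 1000], i.e. already above the high-confidence threshold.
#'
#' Total edge count is deterministic:
#' `choose(m + 1, 2) + m * (n_genes - m - 1)` with m = `attachment_edges`.
#'
#' @param n_genes Number of nodes (>= attachment_edges + 1).
#' @param attachment_edges Edges per new node (m).
#' @param seed Integer seed.
#' @return A `gene_network` (edges only).
#' @export
generate_network <- function(n_genes, attachment_edges = 3, seed = 1) {
  n <- as.integer(n_genes)
  m <- as.integer(attachment_edges)
  if (n < m + 1L) {
    stop("n_genes must be at least attachment_edges + 1", call. = FALSE)
  }
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n))
  deg <- integer(n)
  seed_nodes <- seq_len(m + 1L)
  ledger_from <- integer(0)
  ledger_to <- integer(0)
  for (i in seed_nodes) for (j in seq_len(i - 1L)) {
    ledger_from <- c(ledger_from, j); ledger_to <- c(ledger_to, i)
  }
  deg[seed_nodes] <- m
  if (n > m + 1L) {
    for (v in (m + 2L):n) {
      existing <- seq_len(v - 1L)
      targets <- sample(existing, m, prob = deg[existing])
      ledger_from <- c(ledger_from, targets)
      ledger_to <- c(ledger_to, rep(v, m))
      deg[targets] <- deg[targets] + 1L
      deg[v] <- m
    }
  }
  weights <- stats::runif(length(ledger_from), 700, 1000)
  gene_network(data.frame(from = genes[ledger_from],
                          to = genes[ledger_to],
                          weight = weights,
                          stringsAsFactors = FALSE))
}

#' Generate a full synthetic cohort
#'
#' Each sample's subtype is drawn uniformly; driver genes of the sample's
#' subtype mutate with `driver_mutation_rate` and every gene with
#' `background_mutation_rate`. Each subtype's driver module is planted
#' inside a distinct subset of gene sets (padded with random genes); the
#' remaining sets are random draws, so the prognostic filter and the
#' clustering signal are controllable. Death times are exponential with
#' hazard `baseline_hazard * subtype_hazard_ratio^[subtype == 2]` and are
#' independently censored at rate `censoring_rate`. Samples with zero
#' mutated genes are resampled (up to 100 retries) so the cohort size is
#' exactly `n_samples`.
#'
#' @param config A [synthetic_config()].
#' @return Object of class `synthetic_cohort`: list with `mutations`
#'   (samples x genes integer matrix), `network` (`gene_network`),
#'   `genesets` (named list), `drivers` (list of driver genes per subtype),
#'   `survival` (sample_id/time/event data frame), `true_labels` (named
#'   integer) and the `config`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  network <- generate_network(cfg$n_genes, cfg$attachment_edges, cfg$seed)
  genes <- network$nodes
  set.seed(cfg$seed + 1L)

  drivers <- split(sample(genes, cfg$n_subtypes * cfg$n_drivers_per_subtype),
                   rep(seq_len(cfg$n_subtypes),
                       each = cfg$n_drivers_per_subtype))
  names(drivers) <- paste0("subtype_", seq_len(cfg$n_subtypes))

  # plant each driver module in a distinct block of gene sets
  n_planted_per <- max(1L, cfg$n_genesets %/% (2L * cfg$n_subtypes))
  sizes <- sample(seq(cfg$geneset_size_range[1], cfg$geneset_size_range[2]),
                  cfg$n_genesets, replace = TRUE)
  genesets <- vector("list", cfg$n_genesets)
  set_names <- character(cfg$n_genesets)
  k <- 0L
  for (s in seq_len(cfg$n_subtypes)) {
    for (r in seq_len(n_planted_per)) {
      k <- k + 1L
      core <- drivers[[s]]
      size <- max(sizes[k], length(core))
      pad <- sample(setdiff(genes, core), size - length(core))
      genesets[[k]] <- sample(c(core, pad))
      set_names[k] <- sprintf("ECO_DRIVER_S%d_%02d", s, r)
    }
  }
  while (k < cfg$n_genesets) {
    k <- k + 1L
    genesets[[k]] <- sample(genes, sizes[k])
    set_names[k] <- sprintf("ECO_RANDOM_%02d", k)
  }
  names(genesets) <- set_names

  labels <- sample.int(cfg$n_subtypes, cfg$n_samples, replace = TRUE)
  if (length(unique(labels)) < cfg$n_subtypes) {
    # tiny cohorts: guarantee every subtype is represented
    labels[seq_len(cfg$n_subtypes)] <- seq_len(cfg$n_subtypes)
  }
  samples <- sprintf("S%04d", seq_len(cfg$n_samples))
  names(labels) <- samples

  driver_idx <- lapply(drivers, function(d) match(d, genes))
  mutations <- matrix(0L, cfg$n_samples, cfg$n_genes,
                      dimnames = list(samples, genes))
  draw_row <- function(subtype) {
    row <- stats::rbinom(cfg$n_genes, 1L, cfg$background_mutation_rate)
    di <- driver_idx[[subtype]]
    row[di] <- pmax(row[di],
                    stats::rbinom(length(di), 1L, cfg$driver_mutation_rate))
    row
  }
  for (i in seq_len(cfg$n_samples)) {
    row <- draw_row(labels[i])
    tries <- 0L
    while (sum(row) == 0L) {
      tries <- tries + 1L
      if (tries > 100L) {
        stop("failed to generate a mutated sample after 100 retries; ",
             "background_mutation_rate is too low", call. = FALSE)
      }
      row <- draw_row(labels[i])
    }
    mutations[i, ] <- row
  }

  hazard <- cfg$baseline_hazard *
    ifelse(labels == 2L, cfg$subtype_hazard_ratio, 1)
  death <- stats::rexp(cfg$n_samples, rate = hazard)
  censor <- stats::rexp(cfg$n_samples, rate = cfg$censoring_rate)
  survival <- data.frame(sample_id = samples,
                         time = pmin(death, censor),
                         event = as.integer(death <= censor),
                         stringsAsFactors = FALSE)

  structure(list(mutations = mutations, network = network,
                 genesets = genesets, drivers = drivers,
                 survival = survival, true_labels = labels,
                 config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$mutations), "samples x",
      ncol(x$mutations), "genes;", length(x$genesets), "gene sets;",
      x$config$n_subtypes, "subtypes\n")
  invisible(x)
}

#' Write a synthetic cohort to standard text formats
#'
#' Mutation matrix as TSV (samples as rows), the network as a STRING-style
#' three-column links file, the gene sets as GMT, and survival plus true
#' labels as TSVs.
#'
#' @param cohort A `synthetic_cohort`.
#' @param outdir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, outdir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    mutations = file.path(outdir, "mutations.tsv"),
    network = file.path(outdir, "network_links.tsv"),
    genesets = file.path(outdir, "genesets.gmt"),
    survival = file.path(outdir, "survival.tsv"),
    labels = file.path(outdir, "true_labels.tsv")
  )
  utils::write.table(cbind(sample_id = rownames(cohort$mutations),
                           as.data.frame(cohort$mutations)),
                     paths["mutations"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ed <- cohort$network$edges
  utils::write.table(data.frame(protein1 = ed$from, protein2 = ed$to,
                                combined_score = ed$weight),
                     paths["network"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gmt(cohort$genesets, paths["genesets"])
  utils::write.table(cohort$survival, paths["survival"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = names(cohort$true_labels),
                                subtype = unname(cohort$true_labels)),
                     paths["labels"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
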