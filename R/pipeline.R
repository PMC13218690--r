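#' Split a cohort into training and testing partitions
#'
#' Training size is `floor(n * train_fraction)` after a fixed-seed shuffle;
#' the partitions are disjoint and exhaustive. With the conventional 7:3
#' split, a cohort of 2,526 samples yields 1,768 training and 758 testing
#' samples.
#'
#' @param ids Character vector of sample IDs.
#' @param train_fraction Fraction assigned to training. Default 0.7.
#' @param seed Integer seed for the shuffle.
#' @return List with `train` and `test` ID vectors.
#' @export
split_cohort <- function(ids, train_fraction = 0.7, seed = 1) {
  stopifnot(length(ids) >= 2, !anyDuplicated(ids),
            train_fraction > 0, train_fraction < 1)
  n_train <- floor(length(ids) * train_fraction)
  set.seed(seed)
  shuffled <- sample(ids)
  list(train = shuffled[seq_len(n_train)],
       test = shuffled[-seq_len(n_train)])
}

#' Run the full tumor-ecosystem-subtyping pipeline
#'
#' Orchestrates the four-step workflow: (1) binarize the somatic mutation
#' profile, (2) smooth it by random-walk-with-restart propagation over the
#' interaction network, (3) score the propagated profiles against the
#' ecosystem gene sets by ssGSEA and normalize to NES, then (4) filter sets
#' by univariate Cox association with survival, cluster patients by
#' silhouette-selected K-means, orient labels by prognosis, and
#' characterize the subtypes. With `train_fraction` set, the cohort is
#' split first, the Cox filter and classifier are fit on the training
#' partition only, and the trained classifier predicts the test partition.
#'
#' Inputs may be in-memory objects or file paths (mutation matrix TSV,
#' STRING-style links file, GMT, survival TSV). All paths are validated
#' before any computation starts.
#'
#' @param mutations Mutation count matrix (samples x genes) or TSV path.
#' @param network A `gene_network` or STRING links file path.
#' @param genesets Named list of gene sets or GMT path.
#' @param surv Survival data frame (`sample_id`, `time`, `event`) or TSV
#'   path.
#' @param restart,tol Propagation parameters (see [rwr()]).
#' @param alpha ssGSEA exponent (see [ssgsea_es()]).
#' @param score_threshold STRING combined-score cutoff when `network` is a
#'   path.
#' @param p_threshold Prognostic-filter p-value cutoff.
#' @param k_range,n_init K-means settings (see [fit_subtypes()]).
#' @param train_fraction Optional train/test fraction; enables the
#'   classifier stage.
#' @param seed Integer seed for clustering, splitting and training.
#' @param outdir Optional directory; when given, labels, NES, comparisons,
#'   diagnostics and a JSON run manifest are written there.
#' @return List with `nes`, `filter`, `subtypes`, `comparisons`,
#'   `differential`, `logrank`, `propagation`, and (when `train_fraction`
#'   is set) `split`, `classifier`, `test_predictions`, `test_subtypes`;
#'   plus the run `manifest`.
#' @export
run_tes_pipeline <- function(mutations, network, genesets, surv,
                             restart = 0.75, tol = 1e-6, alpha = 0.25,
                             score_threshold = 700, p_threshold = 0.05,
                             k_range = 2:10, n_init = 25,
                             train_fraction = NULL, seed = 1,
                             outdir = NULL) {
  # validate all file inputs before any computation
  for (arg in list(mutations, network, genesets, surv)) {
    if (is.character(arg) && length(arg) == 1L && !file.exists(arg)) {
      stop("input file not found: ", arg, call. = FALSE)
    }
  }
  if (is.character(mutations)) mutations <- read_mutation_matrix(mutations)
  if (is.character(network)) {
    network <- read_string_links(network, score_threshold)
  }
  if (is.null(network$transition)) {
    network <- build_transition_matrix(network)
  }
  if (is.character(genesets)) genesets <- read_gmt(genesets)
  if (is.character(surv)) {
    surv <- utils::read.delim(surv, stringsAsFactors = FALSE)
    surv$sample_id <- as.character(surv$sample_id)
  }
  validate_survival(surv)

  prop <- propagate_cohort(mutations, network, r = restart, tol = tol)
  nes <- normalize_nes(ssgsea_matrix(prop, genesets, alpha = alpha))

  ids <- rownames(nes)
  split <- NULL
  train_ids <- ids
  if (!is.null(train_fraction)) {
    split <- split_cohort(ids, train_fraction, seed)
    train_ids <- split$train
  }
  surv_of <- function(s) surv[match(s, surv$sample_id), , drop = FALSE]

  filt <- filter_prognostic_genesets(nes[train_ids, , drop = FALSE],
                                     surv_of(train_ids), p_threshold)
  train_nes <- nes[train_ids, filt$kept, drop = FALSE]
  subtypes <- fit_subtypes(train_nes, k_range = k_range, n_init = n_init,
                           seed = seed, surv = surv_of(train_ids))
  labels <- subtypes$labels

  lr <- logrank_test(surv_of(train_ids), labels)
  # the Wilcoxon characterization contrasts exactly two subtypes; with
  # k > 2 it is skipped (the log-rank test above still covers all groups)
  comparisons <- NULL
  differential <- NULL
  if (subtypes$selected_k == 2L) {
    comparisons <- compare_features_by_group(nes[train_ids, , drop = FALSE],
                                             labels)
    differential <- differential_genes(
      prop$values[train_ids, , drop = FALSE], labels)
  }

  result <- list(nes = nes, propagation = prop, filter = filt,
                 subtypes = subtypes, logrank = lr,
                 comparisons = comparisons, differential = differential,
                 split = split)

  if (!is.null(train_fraction) && subtypes$selected_k == 2L) {
    clf <- train_cv(train_nes, labels,
                    tes_classifier_spec(random_state = seed))
    test_nes <- nes[split$test, filt$kept, drop = FALSE]
    result$classifier <- clf
    result$test_predictions <- predict(clf, test_nes)
    result$test_subtypes <- fit_subtypes(test_nes, k_range = k_range,
                                         n_init = n_init, seed = seed,
                                         surv = surv_of(split$test))
  }

  result$manifest <- list(
    seed = seed,
    params = list(restart = restart, tol = tol, alpha = alpha,
                  p_threshold = p_threshold,
                  k_range = range(k_range), n_init = n_init,
                  train_fraction = train_fraction),
    n_samples = nrow(nes), n_genesets = ncol(nes),
    n_network_genes = length(network$nodes),
    excluded_samples = prop$excluded,
    kept_genesets = filt$kept,
    selected_k = subtypes$selected_k
  )

  if (!is.null(outdir)) {
    write_pipeline_outputs(result, outdir)
  }
  result
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(data.frame(sample_id = names(result$subtypes$labels),
                tes_label = unname(result$subtypes$labels)), "labels.tsv")
  wt(cbind(sample_id = rownames(result$nes), as.data.frame(result$nes)),
     "nes.tsv")
  wt(data.frame(k = as.integer(names(result$subtypes$silhouette_by_k)),
                mean_silhouette = unname(result$subtypes$silhouette_by_k)),
     "silhouette_trace.tsv")
  wt(result$filter$results, "cox_filter.tsv")
  if (!is.null(result$comparisons)) wt(result$comparisons,
                                       "nes_comparisons.tsv")
  if (!is.null(result$differential)) wt(result$differential,
                                        "differential_genes.tsv")
  wt(result$propagation$diagnostics, "propagation_diagnostics.tsv")
  jsonlite::write_json(result$manifest,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
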