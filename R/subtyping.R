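#' Filter gene sets by univariate prognostic association
#'
#' Scores every NES column with a univariate Cox model against overall
#' survival and keeps the sets with Wald p below the threshold, reporting
#' the risk/protective direction of each. The filter is meant to be computed
#' on the training partition and then frozen for test data.
#'
#' @param nes Samples x gene-sets NES matrix.
#' @param surv Survival table with `sample_id`, `time`, `event`; must cover
#'   every NES sample.
#' @param p_threshold Wald p-value cutoff. Default 0.05.
#' @return List with `kept` (character vector of set names) and `results`
#'   (per-set Cox table: beta, hazard_ratio, p_value, direction, kept flag).
#' @export
filter_prognostic_genesets <- function(nes, surv, p_threshold = 0.05) {
  stopifnot(is.matrix(nes), !is.null(rownames(nes)), !is.null(colnames(nes)))
  validate_survival(surv)
  missing <- setdiff(rownames(nes), surv$sample_id)
  if (length(missing)) {
    stop("NES samples missing from survival table: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  sv <- surv[match(rownames(nes), surv$sample_id), , drop = FALSE]
  results <- do.call(rbind, lapply(colnames(nes), function(gs) {
    cox_univariate(sv, nes[, gs], name = gs)
  }))
  results$kept <- results$p_value < p_threshold
  kept <- results$covariate[results$kept]
  if (length(kept) == 0L) {
    stop("no gene set passes the prognostic filter at p < ", p_threshold,
         "; consider a more permissive threshold", call. = FALSE)
  }
  list(kept = kept, results = results)
}

#' Mean silhouette width of a clustering
#'
#' Standard silhouette s(i) = (b - a) / max(a, b) under Euclidean distance,
#' where a is the mean within-cluster distance of point i and b the mean
#' distance to the nearest other cluster; singleton clusters contribute 0.
#'
#' @param points Numeric matrix (samples x features).
#' @param labels Cluster label per row; at least two distinct clusters.
#' @return Mean silhouette width over all points, in [-1, 1].
#' @export
mean_silhouette <- function(points, labels) {
  points <- as.matrix(points)
  stopifnot(nrow(points) == length(labels))
  cl <- as.integer(factor(labels))
  if (length(unique(cl)) < 2L) {
    stop("silhouette is undefined for a single cluster", call. = FALSE)
  }
  sil <- cluster::silhouette(cl, stats::dist(points))
  mean(sil[, "sil_width"])
}

#' Cluster samples into tumor ecosystem subtypes
#'
#' K-means (Euclidean, `n_init` random restarts per k) over a range of k,
#' selecting the k with the highest mean silhouette width. NES columns are
#' z-scored first by default so that sets with larger score ranges do not
#' dominate the distance. When a survival table is supplied, labels are
#' oriented so that TES 1 is the better-prognosis cluster
#' (see [orient_labels()]).
#'
#' @param nes Samples x gene-sets NES matrix, typically restricted to the
#'   prognostic sets from [filter_prognostic_genesets()].
#' @param k_range Candidate numbers of clusters. Default 2:10.
#' @param n_init Number of random K-means restarts per k. Default 25.
#' @param seed Integer seed; recorded in the result.
#' @param standardize Z-score the columns before clustering? Default `TRUE`.
#' @param surv Optional survival table for label orientation.
#' @return Object of class `subtype_result`: list with `labels` (named
#'   integer per sample, 1..k), `selected_k`, `silhouette_by_k`, `features`,
#'   `orientation` (NULL when no survival given), `seed`.
#' @export
fit_subtypes <- function(nes, k_range = 2:10, n_init = 25, seed = 1,
                         standardize = TRUE, surv = NULL) {
  stopifnot(is.matrix(nes), !is.null(rownames(nes)))
  k_range <- sort(unique(as.integer(k_range)))
  if (nrow(nes) < max(k_range) + 1L) {
    stop("need at least max(k_range) + 1 samples to cluster", call. = FALSE)
  }
  x <- nes[, order(colnames(nes)), drop = FALSE]  # column-order invariance
  if (standardize) {
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0)) {
      stop("degenerate NES matrix: zero-variance gene set(s) ",
           paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
    }
    x <- scale(x)
  } else if (all(apply(x, 2L, stats::sd) == 0)) {
    stop("degenerate NES matrix: all gene sets have zero variance",
         call. = FALSE)
  }
  sil <- stats::setNames(numeric(length(k_range)), k_range)
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    set.seed(seed + k)  # per-k stream: result for k does not depend on range
    fits[[i]] <- stats::kmeans(x, centers = k, nstart = n_init,
                               iter.max = 100L)
    sil[i] <- mean_silhouette(x, fits[[i]]$cluster)
  }
  best <- which.max(sil)  # ties: smallest k wins
  labels <- fits[[best]]$cluster
  names(labels) <- rownames(nes)
  res <- structure(list(labels = labels,
                        selected_k = k_range[best],
                        silhouette_by_k = sil,
                        features = colnames(x),
                        orientation = NULL,
                        seed = seed),
                   class = "subtype_result")
  if (!is.null(surv)) {
    res <- orient_labels(res, surv)
  }
  res
}

#' @export
print.subtype_result <- function(x, ...) {
  cat("subtype_result: k =", x$selected_k, "over",
      length(x$labels), "samples; mean silhouette",
      round(max(x$silhouette_by_k), 4), "\n")
  print(table(TES = x$labels))
  invisible(x)
}

#' Orient subtype labels by prognosis
#'
#' Canonicalizes cluster numbering so that TES 1 is the cluster with the
#' largest Kaplan-Meier restricted-mean survival (restricted at the largest
#' observed time), TES 2 the next, and so on. Ties are broken by cluster
#' size (larger first), then by original label index, so the orientation is
#' deterministic and invariant to the arbitrary numbering K-means returns.
#'
#' @param result A `subtype_result` (or a named label vector).
#' @param surv Survival table covering every labelled sample.
#' @return The `subtype_result` with relabelled `labels` and an
#'   `orientation` data frame (original label, TES label, restricted mean,
#'   cluster size).
#' @export
orient_labels <- function(result, surv) {
  labels <- if (inherits(result, "subtype_result")) result$labels else result
  stopifnot(!is.null(names(labels)))
  validate_survival(surv)
  sv <- surv[match(names(labels), surv$sample_id), , drop = FALSE]
  if (any(is.na(sv$sample_id))) {
    stop("labelled samples missing from survival table", call. = FALSE)
  }
  rmst <- restricted_mean_survival(sv, labels)
  sizes <- table(labels)
  orig <- names(rmst)
  ord <- order(-rmst, -as.numeric(sizes[orig]), as.integer(orig))
  map <- stats::setNames(seq_along(orig), orig[ord])
  new_labels <- unname(map[as.character(labels)])
  names(new_labels) <- names(labels)
  orientation <- data.frame(original = orig[ord],
                            tes = seq_along(orig),
                            restricted_mean = unname(rmst[orig[ord]]),
                            size = as.integer(sizes[orig[ord]]),
                            stringsAsFactors = FALSE)
  if (inherits(result, "subtype_result")) {
    result$labels <- new_labels
    result$orientation <- orientation
    result
  } else {
    structure(new_labels, orientation = orientation)
  }
}
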