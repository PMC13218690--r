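#' Significance stars for a p-value
#'
#' `ns` for p > 0.05, then `*`, `**`, `***` at 0.05, 0.01, 0.001.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of annotations.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", "ns")))
}

#' Wilcoxon rank-sum comparison of one feature between two groups
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test: exact when both groups
#' have at most 10 observations and no ties, otherwise the normal
#' approximation with tie correction.
#'
#' @param values Numeric vector.
#' @param groups Two-level grouping aligned with `values`.
#' @param feature Feature name for the report row.
#' @return One-row data frame: feature, group medians, rank-sum statistic
#'   (Mann-Whitney U of the first group), p_value, stars.
#' @export
wilcoxon_compare <- function(values, groups, feature = "feature") {
  stopifnot(length(values) == length(groups))
  g <- factor(groups)
  if (nlevels(g) != 2L) {
    stop("wilcoxon_compare needs exactly two groups", call. = FALSE)
  }
  x <- values[g == levels(g)[1L]]
  y <- values[g == levels(g)[2L]]
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("values must be finite", call. = FALSE)
  }
  exact <- length(x) <= 10L && length(y) <= 10L
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact)
  )
  data.frame(feature = feature,
             median_1 = stats::median(x),
             median_2 = stats::median(y),
             statistic = unname(wt$statistic),
             p_value = wt$p.value,
             stars = significance_stars(wt$p.value),
             stringsAsFactors = FALSE)
}

#' Compare every column of a feature matrix between two subtypes
#'
#' Applies [wilcoxon_compare()] per column (gene set NES, clinical score,
#' ...), yielding the per-set comparison table used to contrast the tumor
#' ecosystems of two subtypes.
#'
#' @param features Samples x features numeric matrix.
#' @param labels Two-level group label per row.
#' @return Data frame with one [wilcoxon_compare()] row per feature.
#' @export
compare_features_by_group <- function(features, labels) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  out <- do.call(rbind, lapply(colnames(features), function(f) {
    wilcoxon_compare(features[, f], labels, feature = f)
  }))
  rownames(out) <- NULL
  out
}

#' Differential propagated genes between two subtypes
#'
#' Per gene, the log2 fold change of group means on the propagated
#' (probability-scale) profile, regularized by a pseudocount epsilon equal
#' to the smallest positive profile value times 1e-3 (propagated values can
#' be zero for genes unreachable from any seed), and a Wilcoxon rank-sum
#' p-value. A gene passes the filter iff |log2FC| > `lfc_threshold` and
#' p < `p_threshold`.
#'
#' @param profile A `propagated_profile` or samples x genes matrix.
#' @param labels Two-level subtype label per sample; log2FC is
#'   mean(group 1) over mean(group 2) in the factor-level order, so swapping
#'   labels negates it.
#' @param lfc_threshold Absolute log2 fold-change cutoff. Default 1.0.
#' @param p_threshold P-value cutoff. Default 0.05.
#' @return Data frame: gene, mean_1, mean_2, log2_fold_change, p_value,
#'   passes_filter, flagged (TRUE when both group means are zero, in which
#'   case log2FC is defined as 0).
#' @export
differential_genes <- function(profile, labels, lfc_threshold = 1.0,
                               p_threshold = 0.05) {
  values <- if (inherits(profile, "propagated_profile")) profile$values
            else profile
  stopifnot(is.matrix(values), nrow(values) == length(labels))
  g <- factor(labels)
  if (nlevels(g) != 2L) {
    stop("differential analysis needs exactly two groups", call. = FALSE)
  }
  pos <- values[values > 0]
  eps <- if (length(pos)) min(pos) * 1e-3 else 1e-12
  i1 <- g == levels(g)[1L]
  m1 <- colMeans(values[i1, , drop = FALSE])
  m2 <- colMeans(values[!i1, , drop = FALSE])
  lfc <- log2((m1 + eps) / (m2 + eps))
  flagged <- m1 == 0 & m2 == 0
  lfc[flagged] <- 0
  pvals <- vapply(seq_len(ncol(values)), function(j) {
    wilcoxon_compare(values[, j], g)$p_value
  }, 0)
  out <- data.frame(gene = colnames(values),
                    mean_1 = unname(m1), mean_2 = unname(m2),
                    log2_fold_change = unname(lfc),
                    p_value = pvals,
                    flagged = unname(flagged),
                    stringsAsFactors = FALSE)
  out$passes_filter <- abs(out$log2_fold_change) > lfc_threshold &
    out$p_value < p_threshold
  rownames(out) <- NULL
  out
}
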