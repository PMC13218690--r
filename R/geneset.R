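#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name<TAB>description<TAB>`
#' genes. Duplicate genes within a set are dropped; duplicate set names are
#' an error.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (gene sets), with a `descriptions`
#'   attribute (named character).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    stop("GMT file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("GMT file is empty: ", path, call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- vector("list", length(fields))
  nm <- character(length(fields))
  desc <- character(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3L) {
      stop("GMT line ", i, " has fewer than 3 fields", call. = FALSE)
    }
    nm[i] <- f[1L]
    desc[i] <- f[2L]
    sets[[i]] <- unique(trimws(f[-(1:2)]))
  }
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(desc, nm)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character of per-set descriptions;
#'   defaults to the set name.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "descriptions")
  }
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else nm
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Single-sample GSEA enrichment score for one profile and one set
#'
#' Genes are ranked by profile value in decreasing order (ties broken by
#' gene name for determinism) and assigned the rank-from-bottom statistic:
#' the highest-valued gene gets rank N. A running sum steps up by
#' rank^alpha / sum(in-set rank^alpha) at in-set genes and down by
#' 1/(N - |set|) at out-of-set genes; the enrichment score is the *sum* of
#' the running difference over all N positions (the integrated statistic of
#' single-sample GSEA, not the maximal deviation of classical GSEA). Genes
#' in the set but absent from the profile are ignored.
#'
#' @param profile_row Named numeric vector of propagated values for one
#'   sample (>= 2 genes).
#' @param geneset Character vector of member genes.
#' @param alpha Rank-weighting exponent. Default 0.25, the established
#'   single-sample GSEA default.
#' @return Numeric enrichment score, or `NA` (with a warning) when the set
#'   shares no gene with the profile.
#' @export
ssgsea_es <- function(profile_row, geneset, alpha = 0.25) {
  stopifnot(!is.null(names(profile_row)), length(profile_row) >= 2L)
  genes <- names(profile_row)
  n <- length(genes)
  in_profile <- intersect(geneset, genes)
  if (length(in_profile) == 0L) {
    warning("gene set shares no gene with the profile; score is NA")
    return(NA_real_)
  }
  ord <- order(-profile_row, genes)
  sorted_genes <- genes[ord]
  rank_stat <- n:1  # rank-from-bottom along the sorted order
  hit <- sorted_genes %in% in_profile
  n_hit <- sum(hit)
  steps <- numeric(n)
  steps[hit] <- rank_stat[hit]^alpha / sum(rank_stat[hit]^alpha)
  if (n > n_hit) {
    steps[!hit] <- -1 / (n - n_hit)
  }
  sum(cumsum(steps))
}

#' Score a propagated cohort against a gene-set collection
#'
#' Applies [ssgsea_es()] to every (sample, set) pair. A per-set coverage
#' report (number of member genes present in the profile) is attached.
#'
#' @param profile A `propagated_profile` or a samples x genes numeric matrix.
#' @param genesets Named list of gene sets (see [read_gmt()]).
#' @param alpha Rank-weighting exponent, see [ssgsea_es()].
#' @return Samples x sets matrix of raw enrichment scores with attributes
#'   `alpha` and `coverage`.
#' @export
ssgsea_matrix <- function(profile, genesets, alpha = 0.25) {
  values <- if (inherits(profile, "propagated_profile")) profile$values
            else profile
  stopifnot(is.matrix(values), !is.null(colnames(values)),
            is.list(genesets), !is.null(names(genesets)))
  genes <- colnames(values)
  n <- length(genes)
  coverage <- vapply(genesets, function(s) length(intersect(s, genes)), 0L)
  if (any(coverage == 0L)) {
    warning("gene set(s) with no profile overlap: ",
            paste(names(genesets)[coverage == 0L], collapse = ", "))
  }
  es <- matrix(NA_real_, nrow(values), length(genesets),
               dimnames = list(rownames(values), names(genesets)))
  hit_sets <- lapply(genesets, function(s) intersect(s, genes))
  for (i in seq_len(nrow(values))) {
    v <- values[i, ]
    ord <- order(-v, genes)
    sorted_genes <- genes[ord]
    rank_alpha <- (n:1)^alpha
    for (j in seq_along(hit_sets)) {
      members <- hit_sets[[j]]
      if (length(members) == 0L) next
      hit <- sorted_genes %in% members
      n_hit <- sum(hit)
      steps <- numeric(n)
      steps[hit] <- rank_alpha[hit] / sum(rank_alpha[hit])
      if (n > n_hit) steps[!hit] <- -1 / (n - n_hit)
      es[i, j] <- sum(cumsum(steps))
    }
  }
  attr(es, "alpha") <- alpha
  attr(es, "coverage") <- coverage
  es
}

#' Normalize raw enrichment scores to NES
#'
#' NES = ES / (max(ES) - min(ES)), with the range taken over the *entire*
#' raw matrix. Global range normalization keeps scores comparable across
#' samples, which downstream clustering requires; per-sample alternatives
#' would break that comparability.
#'
#' @param es Raw enrichment-score matrix from [ssgsea_matrix()].
#' @return NES matrix of the same shape, with attributes
#'   `normalization_constant` (the global range) and `alpha` (carried over).
#' @export
normalize_nes <- function(es) {
  stopifnot(is.matrix(es))
  fin <- es[is.finite(es)]
  if (length(fin) == 0L) {
    stop("no finite enrichment scores to normalize", call. = FALSE)
  }
  rng <- max(fin) - min(fin)
  if (rng == 0) {
    stop("degenerate enrichment-score range (all scores equal); ",
         "cannot normalize", call. = FALSE)
  }
  nes <- es / rng
  attr(nes, "normalization_constant") <- rng
  attr(nes, "alpha") <- attr(es, "alpha")
  attr(nes, "coverage") <- attr(es, "coverage")
  nes
}
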