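#' Read a MAF-like somatic mutation table
#'
#' Parses a tab-separated variant table with at least a sample-ID column, a
#' gene-symbol column and a variant-classification column (standard MAF names
#' are the defaults). Synonymous/silent records are dropped by default, since
#' they do not alter the protein and carry no propagation signal.
#'
#' @param path Path to a tab-separated file with a header line.
#' @param drop_synonymous Drop records whose classification is in
#'   `silent_classes`? Default `TRUE`.
#' @param sample_col,gene_col,class_col Column names holding the tumor sample
#'   barcode, gene symbol and variant classification.
#' @param silent_classes Character vector of classifications treated as
#'   silent. MAF dialects differ, so this is configurable.
#' @return A data frame with columns `sample`, `gene`, `classification`,
#'   one row per retained variant record. Whitespace around IDs is stripped.
#' @export
read_maf_table <- function(path,
                           drop_synonymous = TRUE,
                           sample_col = "Tumor_Sample_Barcode",
                           gene_col = "Hugo_Symbol",
                           class_col = "Variant_Classification",
                           silent_classes = c("Silent", "Synonymous")) {
  if (!file.exists(path)) {
    stop("mutation file not found: ", path, call. = FALSE)
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "#")
  if (nrow(tab) == 0L) {
    stop("mutation file is empty: ", path, call. = FALSE)
  }
  for (col in c(sample_col, gene_col, class_col)) {
    if (!col %in% names(tab)) {
      stop("mutation file is missing required column '", col, "'",
           call. = FALSE)
    }
  }
  rec <- data.frame(
    sample = trimws(tab[[sample_col]]),
    gene = trimws(tab[[gene_col]]),
    classification = trimws(tab[[class_col]]),
    stringsAsFactors = FALSE
  )
  if (drop_synonymous) {
    rec <- rec[!rec$classification %in% silent_classes, , drop = FALSE]
    rownames(rec) <- NULL
  }
  rec
}

#' Build a patient-by-gene mutation-count matrix from variant records
#'
#' Counts records per (sample, gene) pair. Rows (samples) and columns (genes)
#' that are entirely zero are removed, and both dimensions are ordered
#' lexicographically so the result is invariant to input record order.
#'
#' @param records Data frame with columns `sample` and `gene` (as returned by
#'   [read_maf_table()]).
#' @return Integer matrix, samples as rows, genes as columns, with unique
#'   dimnames. Entry `[s, g]` is the number of variant records for that pair.
#' @export
build_mutation_matrix <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("no mutation records remain; cannot build an empty mutation matrix",
         call. = FALSE)
  }
  samples <- sort(unique(records$sample))
  genes <- sort(unique(records$gene))
  counts <- table(factor(records$sample, levels = samples),
                  factor(records$gene, levels = genes))
  m <- matrix(as.integer(counts), nrow = length(samples),
              dimnames = list(samples, genes))
  prune_mutation_matrix(m)
}

#' Read a precomputed patient-by-gene mutation matrix from TSV
#'
#' Samples as rows (first column = sample IDs), genes as header. All-zero rows
#' and columns are pruned as in [build_mutation_matrix()].
#'
#' @param path Path to a tab-separated numeric matrix with row and column IDs.
#' @return Integer matrix, samples as rows.
#' @export
read_mutation_matrix <- function(path) {
  if (!file.exists(path)) {
    stop("matrix file not found: ", path, call. = FALSE)
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(tab)
  if (!is.numeric(m) || any(!is.finite(m)) || any(m < 0)) {
    stop("mutation matrix must be non-negative and finite", call. = FALSE)
  }
  storage.mode(m) <- "integer"
  prune_mutation_matrix(m)
}

prune_mutation_matrix <- function(m) {
  m <- m[rowSums(m) > 0L, colSums(m) > 0L, drop = FALSE]
  if (nrow(m) == 0L || ncol(m) == 0L) {
    stop("mutation matrix is empty after removing unmutated samples/genes",
         call. = FALSE)
  }
  m <- m[order(rownames(m)), order(colnames(m)), drop = FALSE]
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop("mutation matrix has duplicated sample or gene IDs", call. = FALSE)
  }
  m
}

#' Binarize a mutation-count matrix
#'
#' The propagation seed uses mutated-vs-not status rather than counts: the
#' restart distribution is defined over the set of mutated genes of a sample,
#' so multiplicity carries no extra weight.
#'
#' @param m Mutation-count matrix (samples x genes).
#' @return Integer 0/1 matrix of the same shape and dimnames.
#' @export
binarize_mutations <- function(m) {
  b <- (m > 0) + 0L
  dimnames(b) <- dimnames(m)
  b
}
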