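#' Construct a gene interaction network from an edge table
#'
#' Canonical constructor shared by the STRING reader and the synthetic
#' generator. Self-loops are dropped, duplicate and reciprocal pairs are
#' merged keeping the maximum score, and nodes/edges are ordered
#' lexicographically so construction is invariant to input edge order.
#'
#' @param edges Data frame with columns `from`, `to` (character) and `weight`
#'   (numeric, STRING combined-score scale 0-1000).
#' @return An object of class `gene_network`: a list with `nodes` (ordered
#'   unique gene symbols) and `edges` (canonicalized edge table). The RWR
#'   transition matrix is added by [build_transition_matrix()].
#' @export
gene_network <- function(edges) {
  stopifnot(is.data.frame(edges),
            all(c("from", "to", "weight") %in% names(edges)))
  from <- trimws(as.character(edges$from))
  to <- trimws(as.character(edges$to))
  w <- as.numeric(edges$weight)
  keep <- from != to
  from <- from[keep]; to <- to[keep]; w <- w[keep]
  if (length(from) == 0L) {
    stop("network has no edges after removing self-loops", call. = FALSE)
  }
  # canonical unordered pair: lexicographically smaller endpoint first
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  w <- tapply(w, key, max)
  pair <- strsplit(names(w), "\r", fixed = TRUE)
  ed <- data.frame(from = vapply(pair, `[`, "", 1L),
                   to = vapply(pair, `[`, "", 2L),
                   weight = as.numeric(w),
                   stringsAsFactors = FALSE)
  ed <- ed[order(ed$from, ed$to), , drop = FALSE]
  rownames(ed) <- NULL
  structure(list(nodes = sort(unique(c(ed$from, ed$to))), edges = ed),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat("gene_network:", length(x$nodes), "nodes,", nrow(x$edges), "edges",
      if (!is.null(x$transition)) "(transition matrix built)" else "", "\n")
  invisible(x)
}

#' Read a STRING-style protein-links file
#'
#' Expects whitespace- or tab-separated columns `protein1 protein2
#' combined_score` (header optional). Only links with combined score
#' *strictly greater than* the threshold are retained; 700 is STRING's
#' high-confidence cutoff. Duplicate/reciprocal pairs keep the maximum score
#' and self-loops are dropped. Isolated nodes cannot occur: every retained
#' node is an endpoint of a retained edge.
#'
#' @param path Path to the links file.
#' @param score_threshold Minimum combined score (exclusive). Default 700.
#' @return A `gene_network` (edges only; see [build_transition_matrix()]).
#' @export
read_string_links <- function(path, score_threshold = 700) {
  if (!file.exists(path)) {
    stop("network file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("network file is empty: ", path, call. = FALSE)
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  first_line <- 1L
  f1 <- fields[[1L]]
  if (length(f1) >= 3L && is.na(suppressWarnings(as.numeric(f1[3L])))) {
    first_line <- 2L  # header
  }
  from <- character(0); to <- character(0); score <- numeric(0)
  for (i in seq(first_line, length.out = length(fields) - first_line + 1L)) {
    f <- fields[[i]]
    if (length(f) < 3L) {
      stop("malformed network line ", i, ": expected 3 fields, got ",
           length(f), call. = FALSE)
    }
    s <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s)) {
      stop("malformed score on network line ", i, ": '", f[3L], "'",
           call. = FALSE)
    }
    from <- c(from, f[1L]); to <- c(to, f[2L]); score <- c(score, s)
  }
  keep <- score > score_threshold
  if (!any(keep)) {
    stop("no interactions exceed score threshold ", score_threshold,
         "; lower --min-score or check the score scale", call. = FALSE)
  }
  gene_network(data.frame(from = from[keep], to = to[keep],
                          weight = score[keep], stringsAsFactors = FALSE))
}

#' Build the column-stochastic RWR transition matrix
#'
#' The random walk update requires a column-stochastic operator W: column j
#' is the adjacency column of node j divided by its sum, so each step
#' conserves probability mass. By default the adjacency is unweighted
#' (1 for every retained edge); with `weighted = TRUE` the combined scores
#' are used as edge weights.
#'
#' @param network A `gene_network` from [gene_network()] or
#'   [read_string_links()].
#' @param weighted Use combined scores as adjacency weights? Default `FALSE`.
#' @return The `gene_network` with a `transition` matrix (dense, nodes x
#'   nodes, column sums exactly 1 up to rounding) and the `weighted` flag.
#' @export
build_transition_matrix <- function(network, weighted = FALSE) {
  stopifnot(inherits(network, "gene_network"))
  nodes <- network$nodes
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  i <- match(network$edges$from, nodes)
  j <- match(network$edges$to, nodes)
  w <- if (weighted) network$edges$weight else rep(1, nrow(network$edges))
  A[cbind(i, j)] <- w
  A[cbind(j, i)] <- w
  cs <- colSums(A)
  # isolated nodes are impossible: every node is an edge endpoint
  W <- sweep(A, 2L, cs, "/")
  network$transition <- W
  network$weighted <- weighted
  network
}
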