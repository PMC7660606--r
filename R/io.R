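#' Construct a validated expression matrix
#'
#' The canonical container throughout the package is a plain numeric matrix
#' with genes in rows and samples in columns, gene identifiers as row names
#' and sample identifiers as column names. An optional per-sample grouping
#' (e.g. case/control) is carried in the `"groups"` attribute.
#'
#' @param values Numeric matrix, genes x samples.
#' @param genes Character vector of unique gene identifiers (defaults to
#'   row names, or `G1..Gp` when absent).
#' @param samples Character vector of sample identifiers (defaults to column
#'   names, or `S1..Sn`).
#' @param groups Optional vector of per-sample group labels, length `ncol`.
#' @return The validated matrix with dimnames set (and a `groups` attribute
#'   when supplied).
#' @examples
#' x <- expression_matrix(matrix(rnorm(12), 3, 4))
#' dim(x)
#' @export
expression_matrix <- function(values, genes = rownames(values),
                              samples = colnames(values), groups = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  p <- nrow(values)
  n <- ncol(values)
  if (p < 2L) stop("at least 2 genes are required")
  if (n < 3L) stop("at least 3 samples are required")
  if (!all(is.finite(values))) stop("expression values must all be finite")
  if (is.null(genes)) genes <- paste0("G", seq_len(p))
  if (is.null(samples)) samples <- paste0("S", seq_len(n))
  if (length(genes) != p || length(samples) != n)
    stop("identifier lists must match matrix dimensions")
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  dimnames(values) <- list(as.character(genes), as.character(samples))
  if (!is.null(groups)) {
    if (length(groups) != n) stop("groups must have one label per sample")
    attr(values, "groups") <- as.character(groups)
  }
  values
}

validate_expression <- function(expr) {
  expression_matrix(expr, groups = attr(expr, "groups"))
}

#' Read an expression matrix from a delimited text file
#'
#' Accepts either orientation. Files are expected to have a header line of
#' identifiers and a leading identifier column; a file whose first body
#' column parses entirely as numeric (the common benchmark layout of a
#' gene-name header over bare sample rows) is treated as having no
#' identifier column, and identifiers are generated.
#'
#' @param path Path to a delimited text file.
#' @param orientation `"genes"` if rows are genes (default), `"samples"` if
#'   rows are samples; the returned matrix is always genes x samples.
#' @param delimiter Field separator (tab by default).
#' @return A genes x samples [expression_matrix()].
#' @export
read_expression <- function(path, orientation = c("genes", "samples"),
                            delimiter = "\t") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "",
                           row.names = NULL, quote = "")
  if (ncol(raw) < 2L) stop("file must have at least two columns")
  first_numeric <- !anyNA(suppressWarnings(as.numeric(raw[[1L]])))
  if (first_numeric) {
    ids <- paste0(if (orientation == "genes") "G" else "S", seq_len(nrow(raw)))
    body <- as.matrix(raw)
  } else {
    ids <- raw[[1L]]
    body <- as.matrix(raw[, -1L, drop = FALSE])
  }
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body),
                                dimnames = list(ids, colnames(body))))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric or missing value at row '%s', column '%s'",
                 ids[bad[1L, 1L]], colnames(body)[bad[1L, 2L]]))
  }
  if (orientation == "samples") num <- t(num)
  if (anyDuplicated(rownames(num)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(num)[duplicated(rownames(num))]), collapse = ", "))
  expression_matrix(num)
}

#' Write an expression matrix to a delimited text file
#'
#' @param expr Expression matrix (genes x samples).
#' @param path Output path.
#' @param delimiter Field separator.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, delimiter = "\t") {
  expr <- validate_expression(expr)
  body <- matrix(sprintf("%.17g", expr), nrow(expr), ncol(expr))
  lines <- c(paste(c("gene", colnames(expr)), collapse = delimiter),
             paste(rownames(expr), apply(body, 1L, paste, collapse = delimiter),
                   sep = delimiter))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a directed weighted gene network
#'
#' @param weights Square non-negative numeric matrix; entry `(i, j)` is the
#'   strength with which gene `i` regulates gene `j`. The diagonal must be
#'   zero (no self-regulation).
#' @param genes Gene identifiers (defaults to row names).
#' @param directed Logical flag, kept for symmetry with undirected scores.
#' @return An object of class `gene_network`.
#' @export
gene_network <- function(weights, genes = rownames(weights), directed = TRUE) {
  weights <- as.matrix(weights)
  p <- nrow(weights)
  if (ncol(weights) != p) stop("weight matrix must be square")
  if (is.null(genes)) genes <- paste0("G", seq_len(p))
  if (length(genes) != p) stop("gene list must match matrix dimension")
  if (anyDuplicated(genes)) stop("duplicate gene identifiers in network")
  if (!all(is.finite(weights))) stop("weights must be finite")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (any(diag(weights) != 0)) stop("self-loops are not allowed (non-zero diagonal)")
  dimnames(weights) <- list(as.character(genes), as.character(genes))
  structure(list(weights = weights, directed = isTRUE(directed)),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  ne <- sum(x$weights > 0)
  cat(sprintf("gene_network: %d genes, %d %s edges\n", nrow(x$weights), ne,
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}

#' Extract the positive-weight edges of a network as a data frame
#'
#' Edges are sorted by decreasing weight, ties broken by (source, target)
#' lexicographic order so the listing is deterministic.
#'
#' @param network A `gene_network`.
#' @param min_weight Keep only edges with weight at least this value.
#' @return Data frame with columns `source`, `target`, `weight`.
#' @export
network_edges <- function(network, min_weight = 0) {
  W <- network$weights
  g <- rownames(W)
  idx <- which(W > 0 & W >= min_weight)
  df <- data.frame(source = g[(idx - 1L) %% nrow(W) + 1L],
                   target = g[(idx - 1L) %/% nrow(W) + 1L],
                   weight = W[idx], stringsAsFactors = FALSE)
  df <- df[order(-df$weight, df$source, df$target, method = "radix"), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a network as a three-column edge list
#'
#' Rows are `source<TAB>target<TAB>weight`, sorted by descending weight with
#' deterministic lexicographic tie order. An empty network produces a
#' header-only file.
#'
#' @inheritParams network_edges
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, min_weight = 0) {
  df <- network_edges(network, min_weight)
  lines <- c("source\ttarget\tweight",
             if (nrow(df)) paste(df$source, df$target,
                                 sprintf("%.17g", df$weight), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a network from a three-column edge list
#'
#' @param path Path to a tab-separated edge list with header
#'   `source target weight`.
#' @param genes Optional gene universe; inferred (sorted) from edge
#'   endpoints when absent. Unlisted pairs get weight 0.
#' @param directed Directedness flag for the returned network.
#' @return A [gene_network()].
#' @export
read_network <- function(path, genes = NULL, directed = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = c("character", "character", "numeric"),
                          col.names = c("source", "target", "weight"))
  if (nrow(df)) {
    if (any(df$weight < 0)) stop("negative edge weight in ", path)
    loops <- df$source == df$target
    if (any(loops))
      stop("self-loop edge: ", df$source[which(loops)[1L]])
  }
  if (is.null(genes)) genes <- sort(unique(c(df$source, df$target)))
  if (!all(c(df$source, df$target) %in% genes))
    stop("edge endpoint outside the supplied gene universe")
  W <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  if (nrow(df)) W[cbind(df$source, df$target)] <- df$weight
  gene_network(W, directed = directed)
}

#' Write a network as an adjacency-matrix CSV (alternative format)
#'
#' @param network A `gene_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_adjacency <- function(network, path) {
  utils::write.csv(network$weights, path, quote = FALSE)
  invisible(path)
}
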