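#' Read a rectangular data table
#'
#' Reads a delimited text file with a header row into the numeric
#' observations-by-variables matrix used throughout the package. Binary
#' status variables encoded 0/1 are ordinary numeric columns.
#'
#' @param path file path; the delimiter is sniffed from the extension
#'   (`.csv` = comma, otherwise tab) unless `sep` is given.
#' @param missing_policy `"drop_rows"` (default) removes every row containing
#'   a missing cell, keeping a single consistent sample size for the
#'   likelihood-ratio tests and regressions downstream; `"error"` fails on
#'   the first missing or non-numeric cell.
#' @param sep field delimiter override.
#' @return Numeric matrix with column names; rows are observations.
#' @export
read_data <- function(path, missing_policy = c("drop_rows", "error"),
                      sep = NULL) {
  missing_policy <- match.arg(missing_policy)
  sep <- sep %||% sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  bad <- !vapply(df, is.numeric, logical(1))
  if (any(bad)) {
    # non-numeric columns arise from genuinely textual cells; coerce and let
    # the policy decide what to do with the resulting NAs
    if (missing_policy == "error")
      stop("non-numeric cell(s) in column(s): ",
           paste(names(df)[bad], collapse = ", "))
    df[bad] <- lapply(df[bad], function(x) suppressWarnings(as.numeric(x)))
  }
  m <- as.matrix(df)
  if (anyNA(m)) {
    if (missing_policy == "error")
      stop("missing values present and missing_policy = \"error\"")
    m <- m[stats::complete.cases(m), , drop = FALSE]
  }
  if (nrow(m) < 3L)
    stop("fewer than 3 complete rows; correlations would be degenerate")
  as_data_matrix(m)
}

#' Read an aggregate correlation matrix
#'
#' Builds a [`corr_matrix`][correlation_matrix] from a stored symmetric
#' correlation matrix plus the sample size it was computed from; this is the
#' aggregate-information entry point for when raw data are not available.
#' The file must carry variable names in both the header row and the first
#' column, and the two must agree.
#'
#' @param path CSV/TSV file holding the full square matrix.
#' @param n sample size the correlations were estimated from (needed for
#'   p-values and likelihood-ratio tests).
#' @param method tag recorded on the result, `"pearson"` or `"spearman"`.
#' @param sep field delimiter override.
#' @return A [`corr_matrix`][correlation_matrix].
#' @export
read_corr <- function(path, n, method = c("spearman", "pearson"), sep = NULL) {
  method <- match.arg(method)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 4, n == as.integer(n))
  sep <- sep %||% sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE)
  r <- as.matrix(df)
  if (nrow(r) != ncol(r)) stop("correlation matrix must be square")
  if (!identical(rownames(r), colnames(r)))
    stop("row names and column names disagree")
  validate_corr_values(r)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  new_corr_matrix(r, n, method)
}

validate_corr_values <- function(r, tol = 1e-8) {
  if (!is.numeric(r) || anyNA(r)) stop("correlation matrix must be numeric")
  if (max(abs(r - t(r))) > tol)
    stop("matrix asymmetric beyond tolerance ", format(tol))
  if (max(abs(diag(r) - 1)) > tol) stop("diagonal entries must equal 1")
  if (max(abs(r)) > 1 + tol) stop("correlation entries must lie in [-1, 1]")
  invisible(r)
}

#' Write a chain graph to a file
#'
#' Serializes an undirected signed graph in one of four plain-text formats.
#' Nodes and edges are written in lexicographic order so repeated runs
#' produce byte-identical files.
#'
#' @param g a [`snha_graph`][merge_chains].
#' @param path output file.
#' @param format one of:
#'   \describe{
#'     \item{`edgelist`}{TSV with columns `node_a`, `node_b`, `sign`,
#'       `weight` (the signed correlation).}
#'     \item{`dot`}{Graphviz DOT; negative-sign edges are colored red,
#'       positive black.}
#'     \item{`graphml`}{GraphML via \pkg{igraph}, with `sign` and `weight`
#'       edge attributes.}
#'     \item{`adjacency`}{full signed adjacency CSV (entries are the signed
#'       correlations, 0 for absent edges), names in header and first
#'       column.}
#'   }
#' @return `path`, invisibly.
#' @seealso [read_adjacency()] for the adjacency round-trip.
#' @export
write_graph <- function(g, path,
                        format = c("edgelist", "dot", "graphml", "adjacency")) {
  stopifnot(inherits(g, "snha_graph"))
  format <- match.arg(format)
  nodes <- sort(g$nodes)
  e <- g$edges
  if (nrow(e) > 0) e <- e[order(e$from, e$to), , drop = FALSE]
  switch(format,
    edgelist = {
      out <- data.frame(node_a = e$from, node_b = e$to,
                        sign = e$sign, weight = format_num(e$weight))
      utils::write.table(out, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    },
    dot = {
      lines <- c("graph snha {",
                 sprintf("  \"%s\";", nodes),
                 if (nrow(e) > 0)
                   sprintf("  \"%s\" -- \"%s\" [color=%s, weight=\"%s\"];",
                           e$from, e$to,
                           ifelse(e$sign < 0, "red", "black"),
                           format_num(e$weight)),
                 "}")
      writeLines(lines, path)
    },
    graphml = {
      ig <- igraph::graph_from_data_frame(
        e[, c("from", "to", "sign", "weight")],
        directed = FALSE,
        vertices = data.frame(name = nodes))
      igraph::write_graph(ig, path, format = "graphml")
    },
    adjacency = {
      a <- matrix(0, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
      if (nrow(e) > 0) {
        a[cbind(e$from, e$to)] <- e$weight
        a[cbind(e$to, e$from)] <- e$weight
      }
      utils::write.csv(as.data.frame(a), path, quote = FALSE)
    })
  invisible(path)
}

#' Read a signed adjacency matrix written by [write_graph()]
#'
#' @param path adjacency CSV.
#' @return Symmetric numeric matrix of signed edge weights (0 = no edge).
#' @export
read_adjacency <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  a <- as.matrix(df)
  if (!identical(rownames(a), colnames(a)) || nrow(a) != ncol(a))
    stop("not a square named adjacency matrix")
  a
}

sniff_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

# full precision, but stable across platforms
format_num <- function(x) formatC(x, digits = 15, format = "g")

`%||%` <- function(a, b) if (is.null(a)) b else a
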