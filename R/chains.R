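#' Grow a descending-correlation sequence from a start variable
#'
#' The greedy walk at the heart of St. Nicolas House Analysis. From the
#' current element, the next element is the not-yet-visited variable with
#' the largest absolute correlation to it. Growth stops when that best
#' candidate falls below the absolute-correlation floor, is not significant
#' at `alpha`, or no unvisited variables remain. Ties in absolute
#' correlation are broken toward the variable that comes first in the
#' matrix's variable order, which makes the walk deterministic.
#'
#' @param c a [`corr_matrix`][correlation_matrix].
#' @param start name of the start variable.
#' @param alpha significance level a correlation must reach to be ranked.
#' @param abs_threshold absolute-correlation floor; the boxed stopping rule
#'   uses 0.1.
#' @return Character vector of variable names, `start` first. Length 1 when
#'   the start has no admissible neighbor.
#' @export
grow_sequence <- function(c, start, alpha = 0.05, abs_threshold = 0.1) {
  stopifnot(inherits(c, "corr_matrix"))
  if (!start %in% c$var_names) stop("unknown start variable: ", start)
  rho <- abs(c$r)
  seq_ <- start
  repeat {
    cur <- seq_[length(seq_)]
    cand <- setdiff(c$var_names, seq_)
    if (length(cand) == 0L) break
    v <- rho[cur, cand]
    best <- cand[which.max(v)]        # first max = earliest in var order
    if (rho[cur, best] < abs_threshold || c$p[cur, best] > alpha) break
    seq_ <- c(seq_, best)
  }
  seq_
}

#' Check the reversibility of a variable sequence
#'
#' A sequence qualifies as an association chain only if walking greedily
#' from its last element reproduces exactly the reversed sequence, i.e.
#' reversing start and end point does not alter the order of elements.
#'
#' @inheritParams grow_sequence
#' @param seq_ character vector of variable names, length at least 2.
#' @return `TRUE` or `FALSE`.
#' @export
is_reversible <- function(c, seq_, alpha = 0.05, abs_threshold = 0.1) {
  stopifnot(length(seq_) >= 2L)
  back <- grow_sequence(c, seq_[length(seq_)], alpha, abs_threshold)
  identical(back, rev(seq_))
}

#' Find all association chains in a correlation matrix
#'
#' Runs the greedy walk from every variable, keeps sequences of at least 3
#' members whose reversal reproduces the same ordering, and deduplicates
#' (a chain and its reversal are the same chain; the canonical orientation
#' puts the lexicographically smaller endpoint first).
#'
#' @inheritParams grow_sequence
#' @param consistent apply the ordering-consistency post-filter: when two
#'   accepted chains order a shared pair of variables incompatibly (under
#'   either orientation), drop the shorter chain (on equal length, the
#'   lexicographically larger one). Off by default; see the methods
#'   vignette for why the unfiltered chain set is the canonical output.
#' @return List of character vectors (possibly empty), each a chain in
#'   canonical orientation, sorted by decreasing length then alphabetically.
#' @export
find_chains <- function(c, alpha = 0.05, abs_threshold = 0.1,
                        consistent = FALSE) {
  stopifnot(inherits(c, "corr_matrix"))
  chains <- list()
  for (v in c$var_names) {
    s <- grow_sequence(c, v, alpha, abs_threshold)
    if (length(s) < 3L) next
    if (!is_reversible(c, s, alpha, abs_threshold)) next
    chains[[length(chains) + 1L]] <- canonical_chain(s)
  }
  keys <- vapply(chains, paste, "", collapse = "\r")
  chains <- chains[!duplicated(keys)]
  chains <- chains[order(-lengths(chains),
                         vapply(chains, paste, "", collapse = "\r"))]
  if (consistent) chains <- filter_consistent(chains)
  chains
}

canonical_chain <- function(s) {
  if (s[1] > s[length(s)]) rev(s) else s
}

# Greedy longest-first pass: keep a chain only if, for every already kept
# chain, the shared members appear in the same relative order under some
# orientation. Input must be sorted by decreasing length then key, so the
# dropped chain is always the shorter (or lexicographically larger) one.
filter_consistent <- function(chains) {
  kept <- list()
  for (ch in chains) {
    ok <- all(vapply(kept, chains_compatible, logical(1), ch))
    if (ok) kept[[length(kept) + 1L]] <- ch
  }
  kept
}

chains_compatible <- function(a, b) {
  shared <- intersect(a, b)
  if (length(shared) < 2L) return(TRUE)
  oa <- a[a %in% shared]
  ob <- b[b %in% shared]
  identical(oa, ob) || identical(oa, rev(ob))
}

#' Merge association chains into the St. Nicolas House graph
#'
#' The final graph is the union of the consecutive pairs of all accepted
#' chains. Each edge keeps the sign and value of its correlation
#' coefficient and records which chains contributed it. Variables that
#' appear in no chain remain as isolated nodes.
#'
#' @param chains list of chains as returned by [find_chains()].
#' @param c the [`corr_matrix`][correlation_matrix] the chains were found in.
#' @return An object of class `snha_graph`: list with `nodes` (all variable
#'   names), `edges` (data frame `from`, `to`, `sign`, `weight`, endpoints
#'   ordered `from < to`), `provenance` (list mapping `"from|to"` to the
#'   indices of contributing chains), and `chains`.
#' @export
merge_chains <- function(chains, c) {
  stopifnot(inherits(c, "corr_matrix"))
  unknown <- setdiff(unique(unlist(chains)), c$var_names)
  if (length(unknown) > 0)
    stop("chain references unknown variable(s): ",
         paste(unknown, collapse = ", "))
  prov <- list()
  for (i in seq_along(chains)) {
    ch <- chains[[i]]
    for (j in seq_len(length(ch) - 1L)) {
      a <- ch[j]; b <- ch[j + 1L]
      key <- paste(min(a, b), max(a, b), sep = "|")
      prov[[key]] <- c(prov[[key]], i)
    }
  }
  keys <- sort(names(prov))
  prov <- prov[keys]
  if (length(keys) > 0) {
    ab <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
    w <- c$r[cbind(ab[, 1], ab[, 2])]
    edges <- data.frame(from = ab[, 1], to = ab[, 2],
                        sign = ifelse(w < 0, -1L, 1L), weight = w,
                        stringsAsFactors = FALSE, row.names = NULL)
  } else {
    edges <- empty_edges()
  }
  new_snha_graph(c$var_names, edges, prov, chains)
}

empty_edges <- function() {
  data.frame(from = character(), to = character(),
             sign = integer(), weight = numeric(), stringsAsFactors = FALSE)
}

new_snha_graph <- function(nodes, edges, provenance = list(), chains = list()) {
  stopifnot(all(edges$from %in% nodes), all(edges$to %in% nodes))
  structure(list(nodes = nodes, edges = edges,
                 provenance = provenance, chains = chains),
            class = "snha_graph")
}

#' Number of edges in a chain graph
#' @param g a [`snha_graph`][merge_chains].
#' @return Integer edge count.
#' @export
n_edges <- function(g) {
  stopifnot(inherits(g, "snha_graph"))
  nrow(g$edges)
}

#' @export
print.snha_graph <- function(x, ...) {
  cat(sprintf("snha_graph: %d nodes, %d edges, %d chains\n",
              length(x$nodes), nrow(x$edges), length(x$chains)))
  if (nrow(x$edges) > 0) {
    e <- x$edges
    cat(paste0("  ", e$from, ifelse(e$sign < 0, " -(-)- ", " ----- "),
               e$to, sprintf("  (r = %.2f)", e$weight), collapse = "\n"),
        "\n")
  }
  invisible(x)
}

#' Chains of a graph as a table
#'
#' @param g a [`snha_graph`][merge_chains].
#' @return Data frame with columns `chain` (id), `members` (names joined by
#'   `-`), `length`.
#' @export
chains_table <- function(g) {
  stopifnot(inherits(g, "snha_graph"))
  data.frame(
    chain = seq_along(g$chains),
    members = vapply(g$chains, paste, "", collapse = "-"),
    length = lengths(g$chains),
    stringsAsFactors = FALSE
  )
}

#' St. Nicolas House Analysis
#'
#' Single-call facade: correlation matrix (if raw data are supplied), chain
#' search, graph merge, and per-chain likelihood-ratio tests. Works equally
#' from a raw data table or from an aggregate correlation matrix with known
#' sample size — the chain search and the LR tests need only correlations
#' and `n`.
#'
#' @param d numeric data matrix/data frame with named columns, or a
#'   [`corr_matrix`][correlation_matrix].
#' @param method correlation method when `d` is raw data (default
#'   `"spearman"`).
#' @param alpha significance level for ranking correlations (default 0.05).
#' @param abs_threshold absolute-correlation floor (default 0.1).
#' @param consistent see [find_chains()].
#' @return Object of class `snha`: list with `graph` (the
#'   [`snha_graph`][merge_chains]), `lr` (data frame of per-chain
#'   likelihood-ratio tests: members, df, chi2, p_value), `corr`, `alpha`,
#'   `abs_threshold`.
#' @examples
#' set.seed(1)
#' d <- generate_planted(planted_path(5, n_obs = 300, seed = 7))
#' fit <- snha(d)
#' fit
#' @export
snha <- function(d, method = c("spearman", "pearson"),
                 alpha = 0.05, abs_threshold = 0.1, consistent = FALSE) {
  method <- match.arg(method)
  cm <- if (inherits(d, "corr_matrix")) d else correlation_matrix(d, method)
  chains <- find_chains(cm, alpha, abs_threshold, consistent)
  g <- merge_chains(chains, cm)
  lr <- lr_table(chains, cm)
  structure(list(graph = g, lr = lr, corr = cm,
                 alpha = alpha, abs_threshold = abs_threshold),
            class = "snha")
}

#' @export
print.snha <- function(x, ...) {
  cat(sprintf("St. Nicolas House Analysis (%s, alpha = %g, |r| >= %g)\n",
              x$corr$method, x$alpha, x$abs_threshold))
  print(x$graph)
  if (nrow(x$lr) > 0) {
    cat("chain likelihood-ratio tests:\n")
    print(x$lr, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
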