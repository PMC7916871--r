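#' Correlation-threshold network
#'
#' The naive baseline: an edge for every pair of variables whose absolute
#' correlation strictly exceeds `r_min`, optionally also requiring
#' significance at `alpha`. No chains are involved.
#'
#' @param c a [`corr_matrix`][correlation_matrix].
#' @param r_min absolute-correlation threshold in \[0, 1).
#' @param alpha optional significance level; `NULL` (default) applies the
#'   \eqn{|r|} threshold alone.
#' @return An [`snha_graph`][merge_chains] with an empty chain list.
#' @export
threshold_network <- function(c, r_min, alpha = NULL) {
  stopifnot(inherits(c, "corr_matrix"),
            is.numeric(r_min), r_min >= 0, r_min < 1)
  vn <- c$var_names
  keep <- abs(c$r) > r_min
  if (!is.null(alpha)) keep <- keep & c$p <= alpha
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    a <- vn[idx[, 1]]; b <- vn[idx[, 2]]
    from <- pmin(a, b); to <- pmax(a, b)
    w <- c$r[cbind(a, b)]
    o <- order(from, to)
    edges <- data.frame(from = from[o], to = to[o],
                        sign = ifelse(w[o] < 0, -1L, 1L), weight = w[o],
                        stringsAsFactors = FALSE)
  } else {
    edges <- empty_edges()
  }
  new_snha_graph(vn, edges)
}

#' Forward-selection linear-model network
#'
#' For each variable taken as regression target, predictors are added one
#' at a time by forward selection: at each step the candidate giving the
#' largest increase in R-squared enters, provided the increase is at least
#' `r2_min` and its partial F-test p-value is at most `alpha`. Every
#' selected target–predictor pair becomes an undirected edge; the graph is
#' the union over all targets.
#'
#' @param d numeric data matrix/data frame.
#' @param r2_min minimum R-squared increase for a predictor to enter
#'   (common choices 0.01 and 0.10).
#' @param alpha partial F-test significance level (default 0.05).
#' @return An [`snha_graph`][merge_chains] with an empty chain list; edge
#'   weights are the pairwise correlations of the connected variables.
#' @export
forward_lm_network <- function(d, r2_min, alpha = 0.05) {
  d <- as_data_matrix(d)
  stopifnot(is.numeric(r2_min), r2_min >= 0)
  vn <- colnames(d)
  pairs <- character()
  for (target in vn) {
    y <- d[, target]
    selected <- character()
    pool <- setdiff(vn, target)
    r2_cur <- 0
    rss_cur <- sum((y - mean(y))^2)
    tss <- rss_cur
    while (length(pool) > 0 && nrow(d) > length(selected) + 2L) {
      r2_new <- vapply(pool, function(p) {
        fit <- stats::lm.fit(cbind(1, d[, c(selected, p), drop = FALSE]), y)
        1 - sum(fit$residuals^2) / tss
      }, numeric(1))
      best <- pool[which.max(r2_new)]
      gain <- r2_new[best] - r2_cur
      if (gain < r2_min) break
      rss_new <- tss * (1 - r2_new[best])
      df_res <- nrow(d) - length(selected) - 2L
      f <- (rss_cur - rss_new) / (rss_new / df_res)
      p <- stats::pf(f, 1, df_res, lower.tail = FALSE)
      if (p > alpha) break
      selected <- c(selected, best)
      pool <- setdiff(pool, best)
      r2_cur <- r2_new[best]
      rss_cur <- rss_new
    }
    if (length(selected) > 0)
      pairs <- c(pairs, paste(pmin(target, selected),
                              pmax(target, selected), sep = "|"))
  }
  pairs <- sort(unique(pairs))
  if (length(pairs) > 0) {
    ab <- do.call(rbind, strsplit(pairs, "|", fixed = TRUE))
    w <- stats::cor(d)[cbind(ab[, 1], ab[, 2])]
    edges <- data.frame(from = ab[, 1], to = ab[, 2],
                        sign = ifelse(w < 0, -1L, 1L), weight = w,
                        stringsAsFactors = FALSE)
  } else {
    edges <- empty_edges()
  }
  new_snha_graph(vn, edges)
}

#' Spurious-edge comparison on null data
#'
#' The falseness experiment: every network builder is applied to the same
#' replicates of null data (scrambled or independently generated, so any
#' edge is spurious), edge counts are recorded, and the builders are
#' compared pairwise with two-sided Wilcoxon rank-sum tests under Holm
#' correction across all builder pairs. A method that agrees less with
#' noise — fewer spurious edges — is the more trustworthy one.
#'
#' @param builders named list of functions, each mapping a data matrix to
#'   an [`snha_graph`][merge_chains].
#' @param null_replicates list of at least 2 null data matrices.
#' @return List of class `network_comparison`: `counts` (data frame
#'   `replicate`, `method`, `n_edges`) and `tests` (data frame `method_a`,
#'   `method_b`, `p_value`, `p_holm`).
#' @export
count_spurious_edges <- function(builders, null_replicates) {
  stopifnot(is.list(builders), length(builders) >= 2,
            !is.null(names(builders)), all(nzchar(names(builders))),
            is.list(null_replicates))
  if (length(null_replicates) < 2)
    stop("need at least 2 null replicates")
  if (length(null_replicates) < 10)
    warning("fewer than 10 replicates: rank-sum comparisons are underpowered")
  methods <- names(builders)
  counts <- expand.grid(replicate = seq_along(null_replicates),
                        method = methods, stringsAsFactors = FALSE)
  counts$n_edges <- mapply(function(rep, m) {
    n_edges(builders[[m]](null_replicates[[rep]]))
  }, counts$replicate, counts$method)
  pairs <- utils::combn(methods, 2)
  p_raw <- apply(pairs, 2, function(pr) {
    a <- counts$n_edges[counts$method == pr[1]]
    b <- counts$n_edges[counts$method == pr[2]]
    if (all(a == b)) return(1)  # identical distributions, nothing to test
    suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
  })
  tests <- data.frame(method_a = pairs[1, ], method_b = pairs[2, ],
                      p_value = p_raw,
                      p_holm = stats::p.adjust(p_raw, "holm"),
                      stringsAsFactors = FALSE)
  structure(list(counts = counts, tests = tests),
            class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  med <- tapply(x$counts$n_edges, x$counts$method, stats::median)
  cat("spurious edges per method (median over",
      max(x$counts$replicate), "replicates):\n")
  print(med)
  cat("pairwise rank-sum tests (Holm-adjusted):\n")
  print(x$tests, row.names = FALSE, digits = 3)
  invisible(x)
}
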