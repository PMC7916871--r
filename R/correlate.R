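#' Correlation matrix with significance levels
#'
#' Computes the matrix of bivariate correlation coefficients that the
#' association-chain algorithm ranks, together with two-sided p-values for
#' each coefficient. Spearman correlations are Pearson correlations of the
#' within-column mid-ranks; for both methods the p-value comes from the
#' t statistic \eqn{t = r \sqrt{(n-2)/(1-r^2)}} referred to a t distribution
#' with \eqn{n-2} degrees of freedom (a large-sample approximation in the
#' Spearman case).
#'
#' @param d numeric matrix or data frame, observations in rows, named
#'   variables in columns (as returned by [read_data()]).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return An object of class `corr_matrix`: a list with components
#'   `r` (signed correlation matrix, unit diagonal), `p` (two-sided p-value
#'   matrix, zero diagonal), `n` (sample size), `method`, and `var_names`.
#' @examples
#' d <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, LETTERS[1:4]))
#' cm <- correlation_matrix(d)
#' cm$r["A", "B"]
#' @seealso [read_corr()] to build the same object from an aggregate
#'   correlation matrix when raw data are unavailable.
#' @export
correlation_matrix <- function(d, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  d <- as_data_matrix(d)
  n <- nrow(d)
  if (n < 4L)
    stop("need at least 4 observations to attach p-values (n - 2 >= 2)")
  sds <- apply(d, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(d)[sds == 0], collapse = ", "))
  r <- stats::cor(d, method = method)
  # numerical guard: cor() can stray from exact symmetry by rounding
  r <- (r + t(r)) / 2
  diag(r) <- 1
  new_corr_matrix(r, n, method)
}

# Shared constructor: p-values always derive from (r, n) by the t transform,
# so matrix input (read_corr) and data input take the same path.
new_corr_matrix <- function(r, n, method) {
  p <- r_to_p(r, n)
  structure(
    list(r = r, p = p, n = as.integer(n), method = method,
         var_names = colnames(r)),
    class = "corr_matrix"
  )
}

r_to_p <- function(r, n) {
  rr <- pmin(pmax(r, -1), 1)
  p <- matrix(0, nrow(rr), ncol(rr), dimnames = dimnames(rr))
  off <- row(rr) != col(rr)
  t_stat <- rr[off] * sqrt((n - 2) / pmax(1 - rr[off]^2, 0))
  # |r| = 1 gives t = Inf and p = 0 via pt()
  p[off] <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  p
}

#' Mask of significant correlations
#'
#' @param c a [`corr_matrix`][correlation_matrix].
#' @param alpha significance level in (0, 1]; a pair is flagged when its
#'   two-sided p-value is at most `alpha`.
#' @return Logical symmetric matrix, `TRUE` for significant off-diagonal
#'   pairs, `FALSE` on the diagonal.
#' @export
significant_mask <- function(c, alpha) {
  stopifnot(inherits(c, "corr_matrix"),
            is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1)
  m <- c$p <= alpha
  diag(m) <- FALSE
  m
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat(sprintf("corr_matrix: %d variables, n = %d, method = %s\n",
              length(x$var_names), x$n, x$method))
  cat("variables:", paste(x$var_names, collapse = ", "), "\n")
  off <- abs(x$r[upper.tri(x$r)])
  cat(sprintf("|r| off-diagonal: min %.3f, median %.3f, max %.3f\n",
              min(off), stats::median(off), max(off)))
  invisible(x)
}

# Coerce raw data input; enforces the DataMatrix invariants.
as_data_matrix <- function(d) {
  if (is.data.frame(d)) d <- as.matrix(d)
  if (!is.matrix(d) || !is.numeric(d))
    stop("data must be a numeric matrix or data frame")
  if (is.null(colnames(d)))
    stop("data must have column names")
  if (anyDuplicated(colnames(d)))
    stop("duplicate variable names")
  if (ncol(d) < 2L)
    stop("need at least 2 variables")
  if (any(!is.finite(d)))
    stop("data contain non-finite values; apply a missing-data policy first")
  d
}
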