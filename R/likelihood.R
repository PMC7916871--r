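#' Degrees of freedom of the chain likelihood-ratio test
#'
#' A chain of `k` members restricts the \eqn{\binom{k}{2}} pairwise
#' dependencies among its members to the `k - 1` adjacent pairs; the number
#' of restrictions, \eqn{\binom{k}{2} - (k-1) = (k-1)(k-2)/2}, is the
#' degrees of freedom of the asymptotic chi-squared test.
#'
#' @param k chain length (number of members), at least 3.
#' @return Integer degrees of freedom.
#' @export
chain_df <- function(k) {
  stopifnot(is.numeric(k), k == as.integer(k), k >= 3)
  as.integer((k - 1) * (k - 2) / 2)
}

#' Right-tail chi-squared probability
#'
#' @param chi2 non-negative test statistic.
#' @param df positive degrees of freedom.
#' @return Upper-tail probability \eqn{P(X \ge \chi^2)} for
#'   \eqn{X \sim \chi^2_{df}}.
#' @export
chi2_right_tail <- function(chi2, df) {
  stopifnot(all(chi2 >= 0), all(df >= 1))
  stats::pchisq(chi2, df = df, lower.tail = FALSE)
}

#' Likelihood-ratio test of a chain's dependence structure
#'
#' Tests the restricted dependence structure implied by an association
#' chain — each member conditionally normal given only its predecessor, a
#' first-order Gaussian Markov chain, so all non-adjacent partial
#' correlations are zero — against the unrestricted multivariate normal
#' with free correlation among the `k` members. Both likelihoods are
#' evaluated at their maximum on the standardized (correlation) scale,
#' where means and variances cancel. The chain model is decomposable, so
#' the deviance has the closed form
#' \deqn{\chi^2 = n \left( \sum_{(a,b)\ adjacent} \log(1 - r_{ab}^2)
#'   - \log \det R \right)}
#' with \eqn{R} the sample correlation submatrix of the chain members. A
#' small p-value means the chain fails to capture the dependencies among
#' its members; a large one means the first-order chain suffices.
#'
#' @param chain character vector of chain member names, length at least 3.
#' @param c a [`corr_matrix`][correlation_matrix] holding `r` and `n`.
#' @return List of class `lr_test`: `chain`, `loglik_unrestricted`,
#'   `loglik_restricted`, `chi2`, `df`, `p_value`.
#' @export
chain_lr_test <- function(chain, c) {
  stopifnot(inherits(c, "corr_matrix"))
  k <- length(chain)
  if (k < 3L) stop("chain must have at least 3 members")
  if (!all(chain %in% c$var_names))
    stop("chain members not all present in correlation matrix")
  n <- c$n
  if (n <= k) stop("sample size must exceed chain length")
  R <- c$r[chain, chain]
  detR <- det(R)
  if (detR <= .Machine$double.eps)
    stop("singular correlation submatrix for chain ",
         paste(chain, collapse = "-"))
  adj <- cbind(chain[-k], chain[-1L])
  r_adj <- c$r[adj]
  if (any(abs(r_adj) >= 1))
    stop("degenerate chain: an adjacent pair is perfectly correlated")
  # maximized log-likelihoods on the standardized scale (per the profile
  # over means/variances); constants kept so the individual logliks are
  # honest, they cancel in the difference
  const <- -n / 2 * (k * log(2 * pi) + k)
  ll_unres <- const - n / 2 * log(detR)
  ll_res <- const - n / 2 * sum(log(1 - r_adj^2))
  chi2 <- max(0, 2 * (ll_unres - ll_res))
  df <- chain_df(k)
  structure(list(chain = chain,
                 loglik_unrestricted = ll_unres,
                 loglik_restricted = ll_res,
                 chi2 = chi2, df = df,
                 p_value = chi2_right_tail(chi2, df)),
            class = "lr_test")
}

#' @export
print.lr_test <- function(x, ...) {
  cat(sprintf("chain %s: chi2 = %.3f, df = %d, p = %.3f\n",
              paste(x$chain, collapse = "-"), x$chi2, x$df, x$p_value))
  invisible(x)
}

# LR tests for a list of chains, as the tabular export (id, members, df,
# chi2, p) used by snha() and the CLI.
lr_table <- function(chains, c) {
  rows <- lapply(seq_along(chains), function(i) {
    t <- chain_lr_test(chains[[i]], c)
    data.frame(chain = i,
               members = paste(t$chain, collapse = "-"),
               df = t$df, chi2 = t$chi2, p_value = t$p_value,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0)
    return(data.frame(chain = integer(), members = character(),
                      df = integer(), chi2 = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Number of candidate chains
#'
#' How many distinct candidate chains of `k` serial correlation
#' coefficients (ordered selections of `k + 1` variables, a sequence and
#' its reversal counted once) can be formed from `I` variables. For
#' `k = 1` this is simply the number of correlation coefficients,
#' \eqn{\binom{I}{2}}.
#'
#' @param I number of variables, at least 2.
#' @param k number of serial correlation coefficients, `1 <= k <= I - 1`.
#' @return Count of reversal-distinct ordered selections:
#'   \eqn{I!/(I-k-1)!/2} for `k >= 2`, \eqn{\binom{I}{2}} for `k = 1`.
#' @export
count_candidate_chains <- function(I, k) {
  stopifnot(is.numeric(I), I >= 2, I == as.integer(I),
            is.numeric(k), k == as.integer(k))
  if (k < 1 || k > I - 1) stop("k must lie in [1, I - 1]")
  if (k == 1) return(choose(I, 2))
  prod(seq(I, I - k, by = -1)) / 2
}
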