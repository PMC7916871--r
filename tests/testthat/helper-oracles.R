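# Independent oracles, deliberately implemented by different routes than the
# package functions they check.

# Brute-force association-chain enumerator: generates every ordered sequence
# of 3+ variables (no greedy shortcuts) and keeps those whose descending-|r|
# property holds step by step from both ends, including maximality at both
# endpoints. Ties resolved toward the earlier variable in matrix order, as
# in the package contract.
oracle_chains <- function(cm, alpha = 0.05, abs_threshold = 0.1) {
  vn <- cm$var_names
  rho <- abs(cm$r)
  p <- cm$p
  step_ok <- function(cur, nxt, visited) {
    rest <- setdiff(vn, visited)
    best <- rest[which.max(rho[cur, rest])]
    identical(best, nxt) &&
      rho[cur, nxt] >= abs_threshold && p[cur, nxt] <= alpha
  }
  stop_ok <- function(last, visited) {
    rest <- setdiff(vn, visited)
    if (length(rest) == 0L) return(TRUE)
    best <- rest[which.max(rho[last, rest])]
    rho[last, best] < abs_threshold || p[last, best] > alpha
  }
  valid_directed <- function(s) {
    k <- length(s)
    for (t in seq_len(k - 1L))
      if (!step_ok(s[t], s[t + 1L], s[seq_len(t)])) return(FALSE)
    stop_ok(s[k], s)
  }
  found <- list()
  gen <- function(prefix) {
    if (length(prefix) >= 3L &&
        valid_directed(prefix) && valid_directed(rev(prefix))) {
      can <- if (prefix[1] > prefix[length(prefix)]) rev(prefix) else prefix
      found[[length(found) + 1L]] <<- can
    }
    for (v in setdiff(vn, prefix)) gen(c(prefix, v))
  }
  for (v in vn) gen(v)
  unique(found)
}

chain_keys <- function(chains)
  sort(vapply(chains, paste, "", collapse = "-"))

# Numeric restricted-MLE oracle for the chain likelihood-ratio test:
# parameterizes the first-order Gaussian chain by its k-1 adjacent
# correlations (tanh-transformed to stay in (-1,1)), maximizes the
# multivariate-normal log-likelihood of the sample correlation matrix by
# quasi-Newton optimization, and returns the deviance against the
# unrestricted model.
oracle_chain_chi2 <- function(R, n) {
  k <- nrow(R)
  markov_corr <- function(theta) {
    C <- diag(k)
    for (i in seq_len(k - 1L))
      for (j in seq(i + 1L, k))
        C[i, j] <- C[j, i] <- prod(theta[i:(j - 1L)])
    C
  }
  negll <- function(eta) {
    C <- markov_corr(tanh(eta))
    d <- det(C)
    if (d <= 1e-12) return(1e10)
    n / 2 * (log(d) + sum(diag(solve(C, R))))
  }
  opt <- optim(rep(0, k - 1L), negll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  ll_res <- -opt$value
  ll_unres <- -n / 2 * (log(det(R)) + k)
  2 * (ll_unres - ll_res)
}

# Closed-form covariance of a planted first-order path computed by forward
# recursion (independent of the package's matrix-inverse route):
# var(X1) = 1, var(Xj) = coef^2 var(X_{j-1}) + noise_sd^2,
# cov(Xi, Xj) = coef^{j-i} var(Xi) for i < j.
oracle_path_cov <- function(k, coef, noise_sd) {
  v <- numeric(k)
  v[1] <- 1
  for (j in seq(2, k)) v[j] <- coef^2 * v[j - 1] + noise_sd^2
  S <- diag(v)
  for (i in seq_len(k - 1L))
    for (j in seq(i + 1L, k))
      S[i, j] <- S[j, i] <- coef^(j - i) * v[i]
  S
}
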