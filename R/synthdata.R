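#' Scramble a data table column-wise
#'
#' Independently permutes the values within each column, destroying every
#' cross-column linkage while leaving each column's marginal distribution
#' (as a multiset) untouched. This is the permutation null used in the
#' spurious-edge experiment.
#'
#' @param d numeric data matrix/data frame with named columns.
#' @param seed integer seed; output is reproducible given the seed.
#' @return Matrix of the same shape and column names.
#' @export
scramble <- function(d, seed) {
  d <- as_data_matrix(d)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  set.seed(as.integer(seed))
  apply(d, 2L, sample)
}

#' Independent normal data matched to a template
#'
#' Draws each column as iid normal with the template column's sample mean
#' and variance, columns mutually independent: null data with the same
#' shape and first two marginal moments as the template but zero
#' population cross-correlation.
#'
#' @inheritParams scramble
#' @return Matrix of the same shape and column names.
#' @export
random_normal_like <- function(d, seed) {
  d <- as_data_matrix(d)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  sds <- apply(d, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(d)[sds == 0], collapse = ", "))
  mus <- colMeans(d)
  set.seed(as.integer(seed))
  out <- vapply(seq_len(ncol(d)),
                function(j) stats::rnorm(nrow(d), mus[j], sds[j]),
                numeric(nrow(d)))
  colnames(out) <- colnames(d)
  out
}

#' Define a planted linear-Gaussian dependence structure
#'
#' Ground truth for recovery tests: a directed acyclic graph over named
#' variables where each root is standard normal and each child is the
#' coefficient-weighted sum of its parents plus independent normal noise.
#'
#' @param edges data frame with columns `from`, `to`, `coef` (may have zero
#'   rows for a fully independent design).
#' @param var_names all variable names (isolated variables allowed).
#' @param noise_sd standard deviation of the child noise terms.
#' @param n_obs number of observations to simulate.
#' @param seed integer seed.
#' @return List of class `planted_structure`.
#' @seealso [planted_path()] for the Markov-chain special case,
#'   [generate_planted()], [implied_covariance()].
#' @export
planted_structure <- function(edges, var_names, noise_sd = 0.5,
                              n_obs = 100, seed = 1) {
  if (nrow(edges) > 0) {
    stopifnot(all(c("from", "to", "coef") %in% names(edges)),
              all(edges$from %in% var_names), all(edges$to %in% var_names),
              all(is.finite(edges$coef)))
  }
  stopifnot(noise_sd > 0, n_obs >= 1, anyDuplicated(var_names) == 0)
  ps <- structure(list(edges = edges, var_names = var_names,
                       noise_sd = noise_sd, n_obs = as.integer(n_obs),
                       seed = as.integer(seed)),
                  class = "planted_structure")
  topological_order(ps)  # errors on cycles
  ps
}

#' Markov-path planted structure
#'
#' Convenience wrapper for the most used design: a first-order chain
#' `X1 -> X2 -> ... -> Xk`.
#'
#' @param k number of variables on the path.
#' @param coef common edge coefficient (default 1, a strong monotone
#'   effect).
#' @inheritParams planted_structure
#' @export
planted_path <- function(k, coef = 1, noise_sd = 0.5, n_obs = 500, seed = 1) {
  stopifnot(k >= 2)
  vn <- paste0("X", seq_len(k))
  planted_structure(
    data.frame(from = vn[-k], to = vn[-1L], coef = coef,
               stringsAsFactors = FALSE),
    var_names = vn, noise_sd = noise_sd, n_obs = n_obs, seed = seed)
}

topological_order <- function(ps) {
  vn <- ps$var_names
  parents <- split(ps$edges$from, factor(ps$edges$to, levels = vn))
  placed <- character()
  remaining <- vn
  while (length(remaining) > 0) {
    ready <- remaining[vapply(remaining, function(v)
      all(parents[[v]] %in% placed), logical(1))]
    if (length(ready) == 0) stop("planted structure contains a cycle")
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  placed
}

#' Simulate data from a planted structure
#'
#' Simulates in topological order: roots iid standard normal, each child
#' the weighted sum of its parents plus `noise_sd` normal noise.
#' Deterministic given the structure's seed.
#'
#' @param ps a [planted_structure()].
#' @return Numeric matrix `n_obs` by `length(var_names)`, columns in
#'   `var_names` order.
#' @export
generate_planted <- function(ps) {
  stopifnot(inherits(ps, "planted_structure"))
  ord <- topological_order(ps)
  set.seed(ps$seed)
  n <- ps$n_obs
  out <- matrix(0, n, length(ps$var_names),
                dimnames = list(NULL, ps$var_names))
  for (v in ord) {
    sel <- ps$edges$to == v
    if (!any(sel)) {
      out[, v] <- stats::rnorm(n)
    } else {
      mu <- out[, ps$edges$from[sel], drop = FALSE] %*% ps$edges$coef[sel]
      out[, v] <- mu + stats::rnorm(n, sd = ps$noise_sd)
    }
  }
  out
}

#' Implied covariance of a planted structure
#'
#' Closed-form population covariance of the linear-Gaussian system:
#' \eqn{\Sigma = (I - B)^{-1} D (I - B)^{-T}} where `B[child, parent]`
#' holds the coefficients and `D` the noise variances (1 for roots,
#' `noise_sd^2` for children).
#'
#' @param ps a [planted_structure()].
#' @return Covariance matrix in `var_names` order.
#' @export
implied_covariance <- function(ps) {
  stopifnot(inherits(ps, "planted_structure"))
  vn <- ps$var_names
  I_ <- diag(length(vn))
  dimnames(I_) <- list(vn, vn)
  B <- I_ * 0
  if (nrow(ps$edges) > 0)
    B[cbind(ps$edges$to, ps$edges$from)] <- ps$edges$coef
  d <- ifelse(vn %in% ps$edges$to, ps$noise_sd^2, 1)
  Ainv <- solve(I_ - B)
  Ainv %*% diag(d, length(vn)) %*% t(Ainv)
}
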