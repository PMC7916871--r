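# Build a corr_matrix directly from a correlation matrix (tests that need
# exact hand-picked coefficients).
cm_from_r <- function(r, n = 100, method = "pearson") {
  stopifnot(isSymmetric(r), !is.null(colnames(r)))
  snha:::new_corr_matrix(r, n, method)
}

# The hand-traceable 4-variable example: greedy walk from A is A,B,C,D and
# the reverse walk from D (DC = .5 > DB = .4 > DA = .3) reproduces it.
abcd_r <- function() {
  r <- diag(4)
  dimnames(r) <- list(LETTERS[1:4], LETTERS[1:4])
  r["A","B"] <- .9; r["B","C"] <- .7; r["C","D"] <- .5
  r["A","C"] <- .6; r["A","D"] <- .3; r["B","D"] <- .4
  r[lower.tri(r)] <- t(r)[lower.tri(r)]
  r
}

# Random correlation matrix via sample correlation of Gaussian data: always
# valid, carries an honest n for the p-values.
random_cm <- function(I, n = 20, method = "pearson") {
  d <- matrix(rnorm(n * I), n, I,
              dimnames = list(NULL, LETTERS[seq_len(I)]))
  correlation_matrix(d, method)
}

# 33 x 10 template with decathlon-like block structure, used by the null
# falseness experiment (the nulls destroy whatever structure it has; only
# shape and marginal moments matter).
null_template <- function(seed = 99, n_obs = 33) {
  vn <- c("v100", "long", "shot", "high", "v400", "v110",
          "disq", "pole", "jave", "v1500")
  edges <- data.frame(
    from = c("v100", "long", "v100", "v400", "shot", "disq", "shot",
             "v110", "pole"),
    to   = c("long", "high", "v110", "v1500", "disq", "jave", "pole",
             "pole", "jave"),
    coef = c(0.9, 0.7, 0.8, 0.8, 0.9, 0.6, 0.5, 0.5, 0.3),
    stringsAsFactors = FALSE)
  generate_planted(planted_structure(edges, vn, noise_sd = 0.8,
                                     n_obs = n_obs, seed = seed))
}

write_temp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
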