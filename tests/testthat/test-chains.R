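# 4-variable matrix where the reverse walk from D takes D -> B first
# (|r_DB| = .75 > |r_DC| = .7), so the forward walk A,B,C,D is not an
# association chain.
jump_r <- function() {
  r <- diag(4); dimnames(r) <- list(LETTERS[1:4], LETTERS[1:4])
  r["A","B"] <- .9; r["B","C"] <- .8; r["C","D"] <- .7
  r["B","D"] <- .75; r["A","C"] <- .2; r["A","D"] <- .1
  r[lower.tri(r)] <- t(r)[lower.tri(r)]
  r
}

test_that("greedy growth follows descending |r| over unvisited variables", {
  cm <- cm_from_r(abcd_r(), n = 100)
  expect_equal(grow_sequence(cm, "A"), c("A", "B", "C", "D"))
  # the same trace, confirmed by the enumeration oracle
  expect_equal(chain_keys(oracle_chains(cm)), "A-B-C-D")

  ident <- diag(4); dimnames(ident) <- list(LETTERS[1:4], LETTERS[1:4])
  cm0 <- cm_from_r(ident, 50)
  expect_equal(grow_sequence(cm0, "B"), "B")

  # growth stops at the absolute-correlation floor even when significant
  expect_equal(grow_sequence(cm, "A", abs_threshold = 0.6), c("A", "B", "C"))
  # and at the significance threshold even when |r| is above the floor
  cmw <- cm_from_r(abcd_r(), n = 4)   # r = .9 at n = 4: p ~ 0.10
  expect_gt(cmw$p["A", "B"], 0.05)
  expect_equal(grow_sequence(cmw, "A"), "A")
})

test_that("reversibility demands the exact reversed walk", {
  cm <- cm_from_r(abcd_r(), n = 100)
  expect_true(is_reversible(cm, c("A", "B", "C", "D")))
  # a pair with no admissible continuation is order-symmetric
  r <- diag(3); dimnames(r) <- list(c("X","Y","Z"), c("X","Y","Z"))
  r["X","Y"] <- r["Y","X"] <- .8
  r["X","Z"] <- r["Z","X"] <- .05; r["Y","Z"] <- r["Z","Y"] <- .03
  expect_true(is_reversible(cm_from_r(r, 100), c("X", "Y")))

  cmj <- cm_from_r(jump_r(), n = 100)
  expect_equal(grow_sequence(cmj, "A"), c("A", "B", "C", "D"))
  expect_false(is_reversible(cmj, c("A", "B", "C", "D")))
  expect_equal(find_chains(cmj), list())  # discarded whole, not trimmed
})

test_that("find_chains keeps reversible length-3+ walks, deduplicated", {
  cm <- cm_from_r(abcd_r(), n = 100)
  ch <- find_chains(cm)
  expect_equal(ch, list(c("A", "B", "C", "D")))  # found from A and from D

  ident <- diag(5); dimnames(ident) <- list(LETTERS[1:5], LETTERS[1:5])
  expect_equal(find_chains(cm_from_r(ident, 50)), list())
})

test_that("a planted Markov path is recovered as a single chain", {
  d <- generate_planted(planted_path(5, n_obs = 500, seed = 3))
  fit <- snha(d, method = "pearson")
  expect_equal(fit$graph$chains, list(paste0("X", 1:5)))
  expect_equal(paste(fit$graph$edges$from, fit$graph$edges$to),
               c("X1 X2", "X2 X3", "X3 X4", "X4 X5"))
  expect_equal(fit$graph$edges$sign, rep(1L, 4))
})

test_that("merge_chains unions consecutive pairs and tracks provenance", {
  r <- diag(4); dimnames(r) <- list(LETTERS[1:4], LETTERS[1:4])
  r["A","B"] <- r["B","A"] <- .8; r["B","C"] <- r["C","B"] <- -.7
  r["C","D"] <- r["D","C"] <- .6
  cm <- cm_from_r(r, 100)
  g <- merge_chains(list(c("A","B","C"), c("B","C","D")), cm)
  expect_equal(nrow(g$edges), 3L)
  expect_equal(g$provenance[["B|C"]], c(1L, 2L))
  expect_equal(g$provenance[["A|B"]], 1L)
  expect_equal(g$edges$sign[g$edges$from == "B"], -1L)

  g0 <- merge_chains(list(), cm)
  expect_equal(length(g0$nodes), 4L)
  expect_equal(n_edges(g0), 0L)
  expect_error(merge_chains(list(c("A", "Z")), cm), "unknown variable")
})

test_that("every output chain is reversible and every edge passes thresholds", {
  set.seed(21)
  for (i in 1:25) {
    cm <- random_cm(sample(4:6, 1), n = 12)
    ch <- find_chains(cm)
    for (s in ch) expect_true(is_reversible(cm, s))
    g <- merge_chains(ch, cm)
    if (nrow(g$edges) > 0) {
      expect_true(all(abs(g$edges$weight) >= 0.1))
      expect_true(all(cm$p[cbind(g$edges$from, g$edges$to)] <= 0.05))
    }
  }
})

test_that("results are equivariant under column permutation", {
  set.seed(22)
  d <- matrix(rnorm(15 * 5), 15, 5, dimnames = list(NULL, LETTERS[1:5]))
  perm <- c(4, 2, 5, 1, 3)
  k1 <- chain_keys(find_chains(correlation_matrix(d, "pearson")))
  k2 <- chain_keys(find_chains(correlation_matrix(d[, perm], "pearson")))
  expect_equal(k1, k2)
})

test_that("ordering-consistency filter drops the shorter conflicting chain", {
  # two shared members can always be reconciled by flipping one chain, so a
  # genuine conflict needs three or more shared members in scrambled order
  chains <- list(c("A", "B", "C", "D", "E"),  # shared order C, D, E
                 c("F", "C", "E", "D"))       # shared order C, E, D
  kept <- snha:::filter_consistent(chains)
  expect_equal(kept, chains[1])  # the shorter conflicting chain is dropped
  # shared order agreeing up to reversal is compatible
  chains2 <- list(c("A", "B", "C", "D"), c("D", "C", "B"))
  expect_equal(snha:::filter_consistent(chains2), chains2)
  # equal length: the lexicographically larger canonical form loses
  chains3 <- list(c("A", "B", "C", "D"), c("C", "D", "B", "E"))
  expect_equal(snha:::filter_consistent(chains3), chains3[1])
})

test_that("snha works from an aggregate correlation matrix alone", {
  cm <- cm_from_r(abcd_r(), n = 100)
  fit <- snha(cm)
  expect_equal(n_edges(fit$graph), 3L)
  expect_equal(nrow(fit$lr), 1L)
  expect_equal(fit$lr$df, 3L)
  expect_true(fit$lr$chi2 >= 0)
})
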