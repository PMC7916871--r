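test_that("threshold network applies strict |r| cutoffs, optional alpha", {
  cm <- cm_from_r(abcd_r(), n = 100)
  g3 <- threshold_network(cm, 0.3)
  expect_equal(n_edges(g3), 5L)           # AD = .3 excluded: strict >
  expect_false("A|D" %in% paste(g3$edges$from, g3$edges$to, sep = "|"))
  g5 <- threshold_network(cm, 0.5)
  expect_equal(n_edges(g5), 3L)  # CD = .5 excluded: strict > again
  # monotone: higher threshold gives a subset
  k5 <- paste(g5$edges$from, g5$edges$to)
  k3 <- paste(g3$edges$from, g3$edges$to)
  expect_true(all(k5 %in% k3))
  expect_equal(n_edges(threshold_network(cm, 1 - 1e-9)), 0L)
  # alpha filter removes weakly supported pairs at small n
  cm_small <- cm_from_r(abcd_r(), n = 10)
  expect_lt(n_edges(threshold_network(cm_small, 0.3, alpha = 0.05)),
            n_edges(threshold_network(cm_small, 0.3)))
})

test_that("forward selection picks an exact copy first, stops when told", {
  set.seed(51)
  d <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, LETTERS[1:4]))
  d[, "B"] <- d[, "A"]  + rnorm(40, sd = 1e-8)  # B is a copy of A
  g <- forward_lm_network(d, r2_min = 0.01)
  expect_true("A|B" %in% paste(g$edges$from, g$edges$to, sep = "|"))
  # an unattainable gain requirement empties the graph on noisy data
  dn <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, LETTERS[1:4]))
  expect_equal(n_edges(forward_lm_network(dn, r2_min = 1.0)), 0L)
})

test_that("forward selection agrees with a step-by-step lm/anova trace", {
  set.seed(52)
  d <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(NULL, LETTERS[1:5]))
  d[, "C"] <- d[, "A"] + 0.7 * d[, "B"] + rnorm(30, sd = .5)
  g <- forward_lm_network(d, r2_min = 0.01, alpha = 0.05)
  # oracle for target C: classic forward selection with anova partial F
  df <- as.data.frame(d)
  selected <- character(); pool <- setdiff(colnames(d), "C")
  fit <- lm(C ~ 1, df)
  repeat {
    if (length(pool) == 0) break
    r2s <- sapply(pool, function(p) summary(
      lm(reformulate(c(selected, p), "C"), df))$r.squared)
    best <- names(which.max(r2s))
    gain <- r2s[best] - summary(fit)$r.squared
    cand <- lm(reformulate(c(selected, best), "C"), df)
    pF <- anova(fit, cand)[2, "Pr(>F)"]
    if (gain < 0.01 || pF > 0.05) break
    selected <- c(selected, best); pool <- setdiff(pool, best); fit <- cand
  }
  got_C <- sort(c(g$edges$to[g$edges$from == "C"],
                  g$edges$from[g$edges$to == "C"]))
  # edges at C from the union over all targets must include C's own
  # selections; and C's own selections must match the oracle
  expect_true(all(sort(selected) %in% got_C))
  expect_true(all(c("A", "B") %in% got_C))
})

test_that("the stricter R-squared threshold always selects a subset", {
  # the forward-selection path does not depend on r2_min, only the stopping
  # point does, so lm 0.10 edges nest inside lm 0.01 edges replicate by
  # replicate (the edge-count ordering seen on null data)
  set.seed(53)
  for (i in 1:8) {
    d <- matrix(rnorm(33 * 8), 33, 8, dimnames = list(NULL, LETTERS[1:8]))
    g01 <- forward_lm_network(d, r2_min = 0.01, alpha = 0.05)
    g10 <- forward_lm_network(d, r2_min = 0.10, alpha = 0.05)
    k01 <- paste(g01$edges$from, g01$edges$to)
    k10 <- paste(g10$edges$from, g10$edges$to)
    expect_true(all(k10 %in% k01))
  }
})

test_that("count_spurious_edges tallies and tests builder pairs", {
  set.seed(54)
  template <- null_template()
  reps <- lapply(1:10, function(r) scramble(template, 100 + r))
  builders <- list(
    empty = function(d) merge_chains(list(),
                                     correlation_matrix(d, "pearson")),
    cor0.1 = function(d) threshold_network(
      correlation_matrix(d, "pearson"), 0.1))
  cmp <- count_spurious_edges(builders, reps)
  expect_equal(sort(unique(cmp$counts$method)), c("cor0.1", "empty"))
  expect_true(all(cmp$counts$n_edges[cmp$counts$method == "empty"] == 0))
  expect_true(all(cmp$counts$n_edges >= 0))
  expect_equal(nrow(cmp$tests), 1L)
  expect_true(all(cmp$tests$p_holm >= cmp$tests$p_value - 1e-12))
  expect_warning(count_spurious_edges(builders, reps[1:2]), "underpowered")
  expect_error(count_spurious_edges(builders, reps[1]), "at least 2")
})

test_that("SNHA edges are always among the significant |r| >= 0.1 pairs", {
  set.seed(55)
  for (i in 1:8) {
    d <- matrix(rnorm(33 * 7), 33, 7, dimnames = list(NULL, LETTERS[1:7]))
    cm <- correlation_matrix(d, "pearson")
    fit <- snha(cm)
    thr <- threshold_network(cm, 0.0999999, alpha = 0.05)
    ks <- paste(fit$graph$edges$from, fit$graph$edges$to)
    kt <- paste(thr$edges$from, thr$edges$to)
    expect_true(all(ks %in% kt))
  }
})
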