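# Population statistics: sign test, contrasts, counts, scatter statistics
# and the within-subject ANOVA.

test_that("the continuity-corrected sign test reproduces known values", {
  st <- sign_test(k = 38, n = 43)
  expect_equal(round(st$Z, 2), 4.88)
  # equal split: Z = 0, p = 1
  st0 <- sign_test(c(rep(1, 5), rep(-1, 5)))
  expect_equal(st0$Z, 0)
  expect_equal(st0$p, 1)
  # all-positive small sample: exact binomial p = 2 * 0.5^10
  st10 <- sign_test(k = 10, n = 10)
  expect_equal(st10$p_exact, 2 * 0.5^10)
  # ties are dropped; all ties is an error
  expect_equal(sign_test(c(0, 0, 1, 1, 1, -1))$n, 4)
  expect_error(sign_test(c(0, 0, 0)), "no non-tied")
})

test_that("sign-test decisions agree with the exact binomial away from the boundary", {
  # brute-force oracle over all n <= 25, k = 0..n at alpha = 0.05;
  # disagreements may occur only where the exact p sits near the threshold
  for (n in 1:25) for (k in 0:n) {
    z_dec <- sign_test(k = k, n = n)$p < 0.05
    p_ex <- binom.test(k, n)$p.value
    if (z_dec != (p_ex < 0.05))
      expect_true(p_ex > 0.02 && p_ex < 0.12,
                  label = sprintf("boundary case n=%d k=%d p=%.4f",
                                  n, k, p_ex))
  }
})

test_that("per-unit contrasts separate selective units and stay calibrated", {
  g <- generate_session(unblocking_config(
    seed = 301L, n_trials_per_novel_odor = 20L, n_initial_trials = 20L,
    class_counts = c(predictive_number = 1L), odor_response_amp = 15,
    noise_sd = 0, learning_rate = 1))
  r <- per_unit_contrast(g$session$units[[1]], g$session, "number",
                         "blocked")
  expect_lt(r$p, 0.05)
  expect_gt(r$statistic, 0)
  # null calibration across 200 independent null units
  gn <- generate_session(null_config(302L, n_units = 200L, n_trials = 15L))
  ps <- vapply(names(gn$session$units), function(uid)
    per_unit_contrast(gn$session$units[[uid]], gn$session, "number",
                      "blocked")$p, numeric(1))
  rej <- mean(ps < 0.05)
  expect_lt(abs(rej - 0.05), 1.96 * sqrt(0.05 * 0.95 / 200) + 0.01)
})

test_that("signed square root transforms for display only", {
  expect_equal(signed_sqrt(4), 2)
  expect_equal(signed_sqrt(-9), -3)
  expect_equal(signed_sqrt(0), 0)
})

test_that("count comparison matches the closed form", {
  eq <- count_comparison(30, 30)
  expect_equal(eq$chisq, 0)
  # closed-form oracle for (31, 37): sum (O - E)^2 / E with E = 34
  o <- c(31, 37); e <- 34
  expect_equal(count_comparison(31, 37)$chisq, sum((o - e)^2 / e))
  expect_equal(count_comparison(31, 37)$chisq, 18 / 34)
  expect_equal(count_comparison(31, 37)$chisq_yates,
               sum((abs(o - e) - 0.5)^2 / e))
  expect_error(count_comparison(0, 0), "zero")
})

test_that("scatter statistics recover known relationships", {
  x <- c(1, 2, 3, 4, 5)
  st <- suppressWarnings(pairwise_scatter_stats(x, x))  # perfect fit
  expect_equal(st$r2, 1)
  expect_equal(st$diff, rep(0, 5))
  # independent null draws: mean R-squared is about 1/(n-1)
  set.seed(12)
  r2s <- replicate(500, pairwise_scatter_stats(rnorm(40), rnorm(40))$r2)
  expect_lt(abs(mean(r2s) - 1 / 39), 0.01)
  expect_error(pairwise_scatter_stats(1:2, 1:2), "n >= 3")
})

test_that("rm_anova detects within-subject effects and rejects degeneracies", {
  make_pop <- function(odor_effect = 0, seed = 1) {
    set.seed(seed)
    d <- expand.grid(unit = paste0("u", 1:12),
                     odor = TRIAL_TYPES, half = c("first", "second"),
                     stringsAsFactors = FALSE)
    d$value <- rnorm(nrow(d)) + odor_effect * (d$odor %in%
                                                 c("number", "flavor"))
    d
  }
  # odor main effect is detected; factors come back with conventional dfs
  an <- rm_anova(make_pop(odor_effect = 3), factors = c("half", "odor"))
  row_odor <- an[an$test == "rm_anova:odor", ]
  expect_lt(row_odor$p, 0.01)
  expect_equal(row_odor$df1, 3)
  expect_equal(row_odor$df2, 33)    # (4-1) x (12-1)
  d1 <- make_pop()
  expect_error(rm_anova(d1[d1$unit == "u1", ], factors = c("half", "odor")),
               "at least 2")
  d0 <- make_pop(); d0$value <- 1   # no variance anywhere
  expect_error(rm_anova(d0, factors = c("half", "odor")), "degeneracy")
})

test_that("null rm_anova interaction p values are calibrated", {
  set.seed(33)
  rej <- replicate(200, {
    d <- expand.grid(unit = paste0("u", 1:10),
                     odor = TRIAL_TYPES, half = c("first", "second"),
                     stringsAsFactors = FALSE)
    d$value <- rnorm(nrow(d))
    an <- rm_anova(d, factors = c("half", "odor"))
    an[an$test == "rm_anova:half:odor", "p"] < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 1.96 * sqrt(0.05 * 0.95 / 200) + 0.01)
})
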