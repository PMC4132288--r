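# Selectivity indices, outlier exclusion and the cue-outcome regressions.

test_that("selectivity index is target minus mean of the other three", {
  r <- c(initial = 1, blocked = 2, number = 3, flavor = 5)
  expect_equal(selectivity_index(r, "flavor"), 5 - 2)
  expect_equal(selectivity_index(c(initial = 4, blocked = 4, number = 4,
                                   flavor = 4), "number"), 0)
  # the four indices of a unit sum to zero (algebraic identity)
  set.seed(2)
  for (i in 1:20) {
    r <- setNames(rnorm(4, 0, 10), TRIAL_TYPES)
    s <- sum(vapply(TRIAL_TYPES, function(tt) selectivity_index(r, tt),
                    numeric(1)))
    expect_equal(s, 0, tolerance = 1e-12)
  }
  expect_error(selectivity_index(r[-1], "flavor"), "TRIAL_TYPES")
})

test_that("sum-to-zero holds for every generated unit and both domains", {
  g <- generate_session(small_config(501L))
  for (uid in names(g$session$units)[1:6]) {
    cr <- unit_condition_rates(g$session$units[[uid]], g$session)
    for (dom in c("odor", "outcome")) {
      s <- sum(vapply(TRIAL_TYPES, function(tt)
        selectivity_index(cr[[dom]], tt), numeric(1)))
      expect_equal(s, 0, tolerance = 1e-10)
    }
  }
})

test_that("outlier exclusion is one-sided at mean + 3 SD on the full set", {
  # a single extreme value in a tight population; mean and SD are computed
  # on the full set, so n must be large enough for the point to sit beyond
  # 3 SD (with n = 4 the largest attainable z is (n-1)/sqrt(n) ~ 1.5)
  v <- c(seq(0.9, 1.1, length.out = 30), 50)
  keep <- exclude_outliers(v)
  expect_equal(keep, v <= mean(v) + 3 * sd(v))   # direct oracle
  expect_equal(which(!keep), 31L)
  expect_true(all(exclude_outliers(rep(2, 5))))
  # a symmetric low outlier is retained under the one-sided rule
  vlow <- c(seq(0.9, 1.1, length.out = 30), -50)
  expect_true(all(exclude_outliers(vlow)))
  expect_false(all(exclude_outliers(vlow, two_sided = TRUE)))
})

test_that("exclusion is idempotent once the outlier is removed", {
  set.seed(9)
  base <- runif(100, -1, 1)           # bounded: no 3-SD points
  v <- c(base, 40)
  keep1 <- exclude_outliers(v)
  expect_equal(sum(!keep1), 1)
  keep2 <- exclude_outliers(v[keep1])
  expect_true(all(keep2))
})

test_that("noise-free regressions approach R-squared of 1", {
  set.seed(3)
  x <- rnorm(20)
  res <- selectivity_regression(x, 2 * x + rnorm(20, 0, 1e-6))
  expect_gt(res$r2, 0.999)
  expect_equal(res$slope, 2, tolerance = 1e-3)
})

test_that("matched cue-outcome coupling beats crossed pairs", {
  wins <- logical(20)
  for (i in seq_len(20)) {
    cfg <- unblocking_config(
      seed = 600L + i, n_trials_per_novel_odor = 20L,
      n_initial_trials = 20L,
      class_counts = c(predictive_number = 16L, predictive_flavor = 16L),
      cue_outcome_coupling = 1, noise_sd = 4)
    g <- generate_session(cfg)
    crs <- lapply(names(g$session$units), function(uid)
      unit_condition_rates(g$session$units[[uid]], g$session))
    idx <- function(dom, tt) vapply(crs, function(cr)
      selectivity_index(cr[[dom]], tt), numeric(1))
    fl <- g$truth$class == "predictive_flavor"
    matched <- selectivity_regression(idx("odor", "flavor")[fl],
                                      idx("outcome", "flavor")[fl])$r2
    crossed <- selectivity_regression(idx("odor", "flavor")[fl],
                                      idx("outcome", "number")[fl])$r2
    wins[i] <- matched > crossed
  }
  expect_gte(mean(wins), 0.9)
})

test_that("the full selectivity analysis reports sane regression tables", {
  cfg <- unblocking_config(
    seed = 521L, n_trials_per_novel_odor = 20L, n_initial_trials = 20L,
    class_counts = c(nonresponsive = 2L, predictive_number = 10L,
                     predictive_flavor = 10L, predictive_both = 4L),
    cue_outcome_coupling = 1, noise_sd = 4)
  g <- generate_session(cfg)
  scr <- screen_units(g$session)
  sel <- selectivity_analysis(scr, g$session)
  expect_s3_class(sel, "ub_selectivity")
  expect_true(all(c("population", "x", "y", "n", "r2", "p") %in%
                    names(sel$regressions)))
  matched <- sel$regressions[sel$regressions$population ==
                               "flavor_responsive" &
                               sel$regressions$y == "outcome_flavor", ]
  crossed <- sel$regressions[sel$regressions$population ==
                               "flavor_responsive" &
                               sel$regressions$y == "outcome_number", ]
  expect_gt(matched$r2, crossed$r2)
  # regressions are invariant to unit ordering
  ord <- rev(seq_len(nrow(scr)))
  scr2 <- scr[ord, ]
  class(scr2) <- class(scr)
  attr(scr2, "alpha") <- attr(scr, "alpha")
  sel2 <- selectivity_analysis(scr2, g$session)
  expect_equal(sel2$regressions$r2, sel$regressions$r2, tolerance = 1e-12)
})
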