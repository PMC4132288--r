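# Synthetic task/spike generator: determinism, rate-model contracts, and
# the thinning sampler checked against Poisson theory.

test_that("the same seed yields an identical session", {
  g1 <- generate_session(small_config(21L), day = "1")
  g2 <- generate_session(small_config(21L), day = "1")
  expect_identical(g1$truth, g2$truth)
  expect_identical(lapply(g1$session$trials, unclass),
                   lapply(g2$session$trials, unclass))
  expect_identical(lapply(g1$session$units, as.numeric),
                   lapply(g2$session$units, as.numeric))
})

test_that("nonresponsive units fire at the configured baseline", {
  cfg <- unblocking_config(seed = 31L, n_trials_per_novel_odor = 10L,
                           n_initial_trials = 10L,
                           class_counts = c(nonresponsive = 5L),
                           baseline_rate = 5)
  g <- generate_session(cfg)
  dur <- session_duration(g$session)
  for (u in g$session$units) {
    n <- length(u)
    rate <- n / dur
    # Poisson count CI: n within 3 sqrt(expected)
    expect_lt(abs(n - 5 * dur), 3 * sqrt(5 * dur))
    expect_gt(rate, 4); expect_lt(rate, 6)
  }
})

test_that("salience novelty decays across presentations", {
  # decay constant 2 => trial-10 increment is ~1% of trial-1; measure the
  # onset-locked transient in the first 300 ms of the novel odor
  cfg <- unblocking_config(seed = 41L, n_trials_per_novel_odor = 12L,
                           n_initial_trials = 12L,
                           class_counts = c(salience = 60L),
                           novelty_amp = 8, novelty_trial_decay = 2,
                           noise_sd = 0)
  g <- generate_session(cfg)
  onset_increment <- function(ks) {
    # novel-odor onset rate minus the same-trial initial-odor-epoch rate,
    # averaged over presentations ks, the three novel odors and all units
    mean(vapply(names(g$session$units), function(uid) {
      sp <- g$session$units[[uid]]
      mean(vapply(c("blocked", "number", "flavor"), function(tt) {
        mean(vapply(ks, function(k) {
          tr <- trials_of_type(g$session, tt)[[k]]
          a <- tr$events$novel_odor_on
          on <- sum(sp >= a & sp < a + 0.3) / 0.3
          pre <- sum(sp >= tr$events$odor_on & sp < a) / 0.2
          on - pre
        }, numeric(1)))
      }, numeric(1)))
    }, numeric(1)))
  }
  expect_gt(onset_increment(1:2), onset_increment(9:10) + 1)
})

test_that("unit_rate_function matches its analytic contract", {
  g <- generate_session(small_config(51L))
  tr_num <- trials_of_type(g$session, "number")[[1]]
  # nonresponsive: rate identically baseline
  nr <- g$truth[g$truth$class == "nonresponsive", ][1, ]
  fn <- unit_rate_function(nr, tr_num, presentation = 3)
  tt <- seq(tr_num$events$light_on - 2, tr_num$events$well_out, by = 0.01)
  expect_equal(fn(tt), rep(nr$baseline_rate, length(tt)))
  # predictive unit: zero increment on presentation 1, asymptote later
  pn <- g$truth[g$truth$class == "predictive_number", ][1, ]
  mid_odor <- tr_num$events$novel_odor_on + 0.4
  f1 <- unit_rate_function(pn, tr_num, presentation = 1)
  expect_equal(f1(mid_odor), pn$baseline_rate)
  f99 <- unit_rate_function(pn, tr_num, presentation = 99)
  expect_equal(f99(mid_odor), pn$baseline_rate + pn$amp_number,
               tolerance = 1e-6)
})

test_that("Monte-Carlo spike counts match the analytic rate integral", {
  g <- generate_session(small_config(61L))
  tr <- trials_of_type(g$session, "flavor")[[1]]
  sal <- g$truth[g$truth$class == "salience", ][1, ]
  fn <- unit_rate_function(sal, tr, presentation = 1)
  a <- tr$events$light_on - 2; b <- tr$events$well_out
  expected <- integrate(fn, a, b, subdivisions = 2000L)$value
  set.seed(99)
  counts <- replicate(500, length(sample_poisson(fn, c(a, b),
                                                 max_rate = 40)))
  se <- sd(counts) / sqrt(500)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("sample_poisson obeys Poisson count statistics and time rescaling", {
  expect_length(sample_poisson(function(t) rep(0, length(t)), c(0, 10)), 0)
  set.seed(7)
  n <- length(sample_poisson(function(t) rep(10, length(t)), c(0, 100),
                             max_rate = 10))
  expect_lt(abs(n - 1000), 3 * sqrt(1000))
  # time-rescaling: transformed inter-event intervals are exponential(1)
  rate <- function(t) 20 + 15 * (t %% 2 >= 1)   # piecewise-constant
  Lambda <- function(t) {                       # analytic integral
    full <- floor(t / 2) * 55                   # 20 + 35 per 2-s period
    r <- t %% 2
    full + ifelse(r <= 1, 20 * r, 20 + 35 * (r - 1))
  }
  set.seed(17)
  spk <- sample_poisson(rate, c(0, 400), max_rate = 35)
  expect_gt(length(spk), 5000)
  iv <- diff(Lambda(spk))
  ks <- suppressWarnings(ks.test(iv, "pexp", 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("event timings honor the task constraints", {
  g <- generate_session(small_config(71L))
  for (tr in g$session$trials) {
    ev <- tr$events
    expect_equal(ev$odor_off - ev$odor_on, 1.0)     # 1-s odor sampling
    if (tr$trial_type != "initial")
      expect_equal(ev$novel_odor_on - ev$odor_on, 0.2)
    expect_gte(ev$light_on, 2)                      # ITI window exists
  }
  # no more than 3 consecutive same-type trials
  runs <- rle(vapply(g$session$trials, `[[`, "", "trial_type"))$lengths
  expect_lte(max(runs), 3)
})

test_that("degenerate configurations are rejected", {
  expect_error(unblocking_config(n_trials_per_novel_odor = 0,
                                 n_initial_trials = 0), "zero trials")
  expect_error(unblocking_config(baseline_rate = -1), ">= 0")
  expect_error(unblocking_config(cue_outcome_coupling = 1.5), "\\[0, 1\\]")
  cfg <- unblocking_config(class_counts = c(nonresponsive = 0L))
  expect_error(generate_session(cfg), "no units")
})
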