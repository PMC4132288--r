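# Epoch arithmetic, normalized firing, PSTHs and the display smoother.

test_that("epoch_rate counts spikes in half-open windows", {
  tr <- make_trial(1, "blocked", t0 = 10)      # odor_on = 11.05
  eps <- default_epochs()
  # 5 spikes inside the 1-s odor window [11.35, 12.35)
  sp <- c(11.4, 11.5, 11.9, 12.0, 12.3)
  expect_equal(epoch_rate(sp, tr, eps$odor), 5.0)
  # boundary convention on exactly representable edges: a trial with
  # odor_on = 10 and a dyadic epoch [10.25, 11.25): start in, end out
  tr2 <- new_trial(1, "initial",
                   list(light_on = 8, port_in = 9.5, odor_on = 10,
                        odor_off = 11, port_out = 11.25, well_in = 12,
                        well_out = 14),
                   drop_times = c(12.25, 12.75))
  dy <- epoch_def("dyadic", "odor_on", 0.25, 1.25)
  expect_equal(epoch_rate(c(10.25), tr2, dy), 1.0)
  expect_equal(epoch_rate(c(11.25), tr2, dy), 0.0)
  # ITI window is the 2 s before light on: [8, 10)
  expect_equal(epoch_rate(c(8.0, 9.0, 9.999, 10.0), tr, eps$iti), 1.5)
})

test_that("missing anchors yield NA, not zero", {
  ptr <- make_trial(1, "flavor", is_probe = TRUE)
  eps <- default_epochs()
  expect_true(is.na(epoch_rate(c(1, 2, 3), ptr, eps$outcome_flavor)))
  expect_true(is.na(epoch_rate(c(1, 2, 3), ptr, eps$outcome_number)))
  expect_false(is.na(epoch_rate(c(1, 2, 3), ptr, eps$odor)))
})

test_that("normalized firing is period minus ITI and is centered under the null", {
  expect_equal(normalized_firing(12, 4), 8)
  expect_equal(normalized_firing(3.7, 3.7), 0)
  # homogeneous Poisson unit: mean normalized firing within 3 SE of 0
  g <- generate_session(null_config(101L, n_units = 8L, n_trials = 20L))
  eps <- default_epochs()
  vals <- unlist(lapply(g$session$units, function(sp) {
    normalized_firing(epoch_rates(sp, g$session$trials, eps$odor),
                      epoch_rates(sp, g$session$trials, eps$iti))
  }))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se)
})

test_that("epoch rates are invariant to a global time translation", {
  g <- generate_session(small_config(81L))
  s <- g$session
  shift <- 1234.5
  shifted_trials <- lapply(s$trials, function(tr) {
    tr$events <- lapply(tr$events, `+`, shift)
    tr$drop_times <- tr$drop_times + shift
    tr
  })
  s2 <- new_session(s$session_id, s$day, shifted_trials,
                    lapply(s$units, function(u) as.numeric(u) + shift))
  eps <- default_epochs()
  u <- names(s$units)[3]
  expect_equal(epoch_rates(s2$units[[u]], s2$trials, eps$odor),
               epoch_rates(s$units[[u]], s$trials, eps$odor))
})

test_that("binned_psth conserves spikes and localizes responses", {
  tr <- make_trial(1, "number", t0 = 10)       # odor_on = 11.05
  # single trial, single spike: exactly one nonzero bin pre-normalization
  p <- binned_psth(c(11.3), list(tr))
  expect_equal(sum(p$raw_rate > 0), 1)
  expect_equal(p$n_spikes, 1)
  # conservation: binned counts equal the spike count in the span
  g <- generate_session(small_config(91L))
  sp <- g$session$units[[5]]
  trs <- trials_of_type(g$session, "number")
  p <- binned_psth(sp, trs)
  in_span <- sum(vapply(trs, function(tr) {
    a <- tr$events$odor_on
    sum(sp >= a - 0.5 & sp < a + 1.5)
  }, numeric(1)))
  expect_equal(p$n_spikes, in_span)
  # a constant-rate unit is flat near zero after normalization
  gn <- generate_session(null_config(102L, n_units = 1L, n_trials = 20L))
  pn <- binned_psth(gn$session$units[[1]], gn$session$trials)
  expect_lt(max(abs(pn$rate)), 4)    # a few sp/s of bin noise around zero
  expect_lt(abs(mean(pn$rate)), 1)
})

test_that("a generator response step appears at the matching PSTH bin", {
  cfg <- unblocking_config(seed = 111L, n_trials_per_novel_odor = 25L,
                           n_initial_trials = 5L,
                           class_counts = c(predictive_number = 1L),
                           odor_response_amp = 30, noise_sd = 0,
                           learning_rate = 0.5)
  g <- generate_session(cfg)
  p <- binned_psth(g$session$units[[1]],
                   trials_of_type(g$session, "number"))
  # response gate opens at novel-odor onset, 200 ms = 4 bins after odor on
  pre <- p$rate[p$time < 0.2 - 1e-9 & p$time >= -0.5]
  post <- p$rate[p$time >= 0.2 & p$time < 1.0]
  expect_gt(mean(post), mean(pre) + 15)
})

test_that("the display smoother is a trailing four-bin average", {
  expect_equal(smooth_for_display(rep(3.5, 10)), rep(3.5, 10))
  # impulse spreads into a plateau of 1.0 across four windows
  x <- c(0, 0, 0, 4, 0, 0, 0, 0)
  expect_equal(smooth_for_display(x), c(0, 0, 0, 1, 1, 1, 1, 0))
  # mean preservation up to the shrinking left-edge rule (oracle recompute)
  set.seed(5)
  y <- rnorm(40)
  sm <- smooth_for_display(y)
  oracle <- vapply(seq_along(y), function(i)
    mean(y[max(1, i - 3):i]), numeric(1))
  expect_equal(sm, oracle)
  expect_error(smooth_for_display(c(1, 2, 3)), "at least 4")
})
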