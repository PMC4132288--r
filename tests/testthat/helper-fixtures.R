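# Hand-built fixtures: tiny deterministic trials/sessions with known spike
# placements, plus small generator configs reused across tests.

# one trial with fully specified, task-consistent event times
make_trial <- function(index = 1L, type = "blocked", t0 = 10,
                       is_probe = FALSE, n_drops = NULL,
                       well_bouts = NULL) {
  ev <- list(light_on = t0, port_in = t0 + 1, odor_on = t0 + 1.05)
  if (type != "initial") ev$novel_odor_on <- ev$odor_on + 0.2
  ev$odor_off <- ev$odor_on + 1
  ev$port_out <- ev$odor_off + 0.15
  drops <- numeric()
  if (!is_probe) {
    if (is.null(n_drops)) n_drops <- if (type == "number") 3L else 2L
    wi <- ev$port_out + 0.8
    d1 <- wi + 0.3
    drops <- d1 + 0.5 * (seq_len(n_drops) - 1)
    ev$well_in <- wi
    ev$well_out <- max(drops) + 1
  } else {
    ev$well_in <- ev$port_out + 0.8
    ev$well_out <- ev$well_in + 1.5
  }
  if (!is.null(well_bouts)) {
    ev$well_in <- well_bouts$well_in
    ev$well_out <- well_bouts$well_out
  }
  new_trial(index, type, ev, drop_times = drops, is_probe = is_probe)
}

# a session holding one trial per type, offset by `spacing` seconds
make_session <- function(units = list(), day = "1", spacing = 20,
                         types = TRIAL_TYPES, probe = FALSE) {
  trials <- lapply(seq_along(types), function(i)
    make_trial(i, types[i], t0 = 10 + (i - 1) * spacing,
               is_probe = probe && types[i] != "initial"))
  new_session("fix1", day, trials, units)
}

# a deterministic spike train: regular firing at `rate` over [0, t_end)
regular_spikes <- function(rate, t_end, phase = 0) {
  seq(phase, t_end, by = 1 / rate)
}

# small generator configs
null_config <- function(seed, n_units = 16L, n_trials = 10L) {
  unblocking_config(
    seed = seed, n_trials_per_novel_odor = n_trials,
    n_initial_trials = n_trials,
    class_counts = c(nonresponsive = n_units),
    odor_response_amp = 0, novelty_amp = 0, outcome_amp = 0,
    latency_novelty_effect = 0, probe_unblock_effect = 0)
}

small_config <- function(seed, ...) {
  unblocking_config(
    seed = seed, n_trials_per_novel_odor = 15L, n_initial_trials = 15L,
    class_counts = c(nonresponsive = 2, salience = 4,
                     predictive_number = 3, predictive_flavor = 3,
                     predictive_both = 3),
    ...)
}
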