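## Task-structured session generator with ground-truth-labelled
## inhomogeneous-Poisson spike trains.
##
## The rate model is additive: baseline plus epoch-gated amplitude terms.
## Salience units respond to every odor with an extra novelty term that is
## onset-locked (exponential within-trial decay) and decays across
## presentations; predictive units acquire responses to their preferred
## novel odor(s) with an exponential learning curve and fire to the
## corresponding outcome epoch with an amplitude coupled, across units, to
## their cue amplitude.

UNIT_CLASSES <- c("nonresponsive", "salience", "predictive_number",
                  "predictive_flavor", "predictive_both", "blocked_only",
                  "initial_only")

#' Generator configuration
#'
#' Builds a validated configuration for [generate_session()]. Defaults
#' emulate the task conditions: 30 trials per novel odor on each learning
#' day (the lower end of the 30-60 used in training), 1-s odor sampling with
#' a 200-ms initial odor followed by an 800-ms novel odor on compound
#' trials, 2-3 milk drops at the well, 15 unrewarded probe trials per novel
#' odor on the probe day, and a 6-s inter-trial interval so the 2-s
#' pre-light baseline window always exists.
#'
#' @param seed Integer seed; a fixed seed yields an identical session.
#' @param n_trials_per_novel_odor Trials per novel odor per learning day.
#' @param n_initial_trials Reminder (initial-odor) trials per learning day.
#' @param n_probe_trials Unrewarded probe trials per novel odor (probe day).
#' @param iti_duration Inter-trial interval, seconds.
#' @param class_counts Named integer vector over
#'   `c("nonresponsive","salience","predictive_number","predictive_flavor",
#'   "predictive_both","blocked_only","initial_only")`.
#' @param baseline_rate Baseline firing rate, spikes/s.
#' @param odor_response_amp Asymptotic odor-response amplitude, spikes/s.
#' @param novelty_amp Novelty amplitude of salience units, spikes/s.
#' @param novelty_trial_decay Across-trial novelty decay constant (trials).
#' @param novelty_time_constant Within-trial, onset-locked novelty decay (s).
#' @param learning_rate Learning-curve trial constant of predictive units.
#' @param outcome_amp Outcome-epoch amplitude, spikes/s.
#' @param cue_outcome_coupling Across-unit coupling in `[0, 1]` between a
#'   unit's cue amplitude and its matched outcome amplitude.
#' @param cue_pair_coupling Across-unit coupling between the number and
#'   flavor amplitudes of dual predictive units.
#' @param noise_sd Between-unit amplitude spread, spikes/s.
#' @param latency_mean Mean odor-port-exit to well-entry latency, s.
#' @param latency_novelty_effect Extra latency on early novel-odor trials, s.
#' @param probe_welltime_base Baseline probe-trial well time, s.
#' @param probe_unblock_effect Extra early well time after number/flavor
#'   odors on probe trials, s.
#' @param probe_effect_decay Across-trial decay of the probe effect (trials).
#' @param behavior_noise_sd SD of behavioral noise, s.
#' @return Object of class `ub_config` (a named list).
#' @export
unblocking_config <- function(seed = 1L,
                              n_trials_per_novel_odor = 30L,
                              n_initial_trials = 30L,
                              n_probe_trials = 15L,
                              iti_duration = 6,
                              class_counts = c(nonresponsive = 10L,
                                               salience = 8L,
                                               predictive_number = 5L,
                                               predictive_flavor = 5L,
                                               predictive_both = 6L,
                                               blocked_only = 2L,
                                               initial_only = 2L),
                              baseline_rate = 5,
                              odor_response_amp = 8,
                              novelty_amp = 8,
                              novelty_trial_decay = 2,
                              novelty_time_constant = 0.25,
                              learning_rate = 3,
                              outcome_amp = 6,
                              cue_outcome_coupling = 0.8,
                              cue_pair_coupling = 0.9,
                              noise_sd = 0.5,
                              latency_mean = 0.8,
                              latency_novelty_effect = 1.0,
                              probe_welltime_base = 1.0,
                              probe_unblock_effect = 1.5,
                              probe_effect_decay = 4,
                              behavior_noise_sd = 0.2) {
  cc <- integer(length(UNIT_CLASSES)); names(cc) <- UNIT_CLASSES
  cc[names(class_counts)] <- as.integer(class_counts)
  bad <- setdiff(names(class_counts), UNIT_CLASSES)
  if (length(bad)) stop("unknown unit class(es): ", paste(bad, collapse = ", "))
  cfg <- list(seed = as.integer(seed),
              n_trials_per_novel_odor = as.integer(n_trials_per_novel_odor),
              n_initial_trials = as.integer(n_initial_trials),
              n_probe_trials = as.integer(n_probe_trials),
              iti_duration = iti_duration,
              class_counts = cc,
              baseline_rate = baseline_rate,
              odor_response_amp = odor_response_amp,
              novelty_amp = novelty_amp,
              novelty_trial_decay = novelty_trial_decay,
              novelty_time_constant = novelty_time_constant,
              learning_rate = learning_rate,
              outcome_amp = outcome_amp,
              cue_outcome_coupling = cue_outcome_coupling,
              cue_pair_coupling = cue_pair_coupling,
              noise_sd = noise_sd,
              latency_mean = latency_mean,
              latency_novelty_effect = latency_novelty_effect,
              probe_welltime_base = probe_welltime_base,
              probe_unblock_effect = probe_unblock_effect,
              probe_effect_decay = probe_effect_decay,
              behavior_noise_sd = behavior_noise_sd)
  rates <- c("baseline_rate", "odor_response_amp", "novelty_amp",
             "outcome_amp", "noise_sd")
  for (r in rates) if (cfg[[r]] < 0) stop(r, " must be >= 0")
  for (cp in c("cue_outcome_coupling", "cue_pair_coupling"))
    if (cfg[[cp]] < 0 || cfg[[cp]] > 1) stop(cp, " must be in [0, 1]")
  if (cfg$n_trials_per_novel_odor < 1 && cfg$n_initial_trials < 1)
    stop("config error: zero trials")
  if (cfg$iti_duration < 2.5)
    stop("iti_duration must exceed the 2-s baseline window")
  structure(cfg, class = "ub_config")
}

#' @export
print.ub_config <- function(x, ...) {
  cat("<ub_config> seed ", x$seed, "; ",
      sum(x$class_counts), " units (",
      paste(names(x$class_counts)[x$class_counts > 0],
            x$class_counts[x$class_counts > 0], sep = "=", collapse = ", "),
      ")\n  trials/novel odor ", x$n_trials_per_novel_odor,
      ", initial ", x$n_initial_trials,
      "; baseline ", x$baseline_rate, " sp/s\n", sep = "")
  invisible(x)
}

#' Sample an inhomogeneous Poisson process by thinning
#'
#' Candidate events are drawn from a homogeneous Poisson process at the
#' bounding rate and accepted with probability `rate(t) / max_rate`.
#'
#' @param ratefn Vectorized non-negative rate function of time (spikes/s).
#' @param interval Length-2 numeric, `[start, end)`.
#' @param max_rate Upper bound on `ratefn` over the interval; computed on a
#'   fine grid when omitted.
#' @return Ascending numeric vector of event times within the interval.
#' @export
sample_poisson <- function(ratefn, interval, max_rate = NULL) {
  a <- interval[1]; b <- interval[2]
  if (b <= a) return(numeric())
  if (is.null(max_rate)) {
    grid <- seq(a, b, length.out = 512L)
    max_rate <- max(ratefn(grid)) * 1.05
  }
  if (max_rate <= 0) return(numeric())
  n <- stats::rpois(1L, max_rate * (b - a))
  if (n == 0L) return(numeric())
  tt <- sort(stats::runif(n, a, b))
  keep <- stats::runif(n) < ratefn(tt) / max_rate
  tt[keep]
}

## --- rate model -----------------------------------------------------------

# Epoch-gated additive segments for one unit on one trial.
# Columns: start, end, c (constant sp/s), a (onset-locked sp/s), tau, t0.
.unit_trial_segments <- function(truth, trial, presentation = 1) {
  ev <- trial$events
  k <- presentation
  segs <- list()
  amp <- c(initial = truth$amp_initial, blocked = truth$amp_blocked,
           number = truth$amp_number, flavor = truth$amp_flavor)
  tt <- trial$trial_type
  gate_start <- if (tt == "initial") ev$odor_on else ev$novel_odor_on
  cue_amp <- amp[[tt]]
  if (isTRUE(truth$learns) && tt %in% c("number", "flavor"))
    cue_amp <- cue_amp * (1 - exp(-(k - 1) / truth$learning_rate))
  if (truth$class == "salience") {
    # responds to the odor stream on every trial type ...
    if (cue_amp > 0)
      segs <- c(segs, list(c(ev$odor_on, ev$odor_off, cue_amp, 0, Inf, 0)))
    # ... plus an onset-locked novelty transient on novel odors
    if (tt != "initial" && truth$novelty_amp > 0) {
      na <- truth$novelty_amp * exp(-(k - 1) / truth$novelty_trial_decay)
      segs <- c(segs, list(c(ev$novel_odor_on, ev$odor_off, 0, na,
                             truth$novelty_tau, ev$novel_odor_on)))
    }
  } else if (cue_amp > 0) {
    segs <- c(segs, list(c(gate_start, ev$odor_off, cue_amp, 0, Inf, 0)))
  }
  if (!trial$is_probe && length(trial$drop_times)) {
    d1 <- trial$drop_times[1]
    if (tt == "number" && truth$out_amp_number > 0)
      segs <- c(segs, list(c(d1 + 1, d1 + 3, truth$out_amp_number, 0, Inf, 0)))
    if (tt == "flavor" && truth$out_amp_flavor > 0)
      segs <- c(segs, list(c(d1, d1 + 2, truth$out_amp_flavor, 0, Inf, 0)))
  }
  if (!length(segs))
    return(matrix(numeric(), ncol = 6,
                  dimnames = list(NULL, c("start", "end", "c", "a",
                                          "tau", "t0"))))
  m <- do.call(rbind, segs)
  colnames(m) <- c("start", "end", "c", "a", "tau", "t0")
  m
}

#' Firing-rate function of one unit on one trial
#'
#' Returns the unit's instantaneous rate over trial time: baseline plus
#' epoch-gated amplitude terms. The salience novelty term multiplies the
#' novelty amplitude by `exp(-(presentation - 1)/novelty_trial_decay)` and
#' decays within the trial from novel-odor onset; the predictive term
#' multiplies the cue amplitude by
#' `1 - exp(-(presentation - 1)/learning_rate)`; outcome terms are active
#' during the relevant drop epoch. Negative values cannot arise under
#' non-negative amplitudes but are clipped to zero regardless.
#'
#' @param truth A single row of the ground-truth table (as a list or 1-row
#'   data.frame) from [generate_session()].
#' @param trial A `ub_trial`.
#' @param presentation Presentation index of this trial within its
#'   condition (the trial-dynamics "trial number").
#' @return Vectorized function of time returning spikes/s.
#' @export
unit_rate_function <- function(truth, trial, presentation = 1) {
  if (is.data.frame(truth)) truth <- as.list(truth[1, ])
  segs <- .unit_trial_segments(truth, trial, presentation)
  base <- truth$baseline_rate
  function(t) {
    r <- rep(base, length(t))
    if (nrow(segs)) for (i in seq_len(nrow(segs))) {
      inside <- t >= segs[i, "start"] & t < segs[i, "end"]
      if (any(inside)) {
        add <- segs[i, "c"]
        if (segs[i, "a"] > 0)
          add <- add + segs[i, "a"] *
            exp(-(t[inside] - segs[i, "t0"]) / segs[i, "tau"])
        r[inside] <- r[inside] + add
      }
    }
    pmax(r, 0)
  }
}

## --- ground truth ---------------------------------------------------------

.draw_truth <- function(config) {
  cc <- config$class_counts
  n <- sum(cc)
  if (n == 0L) stop("config error: no units requested")
  classes <- rep(names(cc), cc)
  pos <- function(x) pmax(x, 0)
  A <- config$odor_response_amp
  rows <- lapply(seq_len(n), function(i) {
    cl <- classes[i]
    amp <- c(initial = 0, blocked = 0, number = 0, flavor = 0)
    nov <- 0; learns <- FALSE
    out_n <- 0; out_f <- 0
    scale_of <- function(a) if (A > 0) a / A else 1
    indep <- function() pos(1 + stats::rnorm(1, 0, config$noise_sd /
                                               max(A, 1e-9)))
    couple <- function(s) config$outcome_amp *
      (config$cue_outcome_coupling * s +
         (1 - config$cue_outcome_coupling) * indep())
    if (cl == "salience") {
      a <- pos(A + stats::rnorm(1, 0, config$noise_sd))
      amp[] <- a
      nov <- pos(config$novelty_amp + stats::rnorm(1, 0, config$noise_sd))
    } else if (cl == "predictive_number") {
      a <- pos(A + stats::rnorm(1, 0, config$noise_sd))
      amp["number"] <- a; learns <- TRUE
      out_n <- couple(scale_of(a))
    } else if (cl == "predictive_flavor") {
      a <- pos(A + stats::rnorm(1, 0, config$noise_sd))
      amp["flavor"] <- a; learns <- TRUE
      out_f <- couple(scale_of(a))
    } else if (cl == "predictive_both") {
      a_n <- pos(A + stats::rnorm(1, 0, config$noise_sd))
      s_f <- config$cue_pair_coupling * scale_of(a_n) +
        (1 - config$cue_pair_coupling) * indep()
      a_f <- pos(A * s_f)
      amp["number"] <- a_n; amp["flavor"] <- a_f; learns <- TRUE
      out_n <- couple(scale_of(a_n)); out_f <- couple(scale_of(a_f))
    } else if (cl == "blocked_only") {
      amp["blocked"] <- pos(A + stats::rnorm(1, 0, config$noise_sd))
    } else if (cl == "initial_only") {
      amp["initial"] <- pos(A + stats::rnorm(1, 0, config$noise_sd))
    }
    data.frame(unit_id = sprintf("u%03d", i), class = cl,
               baseline_rate = config$baseline_rate,
               amp_initial = amp[["initial"]], amp_blocked = amp[["blocked"]],
               amp_number = amp[["number"]], amp_flavor = amp[["flavor"]],
               novelty_amp = nov,
               novelty_trial_decay = config$novelty_trial_decay,
               novelty_tau = config$novelty_time_constant,
               learns = learns, learning_rate = config$learning_rate,
               out_amp_number = out_n, out_amp_flavor = out_f,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## --- schedule -------------------------------------------------------------

# pseudo-random interleave with no more than `max_run` consecutive same types
.interleave <- function(types, max_run = 3L, max_tries = 10000L) {
  for (i in seq_len(max_tries)) {
    ord <- sample(types)
    runs <- rle(ord)$lengths
    if (max(runs) <= max_run) return(ord)
  }
  stop("could not interleave trial types within run-length constraint")
}

.schedule_day <- function(config, day) {
  if (day %in% c("1", "2")) {
    types <- c(rep("initial", config$n_initial_trials),
               rep(c("blocked", "number", "flavor"),
                   each = config$n_trials_per_novel_odor))
    if (!length(types)) stop("config error: zero trials")
    data.frame(trial_type = .interleave(types), is_probe = FALSE,
               stringsAsFactors = FALSE)
  } else {
    # brief rewarded reminder block, then unrewarded probes per novel odor
    # interleaved with rewarded initial trials to maintain responding
    reminder <- data.frame(
      trial_type = c("initial", "blocked", "number", "flavor",
                     sample(TRIAL_TYPES)),
      is_probe = FALSE, stringsAsFactors = FALSE)
    body_types <- c(rep(c("blocked", "number", "flavor"),
                        each = config$n_probe_trials),
                    rep("initial", config$n_probe_trials))
    ord <- .interleave(body_types)
    body <- data.frame(trial_type = ord, is_probe = ord != "initial",
                       stringsAsFactors = FALSE)
    rbind(reminder, body)
  }
}

## --- session assembly -----------------------------------------------------

.make_trials <- function(config, sched, day) {
  t_now <- config$iti_duration
  k_count <- c(initial = 0L, blocked = 0L, number = 0L, flavor = 0L)
  k_offset <- if (day == "2") config$n_trials_per_novel_odor else
    if (day == "probe") 2L * config$n_trials_per_novel_odor else 0L
  trials <- vector("list", nrow(sched))
  pres <- integer(nrow(sched))
  for (i in seq_len(nrow(sched))) {
    tt <- sched$trial_type[i]; probe <- sched$is_probe[i]
    k_count[tt] <- k_count[tt] + 1L
    k <- k_count[tt] + if (tt == "initial") 0L else k_offset
    pres[i] <- k
    ev <- list(light_on = t_now)
    ev$port_in <- ev$light_on + stats::runif(1, 0.8, 1.5)
    ev$odor_on <- ev$port_in + 0.05
    if (tt != "initial") ev$novel_odor_on <- ev$odor_on + 0.2
    ev$odor_off <- ev$odor_on + 1.0
    ev$port_out <- ev$odor_off + stats::runif(1, 0.1, 0.25)
    lat <- config$latency_mean +
      abs(stats::rnorm(1, 0, config$behavior_noise_sd))
    if (tt != "initial")
      lat <- lat + config$latency_novelty_effect *
        exp(-(k - 1) / config$novelty_trial_decay)
    ev$well_in <- ev$port_out + max(lat, 0.2)
    drops <- numeric()
    if (!probe) {
      d1 <- ev$well_in + 0.30
      drops <- d1 + c(0, 0.5)
      if (tt == "number") drops <- c(drops, d1 + 1.0)
      ev$well_out <- max(drops) + stats::runif(1, 0.8, 1.2)
    } else {
      wt <- config$probe_welltime_base +
        (if (tt %in% c("number", "flavor"))
          config$probe_unblock_effect *
            exp(-(k_count[tt] - 1) / config$probe_effect_decay) else 0) +
        stats::rnorm(1, 0, config$behavior_noise_sd)
      ev$well_out <- ev$well_in + max(wt, 0.1)
    }
    trials[[i]] <- new_trial(i, tt, ev, drop_times = drops, is_probe = probe)
    t_now <- ev$well_out + config$iti_duration
  }
  list(trials = trials, presentation = pres)
}

.unit_spikes <- function(truth_row, trials, presentation, t_end, seed) {
  set.seed(seed)
  base <- truth_row$baseline_rate
  spk <- sample_poisson(function(t) rep(base, length(t)), c(0, t_end), base)
  for (i in seq_along(trials)) {
    segs <- .unit_trial_segments(truth_row, trials[[i]], presentation[i])
    if (!nrow(segs)) next
    for (j in seq_len(nrow(segs))) {
      s <- segs[j, ]
      fn <- local({
        cj <- s[["c"]]; aj <- s[["a"]]; tauj <- s[["tau"]]; t0j <- s[["t0"]]
        function(t) cj + if (aj > 0) aj * exp(-(t - t0j) / tauj) else 0
      })
      spk <- c(spk, sample_poisson(fn, c(s[["start"]], s[["end"]]),
                                   s[["c"]] + s[["a"]]))
    }
  }
  spk <- sort(spk)
  spk[c(TRUE, diff(spk) > 1e-9)]   # enforce strict ascent at resolution
}

#' Generate a synthetic session with ground truth
#'
#' Draws a task-structured session (interleaved trial types, task-consistent
#' event timings) and one spike train per configured unit from the additive
#' rate model, with per-unit sub-seeds so unit spike trains are independent.
#' Identical configuration and seed yield an identical session.
#'
#' @param config A [unblocking_config()].
#' @param day `"1"`, `"2"` or `"probe"`. Learning dynamics (novelty decay,
#'   acquisition) continue across days: day-2 presentation indices start
#'   where day 1 ended.
#' @param session_id Session identifier; defaults to `"sim<seed>_d<day>"`.
#' @return List with elements `session` (a `ub_session`) and `truth` (a
#'   data.frame, one row per unit: class label, per-condition asymptotic
#'   amplitudes, novelty/learning parameters, outcome amplitudes).
#' @export
generate_session <- function(config, day = "1", session_id = NULL) {
  stopifnot(inherits(config, "ub_config"))
  day <- as.character(day)
  day_code <- match(day, c("1", "2", "probe"))
  if (is.na(day_code)) stop("day must be '1', '2' or 'probe'")
  if (is.null(session_id))
    session_id <- sprintf("sim%d_d%s", config$seed, day)
  set.seed((config$seed * 1009L + day_code) %% .Machine$integer.max)
  truth <- .draw_truth(config)
  sched <- .schedule_day(config, day)
  made <- .make_trials(config, sched, day)
  t_end <- session_duration(new_session(session_id, day, made$trials)) + 2
  unit_seeds <- (config$seed + 7919L * seq_len(nrow(truth)) +
                   1000003L * day_code) %% .Machine$integer.max
  units <- lapply(seq_len(nrow(truth)), function(i)
    .unit_spikes(as.list(truth[i, ]), made$trials, made$presentation,
                 t_end, unit_seeds[i]))
  names(units) <- truth$unit_id
  list(session = new_session(session_id, day, made$trials, units),
       truth = truth)
}
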