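## Behavioral measures: response latency, probe-test well time with the
## odor x trial repeated-measures ANOVA and planned early-trial
## comparisons, and two-bottle preference ratios.

#' Behavioral measures of one trial
#'
#' Latency is the time from odor-port exit to (first) well entry; well time
#' is the cumulative in-well time from the `well_in`/`well_out` bout pairs
#' falling within a window after port exit. The integration window is an
#' explicit package choice (5 s default) as no standard exists.
#'
#' @param trial A `ub_trial` with a `port_out` event.
#' @param window Well-time integration window after port exit, seconds.
#' @return One-row data.frame: `trial_index`, `trial_type`, `is_probe`,
#'   `latency` (`NA` if the well was never entered), `well_time`.
#' @export
trial_behavior <- function(trial, window = 5) {
  po <- trial$events$port_out
  if (is.null(po)) stop("trial ", trial$trial_index, ": no port_out event")
  wi <- trial$events$well_in; wo <- trial$events$well_out
  if (is.null(wi)) {
    lat <- NA_real_; wt <- 0
  } else {
    lat <- wi[1] - po
    hi <- po + window
    wt <- sum(pmax(0, pmin(wo, hi) - pmax(wi, po)))
  }
  data.frame(trial_index = trial$trial_index, trial_type = trial$trial_type,
             is_probe = trial$is_probe, latency = lat, well_time = wt,
             stringsAsFactors = FALSE)
}

#' Behavioral table of a session
#'
#' @param session A `ub_session`.
#' @param window Passed to [trial_behavior()].
#' @return Data.frame, one row per trial.
#' @export
session_behavior <- function(session, window = 5) {
  do.call(rbind, lapply(session$trials, trial_behavior, window = window))
}

#' Probe-test well-time ANOVA with planned comparisons
#'
#' Two-way repeated-measures ANOVA on probe-trial well time with odor
#' (blocked, number, flavor) and trial (1..15) as within-subject factors
#' (subject = rat/session), followed by planned paired t tests on each
#' subject's mean well time over the first three probe trials: number vs
#' blocked, flavor vs blocked, and number vs flavor.
#'
#' @param records Data.frame with columns `subject`, `odor`, `trial`,
#'   `well_time`; one row per subject x odor x trial.
#' @param trials Probe-trial indices used (default 1:15).
#' @param early Trial indices entering the planned comparisons.
#' @return List: `anova` (a `ub_test` data.frame) and `planned`
#'   (data.frame of the three comparisons with t, df, p).
#' @export
probe_anova <- function(records, trials = 1:15, early = 1:3) {
  stopifnot(all(c("subject", "odor", "trial", "well_time") %in%
                  names(records)))
  records <- records[records$trial %in% trials &
                       records$odor %in% c("blocked", "number", "flavor"), ]
  records$subject <- factor(records$subject)
  if (nlevels(records$subject) < 2)
    stop("probe_anova requires at least 2 subjects")
  dat <- data.frame(unit = records$subject, odor = records$odor,
                    trial = factor(records$trial), value = records$well_time)
  an <- rm_anova(dat, factors = c("trial", "odor"))
  an$test <- sub("rm_anova", "probe_anova", an$test)
  sub_means <- function(od) {
    r <- records[records$odor == od & records$trial %in% early, ]
    tapply(r$well_time, r$subject, mean)
  }
  mb <- sub_means("blocked"); mn <- sub_means("number"); mf <- sub_means("flavor")
  cmp <- function(a, b, lab) {
    ht <- stats::t.test(a, b, paired = TRUE)
    data.frame(comparison = lab, t = unname(ht$statistic),
               df = unname(ht$parameter), p = ht$p.value,
               mean_diff = mean(a - b), stringsAsFactors = FALSE)
  }
  planned <- rbind(cmp(mn, mb, "number_vs_blocked"),
                   cmp(mf, mb, "flavor_vs_blocked"),
                   cmp(mn, mf, "number_vs_flavor"))
  list(anova = an, planned = planned)
}

#' Probe-trial well-time records from generated sessions
#'
#' Extracts per-probe-trial well times from one or more probe-day sessions
#' into the long format [probe_anova()] consumes, numbering each odor's
#' probe trials 1..n in presentation order.
#'
#' @param sessions List of probe-day `ub_session` objects (one per
#'   subject), or a single session.
#' @param window Well-time window, seconds.
#' @return Data.frame: `subject`, `odor`, `trial`, `well_time`.
#' @export
probe_records <- function(sessions, window = 5) {
  if (inherits(sessions, "ub_session")) sessions <- list(sessions)
  rows <- lapply(sessions, function(s) {
    b <- session_behavior(s, window)
    b <- b[b$is_probe, ]
    b <- b[order(b$trial_index), ]
    b$probe_index <- stats::ave(seq_len(nrow(b)), b$trial_type,
                                FUN = seq_along)
    data.frame(subject = s$session_id, odor = b$trial_type,
               trial = b$probe_index, well_time = b$well_time,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-bottle preference ratio
#'
#' `ratio = consumed_a / (consumed_a + consumed_b)`; 0.5 indicates equal
#' preference. A zero total leaves the ratio undefined (`NA`, flagged).
#'
#' @param consumed_a,consumed_b Volumes consumed (ml), non-negative.
#' @return List: `consumed_a`, `consumed_b`, `ratio`, `defined`.
#' @export
preference_ratio <- function(consumed_a, consumed_b) {
  if (consumed_a < 0 || consumed_b < 0) stop("volumes must be >= 0")
  total <- consumed_a + consumed_b
  list(consumed_a = consumed_a, consumed_b = consumed_b,
       ratio = if (total > 0) consumed_a / total else NA_real_,
       defined = total > 0)
}
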