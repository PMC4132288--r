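#' @keywords internal
"_PACKAGE"

## Canonical vocabulary for the task structure.

#' Trial types of the unblocking task
#'
#' The four trial types of a learning session: `initial` (reminder of the
#' pretrained odor), `blocked` (novel odor, unchanged outcome), `number`
#' (novel odor, extra reward drop) and `flavor` (novel odor, different but
#' equally preferred reward flavor).
#'
#' @format Character vector of length 4.
#' @export
TRIAL_TYPES <- c("initial", "blocked", "number", "flavor")

#' Event labels recognised in event tables
#'
#' @format Character vector.
#' @export
EVENT_LABELS <- c("light_on", "port_in", "odor_on", "novel_odor_on",
                  "odor_off", "port_out", "well_in", "drop", "well_out")

# tolerance for the 200-ms initial->novel odor gap (absorbs text round-trips)
.GAP_TOL <- 1e-3
.NOVEL_GAP <- 0.200

#' Construct a trial
#'
#' A trial holds its index, type, event times keyed by event label, reward
#' drop times and a probe flag. `well_in`/`well_out` may be vectors (several
#' in-well bouts); all other labels are scalar.
#'
#' @param trial_index Integer >= 1.
#' @param trial_type One of [TRIAL_TYPES].
#' @param events Named list of event times in seconds (labels from
#'   [EVENT_LABELS], excluding `"drop"`).
#' @param drop_times Numeric vector of reward-drop times (empty for probes).
#' @param is_probe Logical; probe trials are unrewarded novel-odor trials.
#' @return An object of class `ub_trial`.
#' @export
new_trial <- function(trial_index, trial_type, events, drop_times = numeric(),
                      is_probe = FALSE) {
  tr <- structure(list(
    trial_index = as.integer(trial_index),
    trial_type  = trial_type,
    events      = events,
    drop_times  = as.numeric(drop_times),
    is_probe    = isTRUE(is_probe)
  ), class = "ub_trial")
  validate_trial(tr)
  tr
}

validate_trial <- function(tr) {
  if (!tr$trial_type %in% TRIAL_TYPES)
    stop("trial ", tr$trial_index, ": unknown trial_type '", tr$trial_type, "'")
  ev <- tr$events
  bad <- setdiff(names(ev), setdiff(EVENT_LABELS, "drop"))
  if (length(bad))
    stop("trial ", tr$trial_index, ": unknown event label(s): ",
         paste(bad, collapse = ", "))
  # non-decreasing times in canonical event order
  core <- c("light_on", "port_in", "odor_on", "novel_odor_on", "odor_off",
            "port_out")
  seq_times <- unlist(ev[core[core %in% names(ev)]], use.names = FALSE)
  if (is.unsorted(seq_times))
    stop("trial ", tr$trial_index, ": event times are not non-decreasing ",
         "in event order")
  # novel odor present iff compound trial; 200-ms gap to initial odor onset
  has_novel <- "novel_odor_on" %in% names(ev)
  if (tr$trial_type == "initial" && has_novel)
    stop("trial ", tr$trial_index, ": initial trial has novel_odor_on event")
  if (tr$trial_type != "initial") {
    if (!has_novel)
      stop("trial ", tr$trial_index, ": compound trial lacks novel_odor_on")
    gap <- ev$novel_odor_on - ev$odor_on
    if (abs(gap - .NOVEL_GAP) > .GAP_TOL)
      stop("trial ", tr$trial_index, ": initial->novel odor gap ",
           signif(gap, 6), " s (expected ", .NOVEL_GAP, " s)")
  }
  # in-well bouts: equal counts, alternating and ascending, after port exit
  wi <- ev$well_in; wo <- ev$well_out
  if (xor(is.null(wi), is.null(wo)))
    stop("trial ", tr$trial_index, ": unbalanced well_in/well_out events")
  if (!is.null(wi) && !is.null(wo)) {
    if (length(wi) != length(wo))
      stop("trial ", tr$trial_index, ": unbalanced well_in/well_out events")
    inter <- as.vector(rbind(sort(wi), sort(wo)))
    if (is.unsorted(inter))
      stop("trial ", tr$trial_index, ": well bouts not alternating in time")
    if (!is.null(ev$port_out) && any(wi < ev$port_out - 1e-9))
      stop("trial ", tr$trial_index, ": well entry precedes port exit")
  }
  # reward structure
  nd <- length(tr$drop_times)
  if (tr$is_probe) {
    if (nd != 0)
      stop("trial ", tr$trial_index, ": probe trial has drop events")
  } else {
    if (nd < 2)
      stop("trial ", tr$trial_index, ": rewarded trial has ", nd,
           " drops (>= 2 required)")
    if (tr$trial_type == "number" && nd != 3)
      stop("trial ", tr$trial_index, ": number trial has ", nd,
           " drops (3 required)")
  }
  if (nd > 1 && is.unsorted(tr$drop_times))
    stop("trial ", tr$trial_index, ": drop times not ascending")
  invisible(tr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a spike train
#'
#' @param unit_id Character scalar.
#' @param spike_times Strictly ascending numeric vector of seconds.
#' @return Numeric vector with attribute `unit_id`, class `ub_spikes`.
#' @export
new_spike_train <- function(unit_id, spike_times) {
  st <- as.numeric(spike_times)
  if (length(st) > 1 && any(diff(st) <= 0))
    stop("unit ", unit_id, ": spike times not strictly ascending")
  if (any(st < 0)) stop("unit ", unit_id, ": negative spike time")
  structure(st, unit_id = as.character(unit_id), class = "ub_spikes")
}

#' Construct a session
#'
#' The unit of analysis: an ordered list of trials with event times plus a
#' set of simultaneously recorded unit spike trains.
#'
#' @param session_id Character scalar.
#' @param day `"1"`, `"2"` (learning days) or `"probe"`.
#' @param trials List of [new_trial()] objects with unique contiguous
#'   indices 1..n.
#' @param units Named list of spike-time vectors (names are unit ids).
#' @return Object of class `ub_session`.
#' @export
new_session <- function(session_id, day, trials, units = list()) {
  day <- as.character(day)
  if (!day %in% c("1", "2", "probe"))
    stop("day must be '1', '2' or 'probe'")
  idx <- unname(vapply(trials, function(t) t$trial_index, integer(1)))
  if (length(idx) == 0L) stop("session has no trials")
  if (!identical(sort(idx), seq_along(idx)))
    stop("trial indices must be unique and contiguous from 1")
  trials <- trials[order(idx)]
  if (is.null(names(units)) && length(units))
    stop("units must be a named list")
  units <- lapply(seq_along(units), function(i) {
    u <- units[[i]]
    if (inherits(u, "ub_spikes")) u else new_spike_train(names(units)[i], u)
  })
  names(units) <- vapply(units, function(u) attr(u, "unit_id"), character(1))
  structure(list(session_id = as.character(session_id), day = day,
                 trials = trials, units = units),
            class = "ub_session")
}

#' @export
print.ub_session <- function(x, ...) {
  tt <- table(factor(vapply(x$trials, `[[`, "", "trial_type"),
                     levels = TRIAL_TYPES))
  np <- sum(vapply(x$trials, `[[`, logical(1), "is_probe"))
  cat("<ub_session> ", x$session_id, " (day ", x$day, ")\n", sep = "")
  cat("  trials: ", length(x$trials), " (",
      paste(names(tt), tt, sep = "=", collapse = ", "), ")",
      if (np) paste0(", ", np, " probe"), "\n", sep = "")
  cat("  units:  ", length(x$units), "\n", sep = "")
  invisible(x)
}

#' @export
summary.ub_session <- function(object, ...) {
  dur <- session_duration(object)
  ns <- vapply(object$units, length, integer(1))
  cat("Session ", object$session_id, ", day ", object$day, "\n", sep = "")
  cat("  duration: ", round(dur, 1), " s; trials: ", length(object$trials),
      "; units: ", length(object$units), "\n", sep = "")
  if (length(ns))
    cat("  spikes/unit: median ", stats::median(ns), " [", min(ns), ", ",
        max(ns), "]; mean rate ",
        round(stats::median(ns) / dur, 2), " sp/s (median unit)\n", sep = "")
  invisible(object)
}

#' Session duration in seconds
#'
#' Time of the last event (or spike) in the session.
#' @param session A `ub_session`.
#' @return Numeric scalar, seconds.
#' @export
session_duration <- function(session) {
  last_ev <- max(vapply(session$trials, function(t)
    max(unlist(t$events), t$drop_times, -Inf), numeric(1)))
  last_sp <- if (length(session$units))
    max(c(vapply(session$units, function(u)
      if (length(u)) max(u) else -Inf, numeric(1)))) else -Inf
  max(last_ev, last_sp)
}

#' Trials of one type, in presentation order
#'
#' @param session A `ub_session`.
#' @param type One of [TRIAL_TYPES].
#' @param probes Include probe trials? Default `FALSE` (rewarded trials only)
#'   for `"initial"` never applies; probes exist only for novel odors.
#' @return List of trials.
#' @export
trials_of_type <- function(session, type, probes = FALSE) {
  keep <- vapply(session$trials, function(t)
    t$trial_type == type && (probes || !t$is_probe), logical(1))
  session$trials[keep]
}
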