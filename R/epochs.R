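## Epoch definitions, per-trial rates, normalized firing, PSTHs and the
## display-only four-bin smoother. All intervals are half-open [start, end)
## so shared edges are never counted twice; analyses use unsmoothed data.

#' Define an analysis epoch
#'
#' An epoch is a time window anchored to a trial event. The standard epochs
#' are: `odor`, 300-1300 ms after initial-odor onset (approximately the
#' novel-odor delivery period); `outcome_flavor`, 2000 ms from first drop
#' delivery; `outcome_number`, 2000 ms starting 1000 ms after first drop
#' (coinciding with the third drop); and `iti`, the 2 s before house-light
#' illumination, used as each trial's baseline.
#'
#' @param name Epoch name.
#' @param anchor Anchor event label (`"drop"` anchors to the first drop).
#' @param start,end Offsets from the anchor, seconds; `end > start`.
#' @return Object of class `ub_epoch`.
#' @export
epoch_def <- function(name, anchor, start, end) {
  if (end <= start) stop("epoch '", name, "': end must exceed start")
  structure(list(name = name, anchor = anchor, start = start, end = end),
            class = "ub_epoch")
}

#' Standard epoch set
#'
#' @return Named list of [epoch_def()] objects: `iti`, `odor`,
#'   `outcome_flavor`, `outcome_number`.
#' @export
default_epochs <- function() {
  list(iti            = epoch_def("iti", "light_on", -2.0, 0.0),
       odor           = epoch_def("odor", "odor_on", 0.3, 1.3),
       outcome_flavor = epoch_def("outcome_flavor", "drop", 0.0, 2.0),
       outcome_number = epoch_def("outcome_number", "drop", 1.0, 3.0))
}

.anchor_time <- function(trial, anchor) {
  if (anchor == "drop") {
    if (length(trial$drop_times)) trial$drop_times[1] else NA_real_
  } else {
    a <- trial$events[[anchor]]
    if (is.null(a)) NA_real_ else a[1]
  }
}

.count_in <- function(spikes, a, b) {
  # spikes ascending; half-open [a, b); binary search via findInterval
  # (left.open counts spikes strictly below each bound)
  findInterval(b, spikes, left.open = TRUE) -
    findInterval(a, spikes, left.open = TRUE)
}

#' Firing rate within an epoch of one trial
#'
#' Spike count in `[anchor + start, anchor + end)` divided by the window
#' length. A missing anchor (e.g. an outcome epoch on an unrewarded probe
#' trial) yields `NA`, not zero.
#'
#' @param spikes Ascending spike-time vector.
#' @param trial A `ub_trial`.
#' @param epoch A [epoch_def()].
#' @return Spikes/s, or `NA_real_` if the anchor event is absent.
#' @export
epoch_rate <- function(spikes, trial, epoch) {
  a <- .anchor_time(trial, epoch$anchor)
  if (is.na(a)) return(NA_real_)
  .count_in(spikes, a + epoch$start, a + epoch$end) / (epoch$end - epoch$start)
}

#' Epoch rates across a list of trials
#'
#' @inheritParams epoch_rate
#' @param trials List of trials.
#' @return Numeric vector, one rate per trial (`NA` where the anchor is
#'   missing).
#' @export
epoch_rates <- function(spikes, trials, epoch) {
  vapply(trials, function(tr) epoch_rate(spikes, tr, epoch), numeric(1))
}

#' Normalized firing
#'
#' The baseline-corrected firing measure used throughout:
#' `normalized firing = period rate - same-trial ITI rate` (spikes/s).
#'
#' @param period_rate,iti_rate Rates in spikes/s (vectors allowed).
#' @return `period_rate - iti_rate`.
#' @export
normalized_firing <- function(period_rate, iti_rate) {
  period_rate - iti_rate
}

#' Binned, ITI-normalized peri-stimulus time histogram
#'
#' Bins spikes in 50-ms bins anchored to odor onset, converts each trial's
#' bin counts to rates, subtracts that trial's ITI rate, and averages
#' across trials.
#'
#' @param spikes Ascending spike-time vector.
#' @param trials List of trials (one condition).
#' @param bin_width Bin width, seconds.
#' @param span Length-2 analysis span relative to odor onset, seconds.
#' @param epochs Epoch set supplying the ITI definition.
#' @return Object of class `ub_psth`: bin left edges (`time`), per-bin mean
#'   normalized rate (`rate`), per-bin mean raw rate (`raw_rate`), total
#'   spike count in span (`n_spikes`), and `n_trials`.
#' @export
binned_psth <- function(spikes, trials, bin_width = 0.05,
                        span = c(-0.5, 1.5), epochs = default_epochs()) {
  if (!length(trials)) stop("binned_psth requires at least one trial")
  n_bins <- round((span[2] - span[1]) / bin_width)
  if (abs(n_bins * bin_width - (span[2] - span[1])) > 1e-9)
    stop("analysis span must be a whole number of bins")
  edges <- span[1] + bin_width * (0:n_bins)
  counts <- matrix(0, nrow = length(trials), ncol = n_bins)
  iti <- epoch_rates(spikes, trials, epochs$iti)
  for (i in seq_along(trials)) {
    a <- .anchor_time(trials[[i]], "odor_on")
    if (is.na(a)) { counts[i, ] <- NA; next }
    rel <- spikes[spikes >= a + span[1] & spikes < a + span[2]] - a
    counts[i, ] <- tabulate(findInterval(rel, edges,
                                         rightmost.closed = FALSE),
                            nbins = n_bins)
  }
  raw <- counts / bin_width
  norm <- sweep(raw, 1, iti, `-`)
  structure(list(time = edges[-length(edges)],
                 rate = colMeans(norm, na.rm = TRUE),
                 raw_rate = colMeans(raw, na.rm = TRUE),
                 n_spikes = sum(counts, na.rm = TRUE),
                 n_trials = length(trials),
                 bin_width = bin_width, span = span),
            class = "ub_psth")
}

#' @export
print.ub_psth <- function(x, ...) {
  cat("<ub_psth> ", length(x$time), " bins of ", x$bin_width * 1000,
      " ms over [", x$span[1], ", ", x$span[2], ") s; ",
      x$n_trials, " trials, ", x$n_spikes, " spikes\n", sep = "")
  invisible(x)
}

#' @export
plot.ub_psth <- function(x, smooth = TRUE, ...) {
  y <- if (smooth) smooth_for_display(x$rate) else x$rate
  graphics::plot(x$time + x$bin_width / 2, y, type = "s",
                 xlab = "time from odor onset (s)",
                 ylab = "normalized firing (sp/s)", ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Four-bin moving average for display
#'
#' Smooths a binned series with a trailing four-bin average moving one bin
#' at a time, with a shrinking window at the left edge (the average of the
#' bins available so far). For plotting only; statistics in this package
#' always use unsmoothed series.
#'
#' @param series Numeric vector, length >= 4.
#' @return Smoothed vector of the same length.
#' @export
smooth_for_display <- function(series) {
  n <- length(series)
  if (n < 4) stop("smooth_for_display requires at least 4 bins")
  vapply(seq_len(n), function(i) mean(series[max(1, i - 3):i]), numeric(1))
}
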