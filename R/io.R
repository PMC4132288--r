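## Delimited-text readers/writers for event and spike tables.
## Events file columns: session_id, day, trial_index, trial_type,
## event_label, drop_index, time_s, is_probe (UTF-8, comma, '.' decimal,
## header row required). Spikes file columns: unit_id, time_s.

.EVENT_COLS <- c("session_id", "day", "trial_index", "trial_type",
                 "event_label", "drop_index", "time_s", "is_probe")
.SPIKE_COLS <- c("unit_id", "time_s")

#' Write a session to delimited text
#'
#' Writes one row per event occurrence (drop events carry `drop_index`
#' 1, 2, 3) plus a spike table of `unit_id, time_s` rows. Files written by
#' this function parse back to an equal session with [read_session()].
#'
#' @param session A `ub_session`.
#' @param events_path,spikes_path Output file paths.
#' @return Invisibly, the session.
#' @export
write_session <- function(session, events_path, spikes_path) {
  rows <- lapply(session$trials, function(tr) {
    labs <- character(); times <- numeric(); didx <- integer()
    for (lab in setdiff(EVENT_LABELS, "drop")) {
      tv <- tr$events[[lab]]
      if (!is.null(tv)) {
        labs <- c(labs, rep(lab, length(tv)))
        times <- c(times, tv)
        didx <- c(didx, rep(NA_integer_, length(tv)))
      }
    }
    if (length(tr$drop_times)) {
      labs <- c(labs, rep("drop", length(tr$drop_times)))
      times <- c(times, tr$drop_times)
      didx <- c(didx, seq_along(tr$drop_times))
    }
    data.frame(session_id = session$session_id, day = session$day,
               trial_index = tr$trial_index, trial_type = tr$trial_type,
               event_label = labs, drop_index = didx,
               time_s = times, is_probe = tr$is_probe,
               stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, rows)
  ev$time_s <- sprintf("%.9f", ev$time_s)
  utils::write.csv(ev, events_path, row.names = FALSE, quote = FALSE,
                   na = "")
  if (length(session$units)) {
    sp <- data.frame(
      unit_id = rep(names(session$units),
                    vapply(session$units, length, integer(1))),
      time_s = sprintf("%.9f", unlist(session$units, use.names = FALSE)),
      stringsAsFactors = FALSE)
  } else {
    sp <- data.frame(unit_id = character(), time_s = character())
  }
  utils::write.csv(sp, spikes_path, row.names = FALSE, quote = FALSE)
  invisible(session)
}

#' Read a session from delimited text
#'
#' Reads an event table and a spike-timestamp table and reconstructs a
#' validated [new_session()] object. All session invariants (ordered event
#' times within trials, the 200-ms initial-to-novel odor gap on compound
#' trials, drop counts, ascending spike times) are enforced on read;
#' violations raise errors naming the offending trial or unit.
#'
#' @param events_path,spikes_path Input file paths.
#' @return A `ub_session`.
#' @export
read_session <- function(events_path, spikes_path) {
  if (!file.exists(events_path)) stop("events file not found: ", events_path)
  if (!file.exists(spikes_path)) stop("spikes file not found: ", spikes_path)
  ev <- utils::read.csv(events_path, stringsAsFactors = FALSE,
                        colClasses = c(time_s = "numeric"))
  missing_cols <- setdiff(.EVENT_COLS, names(ev))
  if (length(missing_cols))
    stop("events file schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  sp <- utils::read.csv(spikes_path, stringsAsFactors = FALSE)
  if (nrow(sp) == 0 && !all(.SPIKE_COLS %in% names(sp))) {
    # empty body is fine as long as the header is right
    sp <- data.frame(unit_id = character(), time_s = numeric())
  }
  if (!all(.SPIKE_COLS %in% names(sp)))
    stop("spikes file schema error: missing column(s) ",
         paste(setdiff(.SPIKE_COLS, names(sp)), collapse = ", "))
  sid <- unique(ev$session_id)
  if (length(sid) != 1) stop("events file contains ", length(sid),
                             " session ids; expected exactly 1")
  day <- unique(as.character(ev$day))
  if (length(day) != 1) stop("events file contains multiple day values")
  trials <- lapply(split(ev, ev$trial_index), function(df) {
    df <- df[order(match(df$event_label, EVENT_LABELS), df$time_s), ]
    evl <- list()
    for (lab in setdiff(EVENT_LABELS, "drop")) {
      tv <- df$time_s[df$event_label == lab]
      if (length(tv)) evl[[lab]] <- tv
    }
    drops <- df[df$event_label == "drop", ]
    drops <- drops[order(drops$drop_index), ]
    new_trial(df$trial_index[1], df$trial_type[1], evl,
              drop_times = drops$time_s,
              is_probe = as.logical(df$is_probe[1]))
  })
  units <- split(sp$time_s, sp$unit_id)   # ascending order validated below
  # preserve first-appearance order from the file
  units <- units[unique(sp$unit_id)]
  new_session(sid, day, trials, units)
}
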