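## Cue- and outcome-selectivity indices and their regressions.
##
## A selectivity index is a unit's normalized firing to a target condition
## minus the mean of its normalized firing to the other three conditions;
## the four indices of a unit over the four targets sum to zero by
## construction. Outcome firing is measured in each condition's
## characteristic window: the first-drop 0-2 s window for initial, blocked
## and flavor trials, and the 1-3 s window (third drop) for number trials.

#' Mean normalized condition rates for one unit
#'
#' @param spikes Ascending spike-time vector.
#' @param session A `ub_session`.
#' @param epochs Epoch set.
#' @return List with numeric vectors `odor` and `outcome`, each named by
#'   [TRIAL_TYPES]: trial-averaged normalized firing (epoch - ITI, sp/s).
#'   Outcome entries are `NA` when no rewarded trials exist for a
#'   condition.
#' @export
unit_condition_rates <- function(spikes, session, epochs = default_epochs()) {
  odor <- outcome <- stats::setNames(rep(NA_real_, 4), TRIAL_TYPES)
  for (tt in TRIAL_TYPES) {
    trs <- trials_of_type(session, tt, probes = TRUE)
    o <- normalized_firing(epoch_rates(spikes, trs, epochs$odor),
                           epoch_rates(spikes, trs, epochs$iti))
    odor[tt] <- mean(o, na.rm = TRUE)
    rew <- trials_of_type(session, tt, probes = FALSE)
    ep <- if (tt == "number") epochs$outcome_number else epochs$outcome_flavor
    if (length(rew)) {
      u <- normalized_firing(epoch_rates(spikes, rew, ep),
                             epoch_rates(spikes, rew, epochs$iti))
      outcome[tt] <- mean(u, na.rm = TRUE)
    }
  }
  list(odor = odor, outcome = outcome)
}

#' Selectivity index
#'
#' `value = x[target] - mean(x[others])` over the four condition rates.
#'
#' @param rates Named numeric vector over [TRIAL_TYPES].
#' @param target Target condition.
#' @return Numeric scalar (spikes/s).
#' @export
selectivity_index <- function(rates, target) {
  stopifnot(all(TRIAL_TYPES %in% names(rates)))
  if (!target %in% TRIAL_TYPES) stop("unknown target '", target, "'")
  if (any(is.na(rates[TRIAL_TYPES])))
    stop("selectivity_index requires all four condition rates")
  unname(rates[target] - mean(rates[setdiff(TRIAL_TYPES, target)]))
}

#' One-sided outlier exclusion
#'
#' A value is excluded iff it exceeds the full-sample mean by more than
#' `k` standard deviations (one-sided; symmetric low values are retained
#' unless `two_sided = TRUE`). Mean and SD are computed on the full set.
#'
#' @param values Numeric vector, n >= 3.
#' @param k SD multiplier (default 3).
#' @param two_sided Also exclude low outliers.
#' @return Logical inclusion mask (`TRUE` = keep).
#' @export
exclude_outliers <- function(values, k = 3, two_sided = FALSE) {
  if (length(values) < 3) stop("exclude_outliers requires n >= 3")
  m <- mean(values); s <- stats::sd(values)
  keep <- values <= m + k * s
  if (two_sided) keep <- keep & values >= m - k * s
  keep
}

#' Selectivity regression
#'
#' OLS of outcome selectivity on cue selectivity after one-sided 3-SD
#' outlier exclusion on the cue indices.
#'
#' @param x Cue (odor) selectivity indices, one per unit.
#' @param y Outcome selectivity indices, matched by unit.
#' @param k Outlier SD multiplier.
#' @param two_sided Passed to [exclude_outliers()].
#' @return List: `r2`, `adj_r2`, `slope`, `p`, `n_before`, `n` (after
#'   exclusion), `included` mask.
#' @export
selectivity_regression <- function(x, y, k = 3, two_sided = FALSE) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("selectivity_regression requires >= 3 units")
  keep <- exclude_outliers(x, k = k, two_sided = two_sided)
  if (sum(keep) < 3)
    stop("selectivity_regression: fewer than 3 units after exclusion")
  st <- pairwise_scatter_stats(x[keep], y[keep])
  list(r2 = st$r2, adj_r2 = st$adj_r2, slope = st$slope, p = st$p,
       n_before = length(x), n = st$n, included = keep)
}

#' Full selectivity analysis of a screened session
#'
#' Computes all eight per-unit selectivity indices (four odor targets, four
#' outcome targets), then runs the matched (flavor cue vs flavor outcome,
#' number cue vs number outcome) and crossed (flavor cue vs number outcome,
#' number cue vs flavor outcome) regressions on the flavor-responsive and
#' number-responsive predictive populations, plus the single-category
#' (flavor-only, number-only) subsets.
#'
#' @param screen A `ub_screen` for the session.
#' @param session The matching `ub_session`.
#' @param k Outlier SD multiplier.
#' @param epochs Epoch set.
#' @return Object of class `ub_selectivity`: list with `indices` (per-unit
#'   data.frame of category and the eight indices) and `regressions`
#'   (data.frame: population, x, y, n_before, n, r2, adj_r2, p).
#' @export
selectivity_analysis <- function(screen, session, k = 3,
                                 epochs = default_epochs()) {
  stopifnot(inherits(screen, "ub_screen"), inherits(session, "ub_session"))
  rows <- lapply(seq_len(nrow(screen)), function(i) {
    uid <- screen$unit_id[i]
    cr <- unit_condition_rates(session$units[[uid]], session, epochs)
    out <- data.frame(unit_id = uid, category = screen$category[i],
                      stringsAsFactors = FALSE)
    for (tt in TRIAL_TYPES) {
      out[[paste0("odor_", tt)]] <- selectivity_index(cr$odor, tt)
      out[[paste0("outcome_", tt)]] <-
        if (any(is.na(cr$outcome))) NA_real_ else
          selectivity_index(cr$outcome, tt)
    }
    out
  })
  idx <- do.call(rbind, rows)
  flavor_resp <- screen$sig_flavor %in% TRUE &
    idx$category %in% c("predictive_flavor_only", "predictive_both")
  number_resp <- screen$sig_number %in% TRUE &
    idx$category %in% c("predictive_number_only", "predictive_both")
  pops <- list(
    flavor_responsive = flavor_resp,
    number_responsive = number_resp,
    flavor_only = idx$category %in% "predictive_flavor_only",
    number_only = idx$category %in% "predictive_number_only")
  pairs <- list(
    c(x = "odor_flavor", y = "outcome_flavor"),
    c(x = "odor_flavor", y = "outcome_number"),
    c(x = "odor_number", y = "outcome_number"),
    c(x = "odor_number", y = "outcome_flavor"))
  reg_rows <- list()
  for (pn in names(pops)) {
    sel <- pops[[pn]]
    use_pairs <- if (grepl("flavor", pn)) pairs[1:2] else pairs[3:4]
    for (pr in use_pairs) {
      x <- idx[[pr[["x"]]]][sel]; y <- idx[[pr[["y"]]]][sel]
      res <- tryCatch(selectivity_regression(x, y, k = k),
                      error = function(e) NULL)
      reg_rows[[length(reg_rows) + 1L]] <- data.frame(
        population = pn, x = pr[["x"]], y = pr[["y"]],
        n_before = if (is.null(res)) sum(sel) else res$n_before,
        n = if (is.null(res)) NA_integer_ else res$n,
        r2 = if (is.null(res)) NA_real_ else res$r2,
        adj_r2 = if (is.null(res)) NA_real_ else res$adj_r2,
        slope = if (is.null(res)) NA_real_ else res$slope,
        p = if (is.null(res)) NA_real_ else res$p,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(indices = idx, regressions = do.call(rbind, reg_rows),
                 k = k),
            class = "ub_selectivity")
}

#' @export
print.ub_selectivity <- function(x, ...) {
  cat("<ub_selectivity> ", nrow(x$indices), " units; ", x$k,
      "-SD one-sided outlier exclusion\n", sep = "")
  print(x$regressions, digits = 3)
  invisible(x)
}
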