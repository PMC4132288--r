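## Odor-responsiveness screen (Bonferroni-corrected, one-tailed t tests of
## odor-epoch vs same-trial ITI firing) and the derived unit taxonomy.

#' Unit taxonomy categories
#'
#' The mutually exclusive categories assigned by [classify_unit()]:
#' salience (responsive to all four odors), the three predictive
#' subtypes, the single-odor selective types, other multi-odor
#' combinations, and nonresponsive.
#'
#' @format Character vector of length 8.
#' @export
UNIT_CATEGORIES <- c("salience", "predictive_number_only",
                     "predictive_flavor_only", "predictive_both",
                     "blocked_only", "initial_only", "other_combination",
                     "nonresponsive")

# one-tailed (increase) t test robust to zero-variance degeneracy
.increase_t <- function(x, y, paired) {
  if (paired) {
    d <- x - y
    if (stats::sd(d) == 0) {
      m <- mean(d)
      return(list(t = if (m == 0) 0 else sign(m) * Inf,
                  p = if (m > 0) 0 else 1, n = length(d)))
    }
    ht <- stats::t.test(x, y, paired = TRUE, alternative = "greater")
  } else {
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      m <- mean(x) - mean(y)
      return(list(t = if (m == 0) 0 else sign(m) * Inf,
                  p = if (m > 0) 0 else 1, n = length(x)))
    }
    ht <- stats::t.test(x, y, alternative = "greater", var.equal = TRUE)
  }
  list(t = unname(ht$statistic), p = ht$p.value, n = length(x))
}

#' Screen one unit for odor responsiveness
#'
#' For each of the four odor conditions, compares per-trial odor-epoch
#' firing against the same trials' ITI firing with a one-tailed t test for
#' an increase, flagged at the Bonferroni-corrected threshold
#' `alpha = 0.05/4 = 0.0125`. The paired test (default) tests per-trial
#' odor-minus-ITI differences; an unpaired pooled-variance variant is
#' available.
#'
#' @param spikes Ascending spike-time vector.
#' @param session A `ub_session`.
#' @param alpha Per-odor significance threshold.
#' @param min_trials Minimum rewarded-or-probe trials per condition below
#'   which the unit is marked unscreenable.
#' @param paired Paired (per-trial) or unpaired two-sample t test.
#' @param epochs Epoch set ([default_epochs()]).
#' @return A one-row data.frame with per-odor `t_*`, `p_*`, `sig_*`,
#'   `dir_*` (`"increase"`/`"decrease"`/`"none"`), `n_*`, plus
#'   `screenable`.
#' @export
screen_unit <- function(spikes, session, alpha = 0.0125, min_trials = 5L,
                        paired = TRUE, epochs = default_epochs()) {
  out <- list()
  screenable <- TRUE
  for (tt in TRIAL_TYPES) {
    trs <- trials_of_type(session, tt, probes = TRUE)
    odor <- epoch_rates(spikes, trs, epochs$odor)
    iti <- epoch_rates(spikes, trs, epochs$iti)
    ok <- !is.na(odor) & !is.na(iti)
    odor <- odor[ok]; iti <- iti[ok]
    if (length(odor) < min_trials) {
      screenable <- FALSE
      out[[tt]] <- list(t = NA_real_, p = NA_real_, sig = NA, dir = NA, n = length(odor))
      next
    }
    res <- .increase_t(odor, iti, paired)
    m <- mean(odor) - mean(iti)
    out[[tt]] <- list(t = res$t, p = res$p,
                      sig = res$p < alpha,        # significant => increase
                      dir = if (m > 0) "increase" else
                        if (m < 0) "decrease" else "none",
                      n = res$n)
  }
  row <- data.frame(screenable = screenable, stringsAsFactors = FALSE)
  for (tt in TRIAL_TYPES) {
    row[[paste0("t_", tt)]]   <- out[[tt]]$t
    row[[paste0("p_", tt)]]   <- out[[tt]]$p
    row[[paste0("sig_", tt)]] <- out[[tt]]$sig
    row[[paste0("dir_", tt)]] <- out[[tt]]$dir
    row[[paste0("n_", tt)]]   <- out[[tt]]$n
  }
  row
}

#' Classify a screened unit
#'
#' Categories are exhaustive and mutually exclusive: `salience` (significant
#' increase to all four odors); `predictive_number_only`,
#' `predictive_flavor_only`, `predictive_both` (significant to the number
#' and/or flavor odor but not all four); `blocked_only`; `initial_only`;
#' `other_combination` (remaining multi-odor patterns without number or
#' flavor); `nonresponsive`.
#'
#' @param result One row from [screen_unit()] (or a logical vector of four
#'   significance flags named by [TRIAL_TYPES]).
#' @return Category string.
#' @export
classify_unit <- function(result) {
  if (is.data.frame(result)) {
    if (!isTRUE(result$screenable[1])) stop("unit is not screenable")
    sig <- unlist(result[1, paste0("sig_", TRIAL_TYPES)])
    names(sig) <- TRIAL_TYPES
  } else {
    sig <- result[TRIAL_TYPES]
  }
  if (all(sig)) return("salience")
  if (sig[["number"]] || sig[["flavor"]]) {
    if (sig[["number"]] && sig[["flavor"]]) return("predictive_both")
    if (sig[["number"]]) return("predictive_number_only")
    return("predictive_flavor_only")
  }
  if (sig[["blocked"]] && !sig[["initial"]]) return("blocked_only")
  if (sig[["initial"]] && !sig[["blocked"]]) return("initial_only")
  if (sig[["blocked"]] && sig[["initial"]]) return("other_combination")
  "nonresponsive"
}

#' Screen and classify every unit of a session
#'
#' @inheritParams screen_unit
#' @return Object of class `ub_screen`: a data.frame with one row per unit
#'   (`unit_id`, `day`, per-odor test columns, `category`), with the screen
#'   settings stored as attributes. Unscreenable units get category `NA`.
#' @export
screen_units <- function(session, alpha = 0.0125, min_trials = 5L,
                         paired = TRUE, epochs = default_epochs()) {
  if (!length(session$units)) stop("session has no units")
  rows <- lapply(names(session$units), function(uid) {
    r <- screen_unit(session$units[[uid]], session, alpha, min_trials,
                     paired, epochs)
    cbind(data.frame(unit_id = uid, day = session$day,
                     stringsAsFactors = FALSE), r)
  })
  res <- do.call(rbind, rows)
  res$category <- NA_character_
  ok <- res$screenable
  res$category[ok] <- vapply(which(ok), function(i)
    classify_unit(res[i, ]), character(1))
  structure(res, class = c("ub_screen", "data.frame"),
            alpha = alpha, min_trials = min_trials, paired = paired)
}

#' @export
print.ub_screen <- function(x, ...) {
  cat("<ub_screen> ", nrow(x), " units (alpha = ", attr(x, "alpha"),
      ", ", if (attr(x, "paired")) "paired" else "unpaired",
      " one-tailed t)\n", sep = "")
  print(table(factor(x$category, levels = UNIT_CATEGORIES),
              useNA = "ifany"))
  invisible(x)
}

#' @export
summary.ub_screen <- function(object, ...) {
  print(object)
  pc <- population_counts(object)
  cat("odor-responsive: ", pc$odor_responsive, "/", pc$n_screened,
      "; predictive (union): ", pc$predictive,
      "; two-major-category fraction among responsive: ",
      round(pc$two_major_fraction, 3), "\n", sep = "")
  invisible(pc)
}

#' Category counts and derived population fractions
#'
#' @param categories A `ub_screen` (its `category` column is used), or a
#'   character vector of categories. Multiple screens (e.g. per-day) can be
#'   combined with `rbind` before counting.
#' @return List with the per-category `counts` and `fractions`, the number
#'   screened, `odor_responsive` (units significant to any odor),
#'   `predictive` (union of the predictive categories), `salience`, and
#'   `two_major_fraction` (salience + predictive over odor-responsive).
#' @export
population_counts <- function(categories) {
  if (inherits(categories, "ub_screen")) categories <- categories$category
  categories <- categories[!is.na(categories)]
  if (!length(categories)) stop("no classified units")
  counts <- table(factor(categories, levels = UNIT_CATEGORIES))
  n <- sum(counts)
  resp <- n - counts[["nonresponsive"]]
  pred <- counts[["predictive_number_only"]] +
    counts[["predictive_flavor_only"]] + counts[["predictive_both"]]
  sal <- counts[["salience"]]
  list(counts = counts, fractions = counts / n, n_screened = n,
       odor_responsive = resp, predictive = pred, salience = sal,
       two_major_fraction = if (resp > 0) (sal + pred) / resp else NA_real_)
}
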