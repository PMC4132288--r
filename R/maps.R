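## Trial-by-sliding-window differential-firing heat maps with per-cell
## one-tailed significance. Windows move away from novel-odor onset in
## 50-ms increments; the default window length is 200 ms (300 ms available
## for the wider variant used in some displays). Statistics are computed on
## unsmoothed values; the four-bin smoother is applied by the plot method
## only.

MAP_CONTRASTS <- c("novel_vs_initial", "number_vs_blocked",
                   "flavor_vs_blocked")

# per-trial window anchor: novel-odor onset, or its equivalent position
# (odor onset + 200 ms) on initial trials, which carry no novel odor
.novel_anchor <- function(trial) {
  a <- trial$events$novel_odor_on
  if (!is.null(a)) a[1] else trial$events$odor_on[1] + 0.2
}

#' Trial-by-window differential-firing map
#'
#' For each of the first `n_trials` presentations of each condition and
#' each sliding window, computes the per-unit difference in ITI-normalized
#' window firing specified by the contrast, averaged across units:
#' `novel_vs_initial` averages the blocked, number and flavor terms before
#' subtracting the initial term; `number_vs_blocked` and
#' `flavor_vs_blocked` are simple differences. Each cell also carries a
#' one-tailed one-sample t test of the per-unit differences against zero
#' (uncorrected, `alpha = 0.05`), as used for significance maps.
#'
#' @param population A `ub_session` (all of its units are used), or a list
#'   of `list(spikes =, session =)` pairs for units recorded in different
#'   sessions.
#' @param contrast One of [MAP_CONTRASTS].
#' @param n_trials Number of condition presentations (trial axis), default
#'   the first 10.
#' @param window Window length in seconds (0.200 default, 0.300 optional).
#' @param step Window-start increment, seconds.
#' @param alpha Per-cell significance threshold (uncorrected).
#' @param p_adjust Optional multiple-testing correction across cells
#'   (`"none"` default, or a method for [stats::p.adjust()], e.g. `"BH"`).
#' @param units Optional character vector restricting which units of a
#'   `ub_session` population enter the map.
#' @param epochs Epoch set.
#' @return Object of class `ub_diffmap` with matrices `value` (mean
#'   differential normalized firing, spikes/s), `p`, `sig`, `degenerate`
#'   and `n` (trials x windows), plus `trials`, `window_starts`, `window`,
#'   `contrast`, `alpha`.
#' @export
difference_map <- function(population, contrast = MAP_CONTRASTS,
                           n_trials = 10L, window = 0.2, step = 0.05,
                           alpha = 0.05, p_adjust = "none", units = NULL,
                           epochs = default_epochs()) {
  contrast <- match.arg(contrast)
  pop <- .as_population(population, units)
  conds <- switch(contrast,
                  novel_vs_initial = list(pos = c("blocked", "number",
                                                  "flavor"),
                                          neg = "initial"),
                  number_vs_blocked = list(pos = "number", neg = "blocked"),
                  flavor_vs_blocked = list(pos = "flavor", neg = "blocked"))
  # window starts from novel-odor onset over the 800-ms novel-odor period;
  # the last window may extend to odor offset + 200 ms
  starts <- seq(0, 0.8, by = step)
  starts <- starts[starts + window <= 1.0 + 1e-9]
  n_w <- length(starts)
  diffs <- array(NA_real_, c(length(pop), n_trials, n_w))
  for (u in seq_along(pop)) {
    spikes <- pop[[u]]$spikes; sess <- pop[[u]]$session
    by_cond <- lapply(unique(c(conds$pos, conds$neg)), function(tt)
      trials_of_type(sess, tt, probes = FALSE))
    names(by_cond) <- unique(c(conds$pos, conds$neg))
    for (k in seq_len(n_trials)) {
      get_k <- function(tt) {
        trs <- by_cond[[tt]]
        if (length(trs) < k) return(rep(NA_real_, n_w))
        tr <- trs[[k]]
        a <- .novel_anchor(tr)
        bnd <- a + c(starts, starts + window)
        nlt <- findInterval(bnd, spikes, left.open = TRUE)
        rates <- (nlt[n_w + seq_len(n_w)] - nlt[seq_len(n_w)]) / window
        rates - epoch_rate(spikes, tr, epochs$iti)
      }
      pos <- rowMeans(do.call(cbind, lapply(conds$pos, get_k)))
      neg <- get_k(conds$neg)
      diffs[u, k, ] <- pos - neg
    }
  }
  value <- p <- nmat <- matrix(NA_real_, n_trials, n_w)
  degen <- matrix(FALSE, n_trials, n_w)
  for (k in seq_len(n_trials)) for (w in seq_len(n_w)) {
    d <- diffs[, k, w]
    d <- d[!is.na(d)]
    nmat[k, w] <- length(d)
    if (length(d) < 3) next
    value[k, w] <- mean(d)
    if (stats::sd(d) == 0) {
      # zero-variance cell: p = 1 if mean <= 0, else degeneracy marker
      if (mean(d) <= 0) p[k, w] <- 1 else degen[k, w] <- TRUE
    } else {
      p[k, w] <- stats::t.test(d, alternative = "greater")$p.value
    }
  }
  if (p_adjust != "none") {
    pv <- as.vector(p)
    pv[!is.na(pv)] <- stats::p.adjust(pv[!is.na(pv)], method = p_adjust)
    p <- matrix(pv, n_trials, n_w)
  }
  sig <- (!is.na(p) & p < alpha) | degen
  dimnames(value) <- dimnames(p) <- dimnames(sig) <- dimnames(degen) <-
    dimnames(nmat) <- list(trial = seq_len(n_trials),
                           window_start = sprintf("%.2f", starts))
  structure(list(value = value, p = p, sig = sig, degenerate = degen,
                 n = nmat, trials = seq_len(n_trials),
                 window_starts = starts, window = window,
                 contrast = contrast, alpha = alpha,
                 n_units = length(pop)),
            class = "ub_diffmap")
}

.as_population <- function(population, units = NULL) {
  if (inherits(population, "ub_session")) {
    ids <- if (is.null(units)) names(population$units) else units
    missing_ids <- setdiff(ids, names(population$units))
    if (length(missing_ids))
      stop("unknown unit id(s): ", paste(missing_ids, collapse = ", "))
    lapply(ids, function(uid)
      list(spikes = population$units[[uid]], session = population))
  } else if (is.list(population)) {
    stopifnot(all(vapply(population, function(p)
      all(c("spikes", "session") %in% names(p)), logical(1))))
    population
  } else stop("population must be a ub_session or a list of ",
              "(spikes, session) pairs")
}

#' Per-cell significance of a difference map
#'
#' The one-tailed t test of per-unit differential firing against zero is
#' computed by [difference_map()]; this accessor returns its per-cell
#' matrices.
#'
#' @param map A `ub_diffmap`.
#' @return List with matrices `p`, `sig` (flagged at the map's alpha),
#'   `degenerate` and `n`.
#' @export
significance_map <- function(map) {
  stopifnot(inherits(map, "ub_diffmap"))
  list(p = map$p, sig = map$sig, degenerate = map$degenerate, n = map$n)
}

#' @export
print.ub_diffmap <- function(x, ...) {
  cat("<ub_diffmap> ", x$contrast, ": ", nrow(x$value), " trials x ",
      ncol(x$value), " windows (", x$window * 1000, " ms, starts every ",
      diff(x$window_starts[1:2]) * 1000, " ms); ", x$n_units,
      " units\n", sep = "")
  cat("  mean differential firing ", signif(mean(x$value, na.rm = TRUE), 3),
      " sp/s; flagged cells ", sum(x$sig, na.rm = TRUE), "/",
      sum(!is.na(x$p) | x$degenerate), " at p < ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Plot a difference map
#'
#' Heat image of the map (trials on the y axis, window start on the x
#' axis). Values are smoothed along the window axis with the four-bin
#' display smoother unless `smooth = FALSE`; the significance view is
#' never smoothed.
#'
#' @param x A `ub_diffmap`.
#' @param which `"value"` or `"sig"`.
#' @param smooth Apply the display smoother to the value view.
#' @param ... Passed to [graphics::image()].
#' @export
plot.ub_diffmap <- function(x, which = c("value", "sig"), smooth = TRUE,
                            ...) {
  which <- match.arg(which)
  if (which == "value") {
    m <- x$value
    if (smooth && ncol(m) >= 4)
      m <- t(apply(m, 1, smooth_for_display))
    pal <- grDevices::hcl.colors(64, "RdBu", rev = TRUE)
    graphics::image(x$window_starts, x$trials, t(m), col = pal,
                    xlab = "window start from novel odor onset (s)",
                    ylab = "trial", main = x$contrast, ...)
  } else {
    graphics::image(x$window_starts, x$trials, t(x$sig * 1),
                    col = c("grey90", "red3"),
                    xlab = "window start from novel odor onset (s)",
                    ylab = "trial",
                    main = paste0(x$contrast, " (p < ", x$alpha, ")"), ...)
  }
  invisible(x)
}
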