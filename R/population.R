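## Population-level statistics: within-subject ANOVA on binned population
## activity, the continuity-corrected sign test, per-unit contrasts, count
## comparisons, OLS scatter statistics, and the display-only signed square
## root.

#' Construct a test-result record
#'
#' @param test Test name.
#' @param statistic Statistic value.
#' @param stat_name `"t"`, `"F"`, `"Z"` or `"chisq"`.
#' @param df Degrees of freedom (vector for F).
#' @param p P value.
#' @param tails 1 or 2.
#' @param n Sample size.
#' @return A one-row data.frame of class `ub_test`.
#' @export
test_result <- function(test, statistic, stat_name, df, p, tails, n) {
  stopifnot(is.na(p) || (p >= 0 && p <= 1))
  structure(data.frame(test = test, stat_name = stat_name,
                       statistic = statistic,
                       df1 = df[1], df2 = if (length(df) > 1) df[2] else NA,
                       p = p, tails = tails, n = n,
                       stringsAsFactors = FALSE),
            class = c("ub_test", "data.frame"))
}

#' Repeated-measures ANOVA on population activity
#'
#' Two-way within-subject ANOVA with the unit as the subject. In `"bin"`
#' mode the factors are time bin (50 ms) and odor; in `"half"` mode the
#' novel-odor period is averaged into two 500-ms means and the factors are
#' half and odor. Conventional within-subject degrees of freedom are
#' reported, without sphericity correction by default (Greenhouse-Geisser
#' available by flag).
#'
#' @param data Long data.frame with columns `unit`, `odor`, `value` and the
#'   second factor (`bin` or `half`).
#' @param factors Character vector naming the two within-subject factors,
#'   e.g. `c("bin", "odor")` or `c("half", "odor")`.
#' @param gg Apply a Greenhouse-Geisser epsilon correction to the p values.
#' @return Data.frame of class `ub_test`, one row per effect (two main
#'   effects and the interaction).
#' @export
rm_anova <- function(data, factors = c("bin", "odor"), gg = FALSE) {
  stopifnot(all(c("unit", "value", factors) %in% names(data)))
  data$unit <- factor(data$unit)
  if (nlevels(data$unit) < 2)
    stop("rm_anova requires at least 2 units")
  f1 <- factors[1]; f2 <- factors[2]
  data[[f1]] <- factor(data[[f1]]); data[[f2]] <- factor(data[[f2]])
  if (any(is.na(data$value))) stop("rm_anova requires complete data")
  tab <- table(data$unit, data[[f1]], data[[f2]])
  if (any(tab != 1))
    stop("rm_anova requires one value per unit x ", f1, " x ", f2, " cell")
  if (stats::var(data$value) < 1e-20)
    stop("rm_anova degeneracy: zero within-subject variance")
  form <- stats::as.formula(paste0(
    "value ~ ", f1, " * ", f2,
    " + Error(unit/(", f1, " * ", f2, "))"))
  fit <- stats::aov(form, data = data)
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    a <- stratum[[1]]
    terms <- trimws(rownames(a))
    for (i in seq_along(terms)) {
      if (terms[i] == "Residuals") next
      Fv <- a[i, "F value"]; df1 <- a[i, "Df"]
      df2 <- a["Residuals", "Df"]
      if (!is.finite(Fv))
        stop("rm_anova degeneracy: zero within-subject variance for term ",
             terms[i])
      p <- a[i, "Pr(>F)"]
      if (gg) {
        eps <- .gg_epsilon(data, terms[i], f1, f2)
        p <- stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE)
      }
      rows[[terms[i]]] <- test_result(paste0("rm_anova:", terms[i]), Fv,
                                      "F", c(df1, df2), p, 2,
                                      nlevels(data$unit))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ub_test", "data.frame")
  out
}

# Greenhouse-Geisser epsilon from the covariance of the relevant
# within-subject contrast (computed on the term's cell means per unit)
.gg_epsilon <- function(data, term, f1, f2) {
  vars <- strsplit(term, ":")[[1]]
  cell <- interaction(data[vars], drop = TRUE)
  m <- tapply(data$value, list(data$unit, cell), mean)
  k <- ncol(m)
  if (k < 2) return(1)
  S <- stats::cov(m)
  C <- diag(k) - 1 / k            # double-centering projector
  Sd <- C %*% S %*% C
  lam <- eigen(Sd, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  eps <- sum(lam)^2 / ((k - 1) * sum(lam^2))
  min(max(eps, 1 / (k - 1)), 1)
}

#' Continuity-corrected sign test
#'
#' Nonparametric test on the count of positive vs negative paired
#' differences. Exact ties are dropped; with `k` positives of `n`,
#' `Z = (k - 0.5 - n/2) / sqrt(n/4)` with the half-unit continuity
#' correction applied toward the majority (for 38 positives of 43 this
#' gives Z = 4.88). An exact two-sided binomial p value is reported
#' alongside, and is the better reference for `n < 20`.
#'
#' @param diffs Numeric vector of paired differences (or `k` and `n`
#'   directly via `k =`/`n =`, leaving `diffs` missing).
#' @param k,n Alternatively, the number of positive differences and the
#'   number of non-tied pairs.
#' @return List of class `ub_signtest`: `k`, `n`, `Z`, `p` (normal,
#'   two-sided), `p_exact` (binomial, two-sided).
#' @export
sign_test <- function(diffs, k = NULL, n = NULL) {
  if (is.null(k)) {
    d <- diffs[diffs != 0]
    n <- length(d)
    k <- sum(d > 0)
  }
  if (n < 1) stop("sign test: no non-tied differences")
  half <- n / 2
  Z <- if (k == half) 0 else (k - 0.5 * sign(k - half) - half) / sqrt(n / 4)
  p <- 2 * stats::pnorm(-abs(Z))
  p_exact <- stats::binom.test(k, n)$p.value
  structure(list(k = k, n = n, Z = Z, p = min(p, 1), p_exact = p_exact),
            class = "ub_signtest")
}

#' @export
print.ub_signtest <- function(x, ...) {
  cat("Sign test: ", x$k, " positive of ", x$n,
      "; Z = ", round(x$Z, 2), ", p = ", signif(x$p, 3),
      " (exact binomial p = ", signif(x$p_exact, 3), ")\n", sep = "")
  invisible(x)
}

#' Per-unit condition contrast
#'
#' Two-sample t test (pooled variance, two-tailed, alpha = 0.05) on a
#' unit's per-trial normalized odor-epoch rates between two conditions;
#' used to outline individually selective units in population scatter
#' plots.
#'
#' @param spikes Ascending spike-time vector.
#' @param session A `ub_session`.
#' @param odorA,odorB Condition names from [TRIAL_TYPES].
#' @param min_trials Minimum trials per condition.
#' @param epochs Epoch set.
#' @return One-row `ub_test` data.frame.
#' @export
per_unit_contrast <- function(spikes, session, odorA, odorB,
                              min_trials = 5L, epochs = default_epochs()) {
  get_norm <- function(tt) {
    trs <- trials_of_type(session, tt, probes = TRUE)
    normalized_firing(epoch_rates(spikes, trs, epochs$odor),
                      epoch_rates(spikes, trs, epochs$iti))
  }
  x <- stats::na.omit(get_norm(odorA)); y <- stats::na.omit(get_norm(odorB))
  if (length(x) < min_trials || length(y) < min_trials)
    stop("per_unit_contrast: fewer than ", min_trials,
         " trials in a condition")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    m <- mean(x) - mean(y)
    return(test_result(paste0(odorA, "_vs_", odorB),
                       if (m == 0) 0 else sign(m) * Inf, "t",
                       length(x) + length(y) - 2,
                       if (m == 0) 1 else 0, 2, length(x) + length(y)))
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  test_result(paste0(odorA, "_vs_", odorB), unname(ht$statistic), "t",
              unname(ht$parameter), ht$p.value, 2, length(x) + length(y))
}

#' Signed square root (display transform)
#'
#' `sign(x) * sqrt(|x|)`; used only to visualize population spread in
#' scatter plots. Statistics are always computed on untransformed rates.
#'
#' @param x Numeric.
#' @return Transformed values.
#' @export
signed_sqrt <- function(x) sign(x) * sqrt(abs(x))

#' Compare two category counts against equal expectation
#'
#' Goodness-of-fit chi-square of `(n1, n2)` against a 50/50 split, df = 1.
#' Both the uncorrected and the Yates-corrected statistic are reported.
#'
#' @param n1,n2 Non-negative counts.
#' @return List: `chisq`, `p`, `chisq_yates`, `p_yates`, `df`, `n`.
#' @export
count_comparison <- function(n1, n2) {
  if (n1 + n2 <= 0) stop("count_comparison: both counts are zero")
  e <- (n1 + n2) / 2
  chisq <- sum((c(n1, n2) - e)^2 / e)
  d <- max(abs(n1 - e) - 0.5, 0)
  chisq_y <- 2 * d^2 / e
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE),
       chisq_yates = chisq_y,
       p_yates = stats::pchisq(chisq_y, 1, lower.tail = FALSE),
       df = 1L, n = n1 + n2)
}

#' Scatter statistics for paired per-unit measures
#'
#' Ordinary least-squares fit of `y` on `x` with plain and adjusted
#' R-squared and the slope p value, plus the per-unit difference scores
#' (`x - y`) plotted as the diagonal histogram in population scatter
#' figures.
#'
#' @param x,y Per-unit values (equal length, n >= 3).
#' @return List: `r2`, `adj_r2`, `slope`, `intercept`, `p`, `n`, `diff`.
#' @export
pairwise_scatter_stats <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("pairwise_scatter_stats requires n >= 3")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p = sm$coefficients[2, 4], n = length(x), diff = x - y)
}
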