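---
title: "Epoch-normalized single-unit analysis of odor unblocking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epoch-normalized single-unit analysis of odor unblocking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unblockr)
```

## The analysis problem

In a Pavlovian unblocking experiment a rat first learns that an *initial*
odor predicts a specific reward (two drops of flavored milk). On compound
trials the initial odor (200 ms) is followed by one of three novel odors
(800 ms): a *blocked* odor followed by the unchanged reward, a *number*
odor followed by an extra third drop, and a *flavor* odor followed by an
equally preferred but differently flavored milk. Blocking theory predicts
that only the number and flavor odors — the ones whose outcomes deviate
from the prediction — can acquire associative significance. Single units
recorded during learning are screened for odor responses and classified
into populations whose dynamics (novelty-driven vs. learning-driven) and
outcome coupling are then quantified.

`unblockr` implements that analysis chain end-to-end and pairs it with a
task-faithful synthetic data generator, so every statistic can be
exercised and calibrated without recorded data.

## Firing measures

All firing measures derive from one baseline correction,

$$\text{normalized firing} = \text{period rate} - \text{ITI rate}
\quad[\text{spikes/s}],$$

where the ITI window is the 2 s before house-light onset of the same
trial. The standard epochs are:

* **odor**: 300–1300 ms after initial-odor onset (approximately the
  novel-odor delivery period, applied uniformly to all four trial types);
* **outcome (flavor-type)**: 2 s from the first drop;
* **outcome (number-type)**: 2 s starting 1 s after the first drop, i.e.
  from the third drop;
* **ITI**: the 2 s before house-light onset.

All windows are half-open `[start, end)` so a spike on a shared edge is
counted exactly once. Missing anchors (e.g. outcome epochs on unrewarded
probe trials) propagate as missing values, never as zeros.

## Screening and taxonomy

Each unit is screened per odor condition with a one-tailed t test of
per-trial odor-epoch rates against the same trials' ITI rates, flagged at
the Bonferroni-corrected threshold $\alpha = 0.05/4 = 0.0125$. The paired
(per-trial) test is the default because the pairing controls slow rate
drift; a pooled-variance unpaired variant is available
(`screen_unit(..., paired = FALSE)`) since the original description does
not fix this choice. Sessions from different learning days are screened
independently and reported per day and pooled.

Categories are exhaustive and mutually exclusive: *salience* (significant
increase to all four odors), *predictive* (number and/or flavor but not
all four, subdivided into number-only / flavor-only / both),
*blocked-only*, *initial-only*, *other combinations*, *nonresponsive*.
Note that the predictive definition is taken literally: a unit significant
to, say, number and blocked (but not all four) counts as predictive
number-only. Decreases in firing are recorded but never flagged.

## Population statistics

* `sign_test()` uses the continuity-corrected normal approximation
  $Z = (k - 0.5\,\mathrm{sign}(k - n/2) - n/2)/\sqrt{n/4}$ with the
  correction applied toward the majority; this variant reproduces the
  canonical worked value $Z = 4.88$ for 38 positives of 43. An exact
  binomial p value is always reported alongside and is the better
  reference below $n = 20$.
* `rm_anova()` is a two-way within-subject ANOVA (subject = unit) via
  `stats::aov` error strata, either over 50-ms bins × odor or over the
  two 500-ms halves of the novel-odor period × odor. Conventional
  within-subject degrees of freedom are reported; no sphericity
  correction is applied by default (Greenhouse–Geisser by `gg = TRUE`).
* `count_comparison()` reports both the uncorrected and Yates-corrected
  goodness-of-fit chi-square against a 50/50 split. For counts (31, 37)
  these give 0.53 and 0.37 respectively; no standard construction gives a
  smaller value, so both are always reported.
* `pairwise_scatter_stats()` and `selectivity_regression()` report plain
  and adjusted R²; the plain value is used for all pass/fail properties,
  the adjusted one is included because population reports sometimes show
  small negative values, which only an adjusted statistic can produce.

## Difference maps

`difference_map()` computes, for each of the first 10 presentations of
each condition and each 200-ms window sliding from novel-odor onset in
50-ms steps, the across-unit mean difference in ITI-normalized window
firing. The novelty contrast averages the three novel-odor terms before
subtracting the initial term; on initial trials (which have no novel
odor) windows anchor to the position the novel odor would occupy, 200 ms
after odor onset. Both 200-ms and 300-ms windows are supported because
both lengths appear in descriptions of this analysis; 200 ms is the
default. Window starts run from 0 to 0.8 s, and the last window may
extend to odor offset + 200 ms.

Per-cell significance is a one-sample, one-tailed t test of the per-unit
differences against zero at uncorrected $\alpha = 0.05$ (a
Benjamini–Hochberg option exists, off by default). Zero-variance cells
are reported as degeneracies — flagged with a marker if their common
difference is positive, assigned $p = 1$ otherwise — rather than as t
statistics.

**Calibration note.** Under an exchangeable null the two-condition
contrasts (number-vs-blocked, flavor-vs-blocked) have an exactly
symmetric per-unit difference distribution and the per-cell t rejects at
the nominal 5% (measured 5.1–5.2% at 16 units). The three-vs-one novelty
contrast subtracts one noisy term from a mean of three, so its null
difference distribution is negatively skewed at typical baseline rates;
the upper-tailed t then runs slightly hot (≈5.8% at 31 units, ≈6.3% at
16, baseline 5 spikes/s). This is a property of the method on that
contrast, not of the implementation; calibration claims in the test
suite therefore use the symmetric contrasts.

## Selectivity indices and regressions

A unit's selectivity for a target condition is its normalized firing to
the target minus the mean over the other three conditions; the four
indices of a unit sum to zero by construction (checked to machine
precision). Outcome firing is measured in each condition's characteristic
window — first-drop window for initial, blocked and flavor trials, the
third-drop window for number trials — so crossed analyses (e.g. flavor
cue vs. number outcome) simply substitute which index is paired.

One consequence of the bracket formula worth knowing: the crossed outcome
index contains $-1/3$ of the matched outcome response through its
"mean of the other three" term, so even when crossed outcome amplitudes
are exactly zero the crossed regression R² is not driven to zero. The
matched regression still dominates the crossed one replicate-by-replicate
under matched coupling, which is the property the package asserts.

Outlier exclusion is one-sided, exactly as the field describes it: a unit
is dropped from a regression iff its cue index exceeds the full-sample
mean by more than 3 SD (a two-sided variant is available by flag). With
full-sample statistics a point can only exceed 3 SD when
$(n-1)/\sqrt{n} > 3$, i.e. $n \ge 11$ — tiny populations can never lose a
unit, which is the intended conservative behavior.

## The synthetic generator

`generate_session()` draws a task-structured session — interleaved trial
types (no more than 3 consecutive of a kind), house light → odor port
entry → 1-s odor sampling (200 ms initial + 800 ms novel on compound
trials) → well entry → 2–3 drops — and one spike train per unit from an
additive inhomogeneous-Poisson rate model sampled by thinning:

$$\lambda_u(t) = \text{baseline} + \sum_{\text{epochs}} \text{gated
amplitude terms}.$$

* **Salience units** respond to the odor stream on every trial with a
  common amplitude, plus a novelty transient on novel odors that decays
  within the trial from novel-odor onset (time constant 0.25 s) and
  across presentations as $e^{-(k-1)/\tau_{\text{trial}}}$.
* **Predictive units** acquire responses to their preferred novel
  odor(s) as $1 - e^{-(k-1)/\tau_{\text{learn}}}$ — zero on the first
  presentation by construction — and fire during the matched outcome
  epoch with an amplitude coupled across units to their cue amplitude
  (`cue_outcome_coupling`, the mechanism behind the cue–outcome
  regressions).
* **Blocked-only / initial-only / nonresponsive units** fill out the
  taxonomy with constant or absent responses.

The exponential trial dynamics are the simplest monotone family
consistent with the qualitative descriptions the design follows; nothing
quantitative is claimed about real learning curves. Defaults: 30 trials
per novel odor per learning day (the low end of the 30–60 used in
training), 6-s inter-trial interval (unspecified in the source; chosen so
the 2-s pre-light baseline always exists), baseline 5 spikes/s and
asymptotic response amplitudes of 8 spikes/s (typical cortical
magnitudes), 15 unrewarded probe trials per novel odor on the probe day.
Day-2 sessions continue the presentation indices where day 1 ended, so
novelty is exhausted and learning near asymptote — reproducing the
day-specificity of the novelty pattern.

Behavioral ground truth follows the same logic: response latencies carry
a novelty surcharge that decays across presentations, and probe-trial
well times start higher after number/flavor odors than after the blocked
odor and decay across the 15 probes.

Property-specific study conditions, fixed once from a power analysis of
the rate model: the trial-1-peak map property uses 30–60 salience units
with novelty amplitude 15 spikes/s and trial decay 1 (an onset-locked
transient strong enough that the map argmax is not a coin flip at
single-trial, 200-ms resolution); the cue–outcome coupling properties use
heterogeneous populations (between-unit amplitude SD 4 spikes/s on an
8-spikes/s mean, 16 units per class, 20 trials per condition) because
cross-neuron regressions are only informative when between-unit amplitude
spread dominates trial-sampling noise.

What the generator does *not* emulate: biophysical spiking (no
refractoriness, bursting or adaptation), correlated noise between
simultaneously recorded units beyond amplitude coupling, electrode drift,
sorting errors, or session-to-session unit identity. Passing tests
therefore validate the analysis chain's statistical behavior on
Poisson-like data, not its robustness to those artifacts.

## Numerical and API choices

* Half-open intervals everywhere; spike counting by binary search on the
  sorted spike vector.
* The four-bin display smoother is a trailing moving average with a
  shrinking window at the left edge; it and the signed square root exist
  only in plotting paths, and a test poisons both to prove no statistic
  ever calls them.
* Degenerate inputs fail loudly: zero within-subject variance in the
  ANOVA, all-tied sign tests, sub-floor trial counts (default floor 5
  per condition) and empty populations raise errors rather than NAs.
* Determinism: a session is a pure function of its configuration seed;
  units get independent derived sub-seeds. The pipeline manifest records
  seed, configuration and package version, and reruns are byte-identical.
* Problem sizes used by the acceptance properties (2000 null units for
  screen calibration, 200 null maps, 200 coupling replicates, a 60-unit
  recovery session) were chosen to give binomial confidence intervals a
  few thousandths wide while keeping a full run in a few minutes on one
  core.

## Known limitations

* The initial-odor condition is measured on reminder trials only; the
  200-ms initial-odor segment of compound trials is not used for the
  "initial" condition.
* The well-time integration window for probe behavior (5 s after port
  exit) is an explicit package default; no standard value exists.
* The novelty-contrast significance map inherits the mild anticonservatism
  described above; treat its uncorrected per-cell flags as descriptive,
  as the originating analyses do.
* Consumption-test schedules (two-bottle preference, conditioned flavor
  aversion) are supported as measures (`preference_ratio`) and schedule
  templates only; no aversion-learning model is implemented.
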