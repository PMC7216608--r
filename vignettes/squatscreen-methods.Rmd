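---
title: "Methods: scoring and evaluating single-leg-squat screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring and evaluating single-leg-squat screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The single-leg squat (SLS) is a clinical movement-screening test: the
subject squats on one leg while an assessor judges whether the knee stays
over the foot ("pass") or collapses medially past the second toe ("fail",
dynamic knee valgus).  Marker-free depth cameras make it possible to
replace the visual judgement with a measured quantity.  The score this
package implements is the **net trajectory angle (NTA)**: within each squat
phase (descent to the deepest point, then ascent), the knee's frontal-plane
horizontal position is regressed on its vertical position, and the NTA is
the angle between that fitted "line of best fit" and the vertical axis.
The accompanying **net shift** is the horizontal travel of the fitted line
over the phase's vertical excursion, so `|shift| = tan(|NTA|) * excursion`
holds by construction.

Evaluating such a device requires two studies that this package makes fully
reproducible on synthetic data:

* **Test-retest reliability** of the four variables (left/right knee,
  way down/way up) across two occasions: nonparametric descriptives,
  Wilcoxon signed-rank for systematic change, Spearman correlation, an
  agreement ICC from a two-way variance decomposition, SEM, the smallest
  detectable change, and Bland-Altman limits of agreement.
* **Construct validity** against dichotomous visual ratings: the way-down
  medial displacement is dichotomized in 2-degree steps up to 20 degrees,
  and each cut-off is evaluated by percent agreement, Cohen's kappa,
  sensitivity/specificity, predictive values, and the binary-test AUC.

## Sign conventions

Internally the generator uses a *medial-positive* convention: a positive
true angle means the knee travels toward the body midline during the
phase, whichever leg is squatting.  Scored results are reported in the
screening-report convention: **negative NTA = medial displacement for the
left knee** (lateral for the right), positive = medial for the right
(lateral for the left).  `medial_displacement()` maps back
(`left: -NTA`, `right: +NTA`).  The coordinate frame puts +x toward the
subject's right; the mapping is unit-tested through mirror symmetry:
negating x negates the raw angle, and mirroring plus swapping legs leaves
the medial displacement unchanged.

## Fitting and segmentation decisions

The fitting procedure behind the "line of best fit" is not publicly
specified by any vendor, so this package commits to **ordinary least
squares of horizontal on vertical position**.  The vertical coordinate is
the better-conditioned regressor during a squat (it spans the full
excursion monotonically within a phase), and position-on-position fitting
is invariant to the squat's tempo.  The alternative reading — averaging
the instantaneous 30 Hz tangents — amplifies sensor noise at the
near-stationary top and bottom of the squat and was rejected.

The turning point is the **first** sample attaining the minimum height
("first arrival at the bottom"); ties on a flat bottom therefore break to
the earliest sample, which keeps segmentation deterministic.  Down and up
phases are fitted independently, since real reports show different angles
per direction.  Degenerate inputs error early: monotone height (no squat),
fewer than two samples per phase, or zero vertical excursion.

## The synthetic cohort: a stated world

No recorded cohort ships with the package; the generator emulates the
screening-study design the analysis targets:

* **Design**: 37 subjects x 2 legs x 2 occasions (= 148 recordings, 296
  phase measures), 30 samples per phase at 30 Hz.
* **Variance model**: the true displacement angle of a recording is
  `mean + a + b + e`, with `a ~ N(0, sigma2_p)` per subject-leg,
  `b ~ N(0, sigma2_o)` per subject-leg-occasion, and `e ~ N(0, sigma2_res)`
  per phase measure.  Legs are simulated independently (screening studies
  treat the two legs as independent measures), and the occasion effect is
  drawn per subject-occasion rather than as a global shift so that
  `sigma2_o` enters the SEM exactly as the agreement formula requires.  A
  separate `occasion_shift` flag adds a global T2 shift for scenarios with
  a genuine systematic (e.g. learning) effect.
* **Default components** `sigma2_p = 216`, `sigma2_o = 10`,
  `sigma2_res = 87` deg^2 were derived once from the reliability scale the
  package targets: an agreement ICC of 0.69 with SEM near 9.85 deg implies
  `sigma2_error = SEM^2 ~ 97` and
  `sigma2_p = ICC / (1 - ICC) * sigma2_error ~ 216`.  The split of the
  error into occasion and residual parts is not identifiable from an ICC
  and SEM alone; 10/87 keeps the occasion effect small, matching the
  mostly non-significant occasion differences such studies report.
* **Phase means** default to 2 deg (down) and -3 deg (up),
  medial-positive: descent tends slightly medial, ascent slightly lateral,
  consistent with grand medians of a few degrees in magnitude.
* **Trajectory shape**: the height follows a half-cosine per phase (smooth
  start and stop, one global minimum); depth 15 cm and 1 s per phase are
  plausible clinical values, config-exposed because no reference value
  exists.  Horizontal sensor noise defaults to 0.5 cm, the order of
  depth-camera joint jitter.
* **Contamination**: each recording is independently flagged `easy_mode`
  (supported squat variant, excluded from analysis) or `missing`; default
  rates 0.11 and 0.04 reproduce the scale of the reference bookkeeping
  (32 easy-mode + 11 missing/improper of 296).  An improper recording is
  representable as status `no_go`.
* **Raters**: the true state is "fail" when the way-down medial
  displacement is at or beyond `label_threshold` (default 6 deg).  Two
  raters independently flip the truth with probability `rater_error_prob`
  (default 0.1); disagreements are adjudicated by a third simulated rater
  from the same error model, mimicking a consensus procedure.

These defaults are the generator's stated world.  They were chosen once
from the design above and are not tuned to make tests pass.

What the generator does **not** emulate: multi-joint biomechanics (only
the knee point is produced), skeleton-tracking artefacts such as occlusion
spikes or identity swaps, between-leg correlation, rater drift, or
recording-specific squat depth/tempo variation.  A green test therefore
establishes the correctness of the *analysis pipeline* under the stated
model, not the field performance of any camera system.

## Reliability: numerical choices

* **Variance components** come from the two-way ANOVA mean squares with
  one observation per cell; negative component estimates are truncated at
  zero (standard ANOVA practice).  The agreement ICC is
  `sigma2_p / (sigma2_p + sigma2_o + sigma2_res)`.  Note that when the
  occasion mean square falls below the error mean square (so `sigma2_o`
  truncates to 0), this truncated-component ICC coincides with the
  consistency ICC; with positive components it equals the classical
  absolute-agreement single-measure estimator exactly.
* **ICC confidence limits** use the F-based absolute-agreement
  single-measure interval (McGraw & Wong).  The reference study does not
  state its CI method, so printed intervals elsewhere are not a
  correctness target; our implementation is pinned against an independent
  implementation (pingouin's ICC(A,1)) in the test suite.
* **SEM and SDC**: `SEM = sqrt(sigma2_o + sigma2_res)`,
  `SDC = 1.96 * sqrt(2) * SEM`.  Both are computed at full precision;
  rendered reports round half-up to two decimals.
* **Wilcoxon signed-rank**: zero differences are dropped (Wilcoxon's
  original rule) and tied magnitudes get midranks.  The null distribution
  is enumerated exactly (subset-sum convolution over doubled midranks) for
  up to 25 non-zero differences, which covers cohorts of this size; larger
  samples use the normal approximation with continuity correction and
  tie-corrected variance.  Two-sided p-values use the symmetric tail mass.
* **Spearman** p-values use the t approximation; quartiles use linear
  interpolation (type 7).  The conventional correlation bands leave
  [0.5, 0.6) unnamed; we fold it into "fair" so every value gets a label.

## Validity: numerical choices

* **Tie rule**: a measurement at exactly the cut-off counts as *fail*
  (`>=`).  The descriptions "exceeds the cut-off" and "goes 2 degrees
  medial" are ambiguous at the boundary; `>=` makes the sweep reproducible
  and is unit-tested.
* **CI methods**: Clopper-Pearson (exact binomial) for Se/Sp/PPV/NPV —
  consistent with upper bounds of exactly 1.0 at high cut-offs — the
  large-sample (Fleiss-Cohen-Everitt) SE for kappa, and Hanley-McNeil for
  the AUC.
* **Binary AUC**: a single-cut-off test has a two-segment ROC through
  `(0,0)`, `(1 - Sp, Se)`, `(1,1)`, so `AUC = (Se + Sp) / 2` identically;
  this identity is asserted for every row of the sweep.
* Only the **way-down** displacement enters the validity comparison (the
  way up shows systematic occasion differences in this setting), and the
  best cut-off is the AUC argmax with first-on-ties.
* Degenerate tables are flagged rather than silently dropped: `Pe = 1`
  makes kappa undefined; a zero denominator makes the affected predictive
  value undefined.

## Determinism and budgets

Every random draw is routed through seeds derived from one master seed:
the same configuration produces byte-identical cohorts, score tables and
report files.  The Monte-Carlo parameter-recovery check (200 replicates of
a 500-subject cohort at ICC 0.75) runs with 5 samples per phase instead of
30: for noiseless trajectories the scored angle is exact at any sampling
density, so this is purely a runtime reduction, not a change of the
experiment.

## Known limitations

* The ICC is computed on data that need not be normally distributed (the
  same caveat applies to any ANOVA-based ICC); interpret it with care on
  heavily skewed variables.
* The reliability analysis expects exactly two occasions; multi-occasion
  designs are filtered to the first two.
* The exact count tables behind published rounded proportions cannot be
  reconstructed from two-decimal values, so cell-level agreement with any
  particular published table is out of scope; identities that are pure
  functions of printed inputs (SDC from SEM, AUC from Se/Sp, availability
  percentages from exclusion counts) are reproduced exactly.
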