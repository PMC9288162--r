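---
title: "Submaximal and peak oxygen uptake efficiency slope: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Submaximal and peak oxygen uptake efficiency slope: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

The oxygen uptake efficiency slope (OUES) summarises how effectively a
person extracts oxygen as ventilation rises during a graded exercise test.
It is the slope *a* of the log-linear model

$$\dot V O_2 = a \,\log_{10} \dot V_E + b,$$

with oxygen uptake in mL·min⁻¹ and minute ventilation in L·min⁻¹. Because
the relation is close to linear on the log scale throughout exercise, *a*
can in principle be estimated from a submaximal portion of the test — which
matters for people who cannot, or should not, exercise to exhaustion. The
question this package operationalises: if the fitting window is cut at the
aerobic threshold (AerT, first ventilatory threshold) or at the anaerobic
threshold (AnT, respiratory compensation point) rather than at peak
exercise, does the submaximal slope agree with the peak slope well enough
to substitute for it in healthy young males?

`cpetoues` implements the whole chain: breath-by-breath reduction,
automated landmark detection, windowed OUES fitting with anthropometric
normalisation, and a method-comparison battery. A synthetic-data module
generates ramp tests and cohorts with known ground truth so every stage is
testable without any proprietary cart export.

## Signal reduction

Breath-by-breath gas exchange is noisy (5–10% coefficient of variation per
breath is typical). The reduction mirrors common metabolic-cart practice:

* a **six-breath centred moving average** per gas channel. Centred rather
  than trailing, because a trailing window would delay every downstream
  landmark by roughly half a window; edges use the truncated available
  window so the series keeps its length.
* **10-s time bins** aligned to *t* = 0, left-closed right-open, each bin
  the mean of the breaths whose timestamps fall inside it. Empty bins are
  absent rather than zero-filled. The respiratory exchange ratio (RER) of a
  bin is recomputed as the ratio of the bin means (ratio of means, not mean
  of ratios), since landmark tables report RER at averaged points.
* breath timestamps are treated as breath-end times; cart export
  conventions differ, and the choice shifts every bin consistently so it
  does not affect within-test comparisons.

Landmark values are read as **30-s window means** of the binned series; at
the end of the test the window is anchored to the final 30 s of data.

## Landmark detection

The ventilatory-equivalents method is automated as a
*nadir-plus-sustained-rise* rule:

* **AerT**: the minimum of VE/VO₂ followed by a rise sustained over the
  next 60 s while VE/VCO₂ is not yet rising; secondary criterion, the
  V-slope breakpoint of VCO₂ against VO₂.
* **AnT**: the minimum of VE/VCO₂ with a sustained rise; secondary
  criterion, the breakpoint of VE against VCO₂.

Both secondary criteria share one engine: an exhaustive two-segment
least-squares search over all split points leaving at least three points
per segment, without a continuity constraint, ties resolved toward the
earlier breakpoint. The reported breakpoint abscissa is the first point
governed by the upper segment.

Two numerical points deserve emphasis:

1. *The nadir of a ventilatory-equivalent curve is flat.* A pointwise
   minimum of the binned ratio therefore wanders by minutes under realistic
   noise. The detector instead anchors the search within ±30 s of the
   secondary-criterion breakpoint time, locates the basin on a 5-bin
   running mean of the ratio, and refines to the raw-bin minimum within ±2
   bins. On noiseless series this recovers the injected threshold at bin
   resolution; under 5% breath noise the detected threshold VO₂ stays
   within about ±5% of the injected value on average.
2. *Rejection is reserved for qualitatively wrong series.* A candidate is
   refused when the ratio was already rising on approach (more than 8% of
   its level over the preceding 90 s) or, for AerT, when VE/VCO₂ rises by
   more than 10% of its level during the sustain window. These margins are
   several standard deviations of the slope noise seen at 5% breath CV —
   they catch series with no nadir at all, not noisy-but-valid tests.
   Primary/secondary disagreement beyond 30 s flags the result for review
   (mirroring multi-reviewer adjudication practice) instead of failing.

Peak VO₂ is the best 30-s rolling mean among windows ending in the final
minute of exercise; the RER = 1.0 crossing is linearly interpolated at the
first upward crossing sustained for 30 s. Detected landmarks must be
ordered (AerT before AnT, both below peak).

## OUES windows and fits

All fits use the 10-s binned series, not raw breaths. Excluded from every
window: the two pre-exercise minutes (rest plus unloaded pedalling — the
protocol contains exactly two, and we read the "resting period" exclusion
as covering both) and the first ramp minute. The peak window additionally
drops a terminal VO₂ plateau when one exists. No published plateau
criterion accompanies the exclusion rule, so the package defines one: the
terminal contiguous run (≥ 30 s) of 30-s windows whose local VO₂ slope
falls below one third of the ramp-driven expectation (10.3 mL·min⁻¹·W⁻¹ ×
ramp rate); the fraction and the gain are exposed as arguments. Windows are
inclusive of the bin at the landmark and must hold at least 5 bins.

The fit itself is ordinary least squares of VO₂ on log₁₀ VE. Base 10
follows the original OUES formulation; a natural-log fit would scale *a* by
ln 10 ≈ 2.303, and the base is recorded in the fit object. Normalised
variants divide *a* by body mass, fat-free mass, and Haycock body surface
area (0.024265 · BM^0.5378 · H^0.3964, BM kg, H cm).

## The agreement battery

With peak OUES as reference *x* and a submaximal OUES as comparison *y*
(n = 50 pairs in the study design):

* **OLP (geometric-mean) regression**: slope sign(r)·SD(y)/SD(x) through
  the bivariate mean; 95% CIs from the classical B-statistic construction
  (B = t²₀.₉₇₅,ₙ₋₂(1 − r²)/(n − 2), slope CI = slope(√(B+1) ± √B)).
  Proportional bias is declared when the slope CI excludes 1, fixed bias
  when the intercept CI excludes 0.
* **Typical percentage error**: SD(x − y)/√2 as a percentage of the grand
  mean of all pooled observations (the denominator is a documented choice —
  the convention leaves it open), with 10% as the customary acceptability
  bound.
* **ICC(3,1)**: two-way mixed-effects, consistency, single measures, from
  the subject/method mean squares, CI via F-distribution bounds. The form
  is fixed and recorded; a consistency ICC deliberately ignores a fixed
  shift between methods.
* **Bland-Altman on percentage differences** (matching how such plots are
  drawn for ratio-scale physiology): per-subject
  100·(y − x)/((x + y)/2) in `agreement_report()` so the mean difference
  carries the submaximal-minus-peak sign; limits mean ± 1.96 SD.
* **Paired t**, and a one-way **repeated-measures ANOVA** across the three
  windows with Bonferroni-corrected pairwise tests (factor 3) and partial
  η² = SS₍cond₎/(SS₍cond₎ + SS₍err₎). Zero-variance differences are
  reported with a degeneracy flag (p = 1 when the vectors are identical,
  p = 0 for a constant nonzero shift) rather than erroring.

Pearson bands: ≥ 0.8 very strong, 0.6–0.8 moderately strong, 0.3–0.5 fair,
< 0.3 poor; the unassigned interval [0.5, 0.6) maps to fair, and boundaries
are closed upward. ICC bands: ≥ 0.75 excellent, 0.60–0.75 good, 0.40–0.60
fair, < 0.40 poor.

## What the generator emulates — and what it does not

`simulate_cpet()` builds a ramp cycle test: 1-min rest, 1-min unloaded
pedalling, then 15/20/25 W·min⁻¹. Noiseless VO₂ follows the ramp demand
through a 30-s first-order lag with an aerobic cost of 10.3 mL·min⁻¹·W⁻¹.
Two modes:

* **loglinear** — VE is obtained by inverting the OUES relation, so the
  true slope is the configured value exactly. Used for parameter-recovery
  studies.
* **threephase** — VCO₂ is piecewise linear in VO₂ with a knee at the
  injected AerT, VE is piecewise linear in VCO₂ with a knee at the injected
  AnT (default thresholds at 53% and 78% of peak VO₂, ventilation 26.2 L
  per L VCO₂ below the compensation point, steepening ×1.9 above it). RER
  is exactly 0.88 at and below the AerT knee and exactly 1.02 at the AnT
  knee. With a single VCO₂ knee those two anchors exhaust the degrees of
  freedom, so peak RER is emergent (≈ 1.09 under defaults) rather than
  prescribed; the observed peak RER in comparable cohorts (≈ 1.16 ± 0.10)
  sits within a standard deviation of it. True OUES in this mode is defined
  as the fit to the noiseless trace over the standard window.

Per-breath noise is multiplicative log-normal (mean 1, CV 0.05 by default)
applied independently to VO₂, VCO₂ and VE; breath intervals shrink linearly
from 4 s to 1.5 s as ventilatory frequency rises. `simulate_cohort()` draws
body mass 68.0 ± 11.4 kg, height 176.3 ± 7.0 cm, fat mass 16.9 ± 5.2%, peak
VO₂ 43.8 ± 7.3 mL·min⁻¹·kg⁻¹ and threshold fractions 0.53 ± 0.09 /
0.78 ± 0.09 from truncated normals, and additionally varies ventilatory
efficiency (the VE–VCO₂ slope, ±2.5) so that OUES differs between equally
fit participants.

Real breath data differ in ways the generator does not model: aberrant
breaths (coughs, swallows) that survive a six-breath average, slow
components and drifting VO₂ kinetics beyond one first-order lag,
cadence-related power oscillation, and ventilatory-equivalent curves whose
nadirs are broader or double-bottomed. Passing tests on generated data
therefore demonstrate correctness of the estimators under the stated model
and noise — not robustness to every artefact a metabolic cart can produce.

`simulate_reference_cohort()` is different in kind: it does not simulate
breaths at all, but draws a per-participant table (peak and submaximal
OUES, landmark VO₂, anthropometrics) from a multivariate normal model
calibrated to published cohort summary statistics for healthy young males
(means/SDs per window, peak-vs-submaximal correlations √0.32 and √0.86, a
0.88 OUES–VO₂peak correlation, body mass correlated 0.6 with peak VO₂).
It is a synthetic stand-in for the study's per-participant supplementary
table: statistics computed from it verify that the agreement battery
recovers those published summaries from data with that structure, not that
any individual's measurements are reproduced. The AerT–AnT OUES correlation
is not published; it is fixed at 0.65, comfortably inside the
positive-definiteness interval [0.22, 0.83] implied by the two published
correlations. The sampling SD of, e.g., the typical error at n = 50 is
roughly 1 percentage point, which is the scale of run-to-run variation to
expect from the acceptance script under different seeds.

## Numerical conventions and degenerate inputs

* Bin membership is left-closed right-open; a partially filled final bin is
  retained.
* `piecewise_breakpoint()` requires ≥ 8 sorted points and refuses
  degenerate x; on collinear input every split fits and the earliest wins.
* `fit_oues()` refuses windows with zero variance in log₁₀ VE; windows
  shorter than 5 bins are refused upstream.
* Threshold recovery is quantified at bin resolution: the detector returns
  bin midpoints, and the continuous injected time can sit up to half a bin
  from the nearest midpoint, so "one-bin recovery" is asserted as
  |Δt| ≤ 1.5 × bin width.
* Cohort statistics use complete cases only; failed stages degrade the
  participant record with a named error rather than aborting the run, and
  incompleteness is reported, never imputed.

## Problem sizes

The test suite and the acceptance script use: 50-participant cohorts
(matching the study design), 200 log-linear simulations for the
recovery-bias estimate, 1,000 random fixtures per statistic for the
oracle-equivalence sweep, and ~14-minute simulated tests of roughly 370
breaths each. These sizes give sampling noise comfortably below the
tolerances asserted while keeping a full run in the low minutes on a single
core.

## Known limitations

* Threshold detection leans on the secondary (gas-domain breakpoint)
  criterion to localise the search; on pathologies that break the V-slope
  assumption (e.g. glycogen-depleted tests) the anchor may mislead.
* Detected thresholds carry a small early bias (order-statistic selection
  on a flat nadir), visible as cohort threshold fractions a few points
  below the injected ones at 5% breath noise.
* The OLP confidence intervals are the classical large-sample construction;
  a bootstrap alternative is not currently wired in.
* OUES at fixed percentages of exercise duration (75%/90%), lactate-based
  thresholds and heart-rate-deflection methods are out of scope.
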