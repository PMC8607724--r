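---
title: "Methods: gamma analysis and TG-218 process control in tomoqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gamma analysis and TG-218 process control in tomoqa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomoqa)
```

## What the package models

Pre-treatment patient-specific QA for helical tomotherapy compares a planned
dose distribution against a measurement made with a cylindrical diode array.
The comparison is scored by the gamma index; the resulting gamma passing
rates (GP%) accumulate into a longitudinal QA database that a clinic
monitors with statistical process control, following the AAPM TG-218
methodology, and correlates with planning parameters to find predictors of
QA failure. `tomoqa` implements that entire chain — dose containers and
file I/O, the gamma engine, clinic-specific control limits with bootstrap
uncertainty, cohort statistics — together with a synthetic-data generator
that emulates the statistical structure of such a database, so every stage
is testable without clinical data.

## Dose model

Planned doses live on a regular grid (`dose_grid`; axis order `(y, x)` or
`(z, y, x)`, mm coordinates, Gy doses; default step 1.87 mm, the
high-resolution planning export). Measurements are point doses at diode
positions, unwrapped from the cylinder to a plane (`dose_points`): `u` is
arc length along the circumference (0 at the top, clockwise from the gantry
view), `v` the axial position. The comparison is two-dimensional on this
unwrapped plane. The detector geometry (default: 105 mm radius, 10 mm
diode spacing, 210 mm axial extent) is a generic cylindrical-array layout;
every operation works for any valid geometry.

Two plain-text formats (`csv-grid`, `csv-points`) keep fixtures
human-readable; DICOM RT Dose reading/writing supports the explicit-VR
little-endian encoding with dose-grid scaling, which is what planning
systems export. A scalar output correction (session-wise machine output
check) multiplies measured doses and composes multiplicatively; it is
bounded to (0.5, 1.5) purely to catch unit errors.

## The gamma engine

For a measured reference point $r$ with dose $d_r$, the gamma index against
the planned evaluation dose $D_e$ is

$$\gamma(r) = \min_p \sqrt{\frac{\lVert p - r\rVert^2}{\delta^2}
  + \frac{(D_e(p) - d_r)^2}{\Delta D^2}},$$

with $\delta$ the DTA criterion (mm) and $\Delta D$ the dose criterion in
Gy: a fixed percentage of the evaluation maximum under *global*
normalization, or of the local reference dose under *local* normalization.
A point passes iff $\gamma \le 1$ (exactly 1 passes); points below the
low-dose threshold (default 10% of the evaluation maximum, in both modes)
are reported but excluded from GP%. The defaults are the TG-218 clinical
settings: 3%/2 mm with a 10% threshold; 3%/3 mm is kept for comparison
with older literature. The measured points are the scored reference and
the planned grid is the searched evaluation — the sparse distribution is
scored, the dense one searched.

Design choices worth knowing:

* **The minimum is continuous, not a lattice value.** A coarse lattice
  (step `interp_step_mm`, default DTA/10) locates the basin; a successive
  lattice-zoom refinement (9×9 lattice spanning ±2h at spacing h/2, halving
  h each round) then converges to the basin minimum. The zoom is used
  instead of a compass/pattern search because the bilinearly interpolated
  dose surface has kinked valleys along grid-cell edges on which compass
  steps stall. The test suite holds the engine to within $10^{-6}$ of an
  independent brute-force minimiser (dense half-step lattice plus
  restarted Nelder-Mead polish).
* **The search radius cannot truncate the answer.** `max_search_radius_mm`
  (default 3·DTA) is a search budget, auto-expanded to
  $\delta \cdot \gamma_0$ — where $\gamma_0$ is the zero-offset dose-only
  gamma — whenever that bound exceeds it. Beyond that radius the distance
  term alone exceeds $\gamma_0$, so the reported value is provably the
  unconstrained minimum.
* **Degenerate cases error loudly.** An all-below-threshold comparison has
  no defined GP% and raises an error rather than returning 0 or 100; local
  normalization requires a positive threshold so a zero-dose denominator
  cannot occur among evaluated points.
* A relative slack of $10^{-9}$ on the $\gamma \le 1$ comparison absorbs
  floating-point noise in ratios like $0.03/0.03$; it is far below any
  physically meaningful dose or distance difference.

Useful orderings follow from the definition and are property-tested:
enlarging DTA or the dose criterion never increases any gamma; local
normalization never yields a higher GP% than global at equal criteria;
global-mode gamma is invariant to a common dose scale; GP% is invariant to
a common translation.

## Plan-complexity metrics

Per plan: TTDF (delivery time / dose per fraction, s/cGy — a simple
complexity surrogate), and the leaf-open-time descriptors min/mean/max/SD.
The LOT array is treated as one flat vector over projections and leaves;
SD uses the n−1 denominator, and a singleton array has SD 0 by convention
so degenerate plans remain processable. Cohort summaries report mean, SD
and range per parameter plus the field-width split over the fixed
10/25/50 mm classes.

## TG-218 process control

On the deliverable subset (GP% under 3%/2 mm global strictly above 90%,
the universal action limit; failing plans stay in the database but outside
SPC), the clinic-specific limits on an individuals/moving-range chart are

$$AL_{cs} = 100 - 3\sqrt{\sigma^2 + (\bar{x} - 100)^2}, \qquad
  TL_{cs} = \bar{x} - 2.660\,\overline{mR},$$

with $\bar{x}, \sigma$ the period mean and (n−1) SD and $\overline{mR}$
the mean absolute difference of consecutive deliveries; 2.660 = 3/d₂ with
d₂ = 1.128, the standard individuals-chart constant. The baseline period
uses the first 40 deliveries in date order; subsequent evaluations cover
six-month periods. A period is *in control* when no delivery falls below
its action limit.

Uncertainty comes from a nonparametric bootstrap (default 10,000
resamples, percentile intervals). Resampled sequences are used in drawn
order for the order-dependent tolerance limit; whether temporal order
should instead be preserved block-wise is genuinely open — with the iid
generator both choices coincide in distribution, and the drawn-order
convention keeps the statistic well-defined for arbitrary resamples.
Drift between consecutive periods is flagged when the bootstrap intervals
of either limit are disjoint — a deliberately conservative rule whose
false-positive rate on stationary series is property-tested (≤10% of
seeded runs); a Kruskal–Wallis comparison across periods is available from
the same toolbox as a complementary check. Per-site limits can be obtained
by filtering records before monitoring; the default pipeline computes
global limits only.

## Cohort statistics

Site-wise GP% comparison uses Kruskal–Wallis (tie-corrected, chi-square
reference) followed, when significant, by all pairwise two-sided Wilcoxon
rank-sum tests with Bonferroni correction (adjusted p = min(1, m·p), m =
k(k−1)/2). The choice of rank-sum tests as the post-hoc is a design
decision: GP% distributions are heavily left-skewed, so rank tests match
the omnibus test's assumptions.

Before the n-way ANOVA, planning parameters are screened greedily in a
fixed, documented order (complexity surrogates first: MF, TTDF, mean-LOT,
max-LOT, pitch, gantry period, couch speed, then the remaining raw
fields): a parameter is excluded when its absolute Pearson correlation
with an already-included parameter reaches 0.8; the log records the
culprit pair, r, and the correlation-test p. The screening rule in the
underlying methodology ("p > 0.05 and/or r < 0.8") is internally
ambiguous; |r| < 0.8 is implemented as the operative inclusion rule with
the p-value reported for transparency. Constant parameters are excluded
with a reason, not an error.

The ANOVA itself is a main-effects-only linear model with Type II
(marginal) sums of squares, computed as drop-one F tests — for
main-effects models these are exactly the Type II tests, which a
`car::Anova` cross-check in the test suite confirms. Continuous predictors
enter as tertile bins; how continuous covariates entered the original
n-way analysis is unstated, and tertiles keep every factor categorical
with balanced cells. Type-I error calibration of both tests (rejection
rate within [3.5%, 6.5%] at α = 0.05 under the null) and power against an
injected −3 GP% site effect (≥80%) are exercised in the test suite by
simulation.

## The synthetic-data generator

The generator is first-class, tested code; its defaults define the study
conditions everywhere else in the package.

* **Dose pairs.** Planned fields are mixtures of 2–5 Gaussian blobs at
  1.87 mm spacing — smooth, strictly positive, with realistic gradients
  but no anatomical structure. The "measurement" samples the perturbed
  plan at the diode lattice; perturbations apply in the order global scale
  → rigid shift → hotspot (cosine-tapered bump) → per-point Gaussian noise
  relative to local dose, with negative doses clipped at zero and counted.
* **Plan cohorts.** Default size 395 over a two-year span. Sites are drawn
  with probabilities 28/32/77/71/84/52/41 over
  abdomen/brain/head-and-neck/lungs/pelvis/prostate/others; field width
  from the 2.1/92.0/5.9% split over 10/25/50 mm. Numeric parameters come
  from truncated normals with the reference cohort's mean/SD/range
  (e.g. MF 1.68 ± 0.28 in [1.10, 2.79], pitch 0.39 ± 0.06, dose/fraction
  219.8 ± 62.6 cGy in [160, 500]); truncation means realized moments sit
  slightly off the nominal values, and tests use realized-moment oracles.
  Derived quantities are kept internally consistent — TTDF is recomputed
  as time/dose and couch speed as travel/time — so their marginal moments
  are emergent rather than imposed. LOT arrays are simulated per plan
  (truncated normal above the 18 ms mechanical floor, with a 5% admixture
  of near-floor openings that drives min-LOT to sit just above 18 ms as in
  clinical sinograms) and the descriptor columns are recomputed from the
  arrays, so plan-record invariants hold by construction.
* **GP% models.** Per-criteria truncated/clipped normals — defaults
  3%G/2mm: 97.6 ± 2.6, 3%L/2mm: 90.9 ± 5.0, 3%G/3mm: 99.2 ± 1.3,
  3%L/3mm: 96.0 ± 3.0; the two local-normalization SDs and the 3%L/3mm
  mean are free parameters (no reference values exist) chosen to mirror
  the wider spread local normalization shows. A shared per-plan latent
  factor (loading 0.7) correlates the four criteria, since measurement
  quality is plan-specific. Per-site offsets default to zero — the
  reference data fix no per-site means — and are set explicitly in power
  simulations. `make_gp_series` generates monitoring series with an
  optional level shift (and optional SD change) at a chosen changepoint,
  dated across four six-month periods.
* One structural limitation matters when interpreting results: an
  upper-truncated normal always has SD smaller than its distance to the
  bound, so a realized pair like mean 97.6 / SD 2.6 is unreachable for a
  truncated normal capped at 100 — real GP% data achieve it through
  skewness and outliers the generator does not model. Calibrations
  therefore target realized limit pairs (AL, TL) rather than raw moments
  where exactness matters; `truncnorm_parent()` inverts realized moments
  into parent parameters where they are feasible.

What passing tests do *not* show about real data: no anatomical realism,
no autocorrelated delivery drift within a period (the moving range of real
series is smaller than iid sampling implies, so real TL_cs sits above the
iid expectation), no detector calibration error structure, no heavy GP%
tails.

## Problem sizes and numerical choices

The test suite runs everything at desk scale, chosen so the full suite
completes in a few minutes while keeping sampling error well inside the
asserted tolerances: oracle equivalence on 100 random pairs of ≤50×50
grids with 28 diodes each; bootstrap coverage with 200 outer replications
of n = 40 at 10,000 resamples; calibration with 1,000 null simulations;
drift detection over 40 seeded series of length 384. Bootstrap seeds are
derived deterministically from the user seed (sub-seeds offset per stage),
so every pipeline run is bit-reproducible. Reports are versioned JSON
validated against a bundled structural schema.
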