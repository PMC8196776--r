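---
title: "Methods: physiological profiling and race-time modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: physiological profiling and race-time modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xcprofiler)
```

This vignette documents the models behind `xcprofiler`, their assumptions,
the tunable parameters and the design decisions taken where the methodology
literature leaves choices open. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## 1. The measurement models

### Lactate-power curve and thresholds

An incremental step test (150 W start, +25 W per 5 min stage, stopping once
blood lactate exceeds 4 mmol/L) yields per-stage (power, lactate) pairs plus
a resting baseline. We fit an ordinary least-squares polynomial to the
stages; the baseline is excluded because it is not taken at a work rate.

* **Degree 3** is used for the fixed-concentration markers and Dmax. This is
  the convention of the lactate-analysis tools used in field practice, and a
  cubic is flexible enough to track the convex rise without oscillating on
  5–10 stages.
* **Degree 4** is required for the second lactate threshold, defined as the
  power of maximal *acceleration* (maximum of the second derivative). A
  cubic's second derivative is linear and is maximised only at a boundary,
  which would contradict an interior acceleration maximum; a quartic's is a
  quadratic whose vertex is found in closed form. When the vertex falls
  outside the stage range the boundary value is returned with a
  `BoundaryMaximum` flag — for convex, exponential-shaped lactate profiles
  this is the *expected* outcome, not an error.
* **Fixed concentrations** (2 and 4 mmol/L) are the smallest real root of
  `curve(P) = c` inside the stage range at which the curve is locally
  increasing; spurious roots on decreasing branches of the polynomial are
  rejected because the physiological curve is monotone.
* **Dmax** maximises the perpendicular distance between the fitted curve and
  the chord joining the first and last *measured* lactate points (measured,
  not fitted, per the marker's standard definition). Because the chord is
  fixed, stationary points satisfy `curve'(P) = slope(chord)` and are
  screened for the maximal distance; axes are used in raw units (W, mmol/L).
* **LT1** is deliberately stage-discrete: the work rate preceding the first
  stage whose measured lactate rises ≥ 1 mmol/L above baseline. No curve is
  involved, matching the marker's definition as a stage rule.
* All powers are reported at 0.01 W resolution with ties broken toward lower
  power; each extraction degrades independently to an `NA` plus a reason flag
  so one failed marker never discards an athlete.

### Critical power and maximal aerobic power

The two-parameter power-duration model `P = W'·(1/t) + CP` is fitted by OLS
of mean effort power on `1/t` over the 60 s, 5 min and 10 min maximal
efforts: the intercept is CP (W), the slope W' (J; reported in kJ). We use
the linear transform rather than a nonlinear work-time fit because the
linearised form is the stated field convention; its R² is reported for QC.
The graded-test endpoint converts to maximal aerobic power by the standard
partial-stage proration `PO_VO2max = W_f + (t/60)·25` for a 25 W / 1 min
ramp, and a test is flagged valid when RPE exceeded 9/10 and maximal HR
exceeded 80 % of (220 − age).

### Anthropometry and strength

Five-way fractionation expresses each indicator measurement as a z-score
against the 170.18 cm phantom reference, averages the z within a tissue and
maps back to a tissue mass scaled by the cube of the stature ratio. The
constants (phantom means/SDs, tissue assignments) are a *fixture*, not
literals in logic: the original tabulation was unavailable, so the shipped
files are a reconstruction from the widely published phantom reference
values, labelled `_synthetic` and guarded by an md5 checksum (a mismatch
aborts). Phantom identity (all-phantom inputs give the phantom tissue
masses) and the λ³ geometric-similarity law hold exactly by construction;
absolute tissue masses should be treated as method-faithful rather than
source-verified. The five fractions are referenced to measured body mass and
need not sum to 100 %; a deviation beyond ±8 % of body mass is flagged.
Squat-jump height uses ballistic flight `h = g·t²/8` with standard gravity
9.80665 m/s² (unspecified in the protocol literature); isometric strength is
the per-leg maximum across attempts with asymmetry |R − L|, normalised per
athlete before any averaging (ratio-of-means and mean-of-ratios differ
visibly at squad scale).

## 2. The statistical pipeline

The analysis chain is: Shapiro–Wilk annotation → Spearman screen → VIF
filter → backward elimination → forward selection → final OLS report.

* **Spearman ρ** is the Pearson correlation of average ranks; p-values use
  the exact permutation distribution for n ≤ 10 without ties (deterministic)
  and the t approximation otherwise. The 95 % CI is a seeded bootstrap
  percentile interval over athletes, clamped to [−1, 1] — at n = 10 such
  intervals legitimately hit ±1, which a Fisher-z interval cannot, and both
  methods are exposed (`ci_method`).
* **Screen**: candidates (body-mass-normalised markers) with p < 0.05
  against total race time are retained, with *no* multiplicity correction;
  the report carries a note that the family-wise error is inflated.
* **VIF filter**: `VIF_j = 1/(1 − R²_j)`; while any VIF exceeds 5 the
  largest is removed, ties broken alphabetically; perfect collinearity is
  flagged `InfiniteVIF`.
* **Backward elimination** drops the largest slope p-value while it exceeds
  `alpha_stay = 0.05`, recording a trace; **forward selection** then adds
  candidates by largest R² gain.

### The forward entry gate

`forward_select_and_fit(alpha_enter = 0.05)` gates entry on the incoming
slope's p-value. This default is appropriate for exploratory use, but it is
provably wrong for re-selecting among *pre-vetted* predictors under
suppressor structure: a variable can have a near-zero marginal correlation
with the outcome yet a large, highly significant conditional coefficient
(that is exactly what a positive coefficient on PO<sub>X2</sub> alongside
negative ones on PO<sub>X4</sub> and PO<sub>VO2max</sub> means). Gating on
marginal significance then blocks the first entry and the selection stalls.
When forward selection is run on the survivors of backward elimination —
each already significant at `alpha_stay` in the joint model — we therefore
recommend `alpha_enter = 1` (order-only), which is what the acceptance
harness uses; the default remains 0.05 for standalone screening use.

### Small-sample bookkeeping

Complete-case analysis is used throughout; when complete cases are fewer
than athletes the report warns (it never silently reconciles a cohort of 10
with a regression on 9). `F = (R²/df1)/((1 − R²)/df2)` with `df1` = number
of slopes and `df2 = n − df1 − 1` is asserted as an identity in the test
suite.

## 3. The synthetic cohort: what it emulates and what it does not

The generator states a world matching a 10-rider junior national squad:

| parameter | default | why |
|---|---|---|
| normalised marker means/SDs (W/kg) | PO_X2 3.24 ± 0.49, PO_X4 3.86 ± 0.43, PO_VO2max 5.29 ± 0.38, CP 3.91 ± 0.65, P30s 10.45 ± 0.94, Psprint 13.52 ± 2.8 | published squad moments |
| body mass | 67.22 ± 7.49 kg | published squad moments |
| latent correlation r | 0.85 | one shared ability factor reproduces the strong collinearity among aerobic markers that made VIF screening necessary |
| race noise | 2 min SD, floored at 30 min | plausible race-to-race variability; the floor guards degenerate extreme draws |
| stage lactate noise | 0.15 mmol/L | typical portable-analyser repeatability |
| effort power CV | 2 % | power-meter plus pacing variability for maximal efforts |
| baseline lactate | 1.0 ± 0.2 mmol/L | normal resting values |
| W'/kg | 282 ± 40 J/kg | chosen once so the 5-min − 10-min effort gap (W'/600) matches the squad's printed 0.47 W/kg gap; within the 15–25 kJ range typical of trained juniors |

Each normalised marker is `mean + sd·(√r·A + √(1−r)·ε)` with per-athlete
latent ability `A`; absolute watts are normalised values × mass. The lactate
world is `c(P) = c_b + a·e^{kP}`, solved so the curve passes *exactly*
through 2 mmol/L at PO<sub>X2</sub> and 4 mmol/L at PO<sub>X4</sub> —
monotone, convex, and two-point solvable, which the threshold recovery tests
exploit. True race time is the three-marker linear equation
`255.86 − 32.87·PO_VO2max − 51.18·PO_X4 + 60.77·PO_X2` (W/kg inputs,
minutes out) plus noise, so that coefficient recovery is the acceptance
surface. Anthropometric geometry is phantom-proportional at the athlete's
stature with skinfolds shrunk to a lean six-fold sum (47.71 ± 8.24 mm) and a
single girth/breadth scale factor solved so the five tissue masses sum to
the athlete's body mass.

**What a green test does establish**: the threshold extractors invert the
generative curve to ~1.5 W (median) under realistic noise; CP/W' and the
maximal-aerobic-power endpoint invert exactly; the regression stage recovers
the generating equation to machine precision when measurement error is
removed; the screen holds its nominal type-I rate.

**What it does not establish**, and the package's honest limitations:

* *The exponential lactate world is not a cubic.* The degree-3 fit carries a
  deterministic lack-of-fit of roughly 1–2 W at the fixed concentrations for
  typical athletes, and much more for rare draws in which PO<sub>X2</sub>
  and PO<sub>X4</sub> land close together (a steep, nearly-vertical curve no
  low-order polynomial tracks). Median-based recovery criteria are used for
  this reason; single-athlete guarantees are bounded at 2 W on well-behaved
  profiles.
* *Marginal correlations in this world are weak by construction.* Because
  the generating equation's coefficients nearly cancel along the shared
  ability factor (Σ bⱼ·sdⱼ·√r ≈ −4.4 min per SD of ability against ~15 min
  of idiosyncratic spread), race time correlates only weakly with any single
  marker, and essentially not at all with PO<sub>X2</sub>. A default
  10-rider cohort therefore usually retains *nothing* at p < 0.05 — unlike
  the real squad, whose printed correlations reach −0.95. The generator
  reproduces the published *equation* and *moments*, not the published
  correlation strengths; those would require a different error structure the
  source does not specify. Green pipeline tests therefore validate
  machinery, not the claim that a 10-rider screen is well powered.
* *LT2 on exponential-shaped data is boundary-maximal*: the acceleration of
  an exponential increases monotonically, so the `BoundaryMaximum` flag is
  the expected generator-world outcome and the flag, not the value, carries
  the information.
* No VO₂ kinetics, muscle metabolism, pacing, terrain or device artefacts
  are modelled; streams are white noise around constant effort means.

## 4. Numerical choices

* Polynomial fits use QR; roots use `polyroot` with an imaginary-part
  tolerance scaled to root magnitude; all threshold powers are reported at
  0.01 W with ties toward lower power.
* Closed-form maximisers (Dmax, LT2) are validated against 0.01 W grid
  searches on 1000 fitted curves in the acceptance suite.
* Redraw rules in the generator: marker draws violating
  PO<sub>X2</sub> < PO<sub>X4</sub> < PO<sub>VO2max</sub>, non-physiological
  mass, or a baseline lactate ≥ 1.8 mmol/L (which would make the 2 mmol/L
  anchor unsolvable) are rejected and redrawn; rejection is rare (~1 %) so
  moment fidelity is preserved to well within the 1 % / 3 % test bounds.
* Per-athlete substreams are derived from the master seed and the athlete
  index, so cohorts are extensible: athlete *i* is identical in any cohort
  of size ≥ *i* with the same seed.
* The 30-min race floor censors ~0.06 % of athletes; recovery analyses
  exclude exactly-floored times as censored observations (the linear truth
  does not hold for them by construction).
* The n = 10 squad vs a 9-case regression: the generator offers
  `drop_one = TRUE` to mimic one incomplete athlete; the analysis warns
  whenever complete cases < athletes and never reconciles the two silently.
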