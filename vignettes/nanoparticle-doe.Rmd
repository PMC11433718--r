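---
title: "Methods: design-of-experiments optimization and release kinetics for nanoparticle formulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design-of-experiments optimization and release kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanodoe)
```

`nanodoe` implements the statistical pipeline behind a common nanoparticle
formulation-development strategy: screen many candidate process factors with
a Plackett–Burman design, model the few significant ones with a Box–Behnken
response surface fitted to a composite desirability score, read the optimal
recipe off the fitted surface, and characterize the optimized particle's
drug-release kinetics. This vignette records the models, conventions and
numerical choices, and what the packaged tests do and do not demonstrate.

## Screening: Plackett–Burman main effects

`design_pbd()` builds the standard 12-run Plackett–Burman design by cyclic
rotation of the 11-element generator row `+ + − + + + − − − + −` plus a
final all-`−1` row. Published studies rarely state which of the equivalent
generators their software used; since all 12-run PB designs estimate main
effects identically, we fixed this canonical generator once. Run order is
deterministic by default — reproducibility first — with an optional seeded
shuffle for physical run randomization.

The screening model is main-effects only. With `k` real factors assigned,
the remaining `11 − k` dummy columns estimate error:
`SS_resid = SS_total − Σ SS_factor` on `11 − k` degrees of freedom, which on
this orthogonal design equals the sum of the dummy-column contrasts. Each
factor's effect is the high-minus-low mean difference; its sum of squares is
`N·effect²/4` (`3·effect²` at N = 12), tested against the pooled residual
with an F on (1, 11 − k) df. Significance flags use α = 0.05, the starring
convention of screening tables in this field. The packaged example study
screened 6 factors (chitosan concentration, TPP concentration, their mass
ratio, drug dosage, hyaluronic-acid concentration, stirring time), leaving
5 error df.

Because published screening tables in the example study do not include the
raw 12-run responses (and their printed F/p pairs are not internally
reconcilable with any standard 12-run ANOVA), the screening module is
validated by construction instead: synthetic-recovery tests (a planted
effect must be flagged, and only it), an OLS cross-check (contrast effects
must equal twice the regression slopes), and a null calibration — over
2,000 seeded pure-noise tables the per-factor false-flag rate must sit at
0.05 ± 0.02.

## Composite desirability

With four responses of conflicting direction (particle size down; zeta
potential, encapsulation efficiency, drug loading up), the surface is fitted
to a single overall desirability. Each response column is min–max
normalized over the analyzed runs themselves —
`d = (Y − Ymin)/(Ymax − Ymin)` when maximizing,
`d = (Ymax − Y)/(Ymax − Ymin)` when minimizing — and combined as the
geometric mean `OD = (d₁…d_k)^(1/k)`.

Conventions worth making explicit:

* **Extremes are observed, not theoretical.** `Ymin`/`Ymax` are the
  analyzed table's own column extremes. This makes OD a relative score
  within a design: the best run in every column scores exactly 1, a run
  worst in any column scores exactly 0. The packaged study's OD column
  confirms this convention (its zero and unit entries fall exactly where
  observed extremes put them).
* **Zeros propagate exactly.** The geometric mean is computed as
  `exp(mean(log d))` with an explicit short-circuit to 0 whenever any
  `d = 0`, avoiding `log(0)`.
* **No weighting or one-sided target shapes.** Plain Hassan-style min–max
  normalization only; Derringer–Suich exponents are out of scope.
* **Rounding only at report time.** Internally OD is kept at full
  precision; tables display 4 decimals.

A reproduction caveat: recomputing OD from the example study's *printed*
response columns reproduces its published OD column to within about 1e-3
per run, not digit-for-digit, because the published scores were evidently
computed from unrounded raw measurements while the table prints responses
rounded to 0.1 nm / 0.1 mV / 0.01 %. The discrepancy is largest (1.3e-3)
for the run whose drug loading sits closest to the column minimum, where
the normalized value is most sensitive to rounding of the extremes. The
package treats the printed responses as the reproducible input and makes no
attempt to reverse-engineer unprinted raw data.

## Response-surface model and ANOVA

`fit_rsm()` fits the full second-order polynomial
`ŷ = b₀ + Σbᵢxᵢ + Σbᵢⱼxᵢxⱼ + Σbᵢᵢxᵢ²` by OLS on coded levels
(`x = (natural − center)/step`). On a three-factor Box–Behnken design the
linear and interaction columns are mutually orthogonal, so those
coefficients equal simple contrasts (`Σxᵢy/8`, `Σxᵢxⱼy/4`) — the test suite
requires both computational routes to agree to 1e-10.

`anova_rsm()` reports *partial* (drop-one-column) sums of squares: the
increase in residual SS when a single term is removed from the full model.
For the orthogonal linear/interaction terms this coincides with the
contrast SS (`8b²`, `4b²`); the quadratic columns are not orthogonal to the
intercept or to each other, so the drop-one refit is required for them.
Residual variation is split into pure error — within-group squared
deviations over replicated design points, i.e. the center runs — and lack
of fit, tested against pure error. All p-values are upper-tail F
probabilities with no multiplicity correction, matching standard DOE
software output.

Diagnostics are defined from the SS decomposition: `R² = 1 − SSres/SStot`,
adjusted R² with the matching df correction, and `CV% = 100·√MSres/ȳ`. For
the packaged study these evaluate to R² = 0.847, adjusted R² = 0.650 and
CV% = 28.6. The study's own printed summary scalars (R² = 0.9467,
R²adj = 0.7495, CV% = 2.86) are mutually inconsistent with its printed SS
table, which *is* internally consistent (model F, lack-of-fit F and pure
error all cross-check); the package therefore reports the SS-derived
values and treats the printed scalars as typographical.

### Locating the optimum

`rsm_optimum()` solves the stationary system `∇ŷ = Hx + g = 0` with the
Hessian assembled from the quadratic and interaction coefficients. The
stationary point is accepted as an interior optimum only if it lies in the
coded cube `[−1, 1]^m` and the Hessian is definite in the goal's direction;
definiteness is decided by eigenvalue signs with tolerance 1e-10. Otherwise
the surface is maximized over the cube by a dense grid (step 0.01 per axis,
evaluated in chunks) refined with box-constrained BFGS polish, and labelled
a boundary optimum or `saddle-fallback`.

Natural-unit optima are additionally reported rounded half-up to a
per-factor step (default 0.1 in each factor's units): a lab recipe is set
on a pipette, not at a stationary point's seventh decimal. For the packaged
study this converts the stationary point (1.974 mg/mL, 2.258 mg/mL,
1.455:1) into the operational optimum (2 mg/mL chitosan, 2.3 mg/mL TPP,
1.5:1 ratio). Whether the original optimization used a numerical
desirability optimizer or rounded the stationary point is immaterial here —
both land on the same rounded recipe — so the package implements the
transparent route (solve, uncode, round).

## Release kinetics

`cumulative_release()` converts dialysis sampling concentrations into
cumulative release percentages with the standard replacement-sampling
correction `Qn = 100·(Cn·V + v·Σ_{i<n} Ci)/m`; the correction formula is a
package convention (field standard) since published methods sections often
omit it. Values above 100 % are clipped with an explicit warning, never
silently.

Four model families are fitted on the untransformed Q scale so that their
R² values are directly comparable:

| model | form | parameters |
|---|---|---|
| zero-order | `Q = Q₀ + k₀t` | intercept, rate |
| first-order (plateau) | `Q = Q∞(1 − e^(−k₁t))` | plateau (0, 100], rate |
| Higuchi | `Q = k_H√t + c` | rate, intercept |
| Ritger–Peppas | `Q = k_P tⁿ` | rate, exponent |

The first-order model uses the plateau form rather than the classic
`ln(100 − Q)` linearization, because sustained-release carriers commonly
plateau well below 100 %. The Higuchi model carries an additive intercept
by default (published fits in this area often include one); an
intercept-free variant is available via `higuchi_intercept = FALSE`, and
fixing the Peppas exponent at `n = 0.5` (`n_fixed = 0.5`) reproduces it
exactly — a nesting the tests exploit. Nonlinear fits use
Levenberg–Marquardt with linearized initialization (first-order:
regression of `−log(1 − Q/Q̂∞)` on t; Peppas: log–log regression), `t = 0`
points excluded from initialization but included in the objective, and a
small ladder of fallback starts before declaring failure.

`select_release_model()` returns the highest-R² fit; ties within 1e-9 go to
the earlier model in the fixed order zero, first, Higuchi, Peppas, which
prefers the more parsimonious special case when a curve is exactly nested
(e.g. intercept-free Higuchi data tie Peppas at n = 0.5 and are reported as
Higuchi).

## Assay metrics

The closed-form characterization formulas are implemented exactly as used
in practice: `EE% = (Wtotal − Wdissociate)/Wtotal·100`,
`DL% = Wtotal/Wlyophilized·100`, `DPPH = (A0 − A1 + A2)/A0·100`,
`ABTS⁺ = (A0 − A1)/A0·100`. For CCK-8 cell viability two conventions
circulate: the difference form `(OD_sample − OD_control)/OD_control` (which
scores the control itself as 0) and the ratio form `OD_sample/OD_control`.
The difference form appears verbatim in methods sections but is almost
certainly a transcription of the ratio; `cell_viability()` defaults to the
difference form for fidelity to the packaged study's stated method and
offers `mode = "ratio"` as the conventional alternative.

## Synthetic-data generators

The simulators generate exactly the structure the estimators assume:

* `sim_bbd()` — a quadratic surface evaluated on the coded Box–Behnken
  design plus i.i.d. Gaussian noise. The default noise sd 0.154 is the
  residual scale (√MSres) of the packaged study, so simulated power
  behavior resembles the real experiment.
* `sim_pbd()` — additive main effects (`effect/2` per coded unit) plus
  Gaussian noise on the 12-run design.
* `sim_release()` — a kinetic model evaluated on the standard sampling grid
  (0, 0.25, 0.5, 0.75, 1, 2, 4, 6, 8, 12, 24, 48 h) plus Gaussian noise
  truncated to [0, 100], with `Q(0) = 0` by convention and an optional
  running-maximum monotonization.

All generators are pure functions of their parameters and seed. What they
deliberately do **not** emulate: replicate-level triplicate structure
(published tables report means; a per-replicate simulation would claim a
variance structure we cannot verify), heteroscedastic or autocorrelated
release noise, and any physics of ionic gelation. Passing the recovery and
calibration tests therefore demonstrates the *estimators* are correct and
calibrated under the assumed error model — not that real lab data satisfy
that model.

## Problem sizes and numerical tolerances

The shipped test suite uses: 2,000 seeded null tables for the screening
false-positive calibration (rate within 0.05 ± 0.02), 500 replicates at the
study's noise scale for 95 % t-interval coverage (within ± 3 %), 100 noisy
replicates for kinetic model selection (first-order must win at least 95),
and 10–25 case loops for algebraic property checks at 1e-10. These sizes
give Monte-Carlo standard errors several times smaller than the asserted
bands while keeping the suite quick on a laptop. Exact identities
(SS additivity, contrast agreement, round-trips) are asserted at 1e-9–1e-12;
noiseless nonlinear recovery at 1e-6.

## Known limitations

* Designs are the 12-run Plackett–Burman and the 3-factor Box–Behnken; no
  general fractional factorials, central composites, D-optimal search or
  blocking.
* OD offers no response weighting or one-sided target shapes.
* Release models exclude Weibull, Hixson–Crowell and mechanistic diffusion
  PDEs; there is no f2 curve-similarity testing.
* The optimizer reports a single optimum of a single fitted surface;
  canonical/ridge analysis and multi-response trade-off exploration are out
  of scope.
* The packaged study fixtures are printed-precision snapshots; analyses
  that depended on the original unrounded raw data can be reproduced only
  to printed precision (see the desirability caveat above).
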