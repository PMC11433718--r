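# nanodoe

Design-of-experiments tools for optimizing nanoparticle formulations, built
tidyverse-style: every user-facing function takes a data frame and returns a
tibble, so the whole workflow chains with the pipe.

`nanodoe` is aimed at formulation scientists optimizing ionic-gelation
nanoparticles (e.g. chitosan/TPP carriers) and covers the full
screen → model → optimize → characterize loop:

* **Plackett–Burman screening** (`design_pbd()`, `screen_pbd()`): 12-run
  orthogonal two-level designs with main-effects ANOVA, pooling unassigned
  dummy columns into the error term.
* **Composite desirability** (`score_od()`): each response *Y* is min–max
  normalized over the design's own runs, oriented so larger is better —
  d<sub>max</sub> = (Y<sub>i</sub> − Y<sub>min</sub>)/(Y<sub>max</sub> − Y<sub>min</sub>)
  for maximized responses,
  d<sub>min</sub> = (Y<sub>max</sub> − Y<sub>i</sub>)/(Y<sub>max</sub> − Y<sub>min</sub>)
  for minimized ones — and the runs are scored with the overall
  desirability, the geometric mean OD = (d₁d₂…d<sub>k</sub>)^(1/k).
* **Box–Behnken response-surface modelling** (`design_bbd()`, `fit_rsm()`,
  `anova_rsm()`, `rsm_optimum()`): OLS fit of the full quadratic
  ŷ = b₀ + Σbᵢxᵢ + Σbᵢⱼxᵢxⱼ + Σbᵢᵢxᵢ², partial (drop-one-term) ANOVA with
  the lack-of-fit / pure-error split from center replicates, and a
  constrained optimum from the stationary system ∇ŷ = 0 uncoded back to
  natural units.
* **Drug-release kinetics** (`cumulative_release()`, `fit_release()`,
  `select_release_model()`): replacement-sampling correction for dialysis
  data and least-squares fits of zero-order (Q = Q₀ + k₀t), plateau
  first-order (Q = Q∞(1 − e^(−k₁t))), Higuchi (Q = k<sub>H</sub>√t + c) and
  Ritger–Peppas (Q = k<sub>P</sub>tⁿ) models, compared on a common raw-scale R².
* **Assay metrics** (`ee_percent()`, `dl_percent()`, `dpph_scavenging()`,
  `abts_scavenging()`, `cell_viability()`): the closed-form encapsulation,
  loading, antioxidant and viability formulas.
* **Seeded simulators** (`sim_bbd()`, `sim_pbd()`, `sim_release()`): generate
  design tables and release curves from known truths so every stage can be
  tested end to end.

A complete 17-run Box–Behnken study of a chitosan/TPP nanoparticle carrier
(four responses: particle size, zeta potential, encapsulation efficiency,
drug loading) ships as plain-text fixtures; see `doe_example()`.

## Worked example

```r
library(nanodoe)

runs <- doe_example("bbd_runs")                        # 17-run BBD study
scores <- score_od(runs, doe_example_directions())     # per-run OD
fit <- fit_rsm(runs, "od")                             # quadratic surface
fit
#> Second-order response-surface fit
#>   response: od | factors: X1, X2, X3 | n = 17
#>   R2 = 0.8467, adj R2 = 0.6495, CV% = 28.60
#> (Intercept)          X1          X2          X3       X1:X2       X1:X3
#>      0.7588     -0.1362      0.0767     -0.1490      0.1130     -0.1475
#>       X2:X3        X1^2        X2^2        X3^2
#>      0.0441     -0.2555     -0.0907     -0.1192
```

The intercept 0.7588 is the predicted OD at the center of the design; the
negative X1² term (−0.2555) curves the surface downward, so an interior
maximum exists. The ANOVA (`anova_rsm(fit)`) gives the model F = 4.2942
(p = 0.0339) and a non-significant lack of fit (F = 0.2975, p = 0.8265):
the quadratic describes the data adequately. Locating the optimum:

```r
rsm_optimum(fit, factors = doe_example_factors(), step = 0.1)
#> Response-surface optimum (maximize, interior maximum)
#>   coded:  X1 = -0.0520, X2 = 0.2581, X3 = -0.5451
#>   natural:  X1 = 1.9740, X2 = 2.2581, X3 = 1.4549
#>   rounded:  X1 = 2, X2 = 2.3, X3 = 1.5
#>   predicted response: 0.8128
```

i.e. an operational recipe of 2 mg/mL chitosan, 2.3 mg/mL TPP and a 1.5:1
chitosan:TPP mass ratio, with predicted OD 0.81. Release kinetics on a
simulated noisy curve:

```r
curve <- sim_release("first", c(Qinf = 83.5, k1 = 0.10), noise_sd = 1, seed = 7)
select_release_model(curve)
#> Release kinetic fit: first
#>    Qinf = 85.95, k1 = 0.09673
#>   R2 = 0.9992 (raw release scale, n = 12)
```

Each result type has `tidy()`/`glance()` methods and an `autoplot()`
(surface contours, release overlays, screening heat maps), and
`run_report()` chains OD → fit → ANOVA → optimum into one JSON-serializable
report.

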