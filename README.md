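# sorbRSM

Design–fit–optimize toolkit for batch heavy-metal **biosorption**
experiments, built around a packaged case study: Pb(II) removal from
synthetic wastewater by dried *Chlorella kessleri* microalgal biomass. It is
aimed at environmental-biotechnology practitioners who run small designed
experiments (pH, temperature, sorbent dose …) and want the full desk
analysis — response-surface modelling, diagnostics, and two independent
optimizers — reproducible in one place.

## What it computes

* **Design**: three-factor Box–Behnken designs (12 cube-edge midpoints +
  replicated center points) with exact affine coding
  `x = (actual − center) / half-range`.
* **Response surface**: the full second-order model on coded factors,

  `y = β₀ + Σ βᵢxᵢ + Σ βᵢᵢxᵢ² + ΣΣ βᵢⱼxᵢxⱼ + ε`,

  fitted by OLS, with an ANOVA that splits error into lack-of-fit vs pure
  error (from the center replicates) and a standardized-effect (Pareto)
  ranking `t = β̂ / se(β̂)`.
* **Desirability optimization**: Derringer's one-sided ramp
  `d = ((y−L)/(U−L))^w` on `[L, U]`, composite `D = (∏ dᵢ)^{1/n}`, maximized
  deterministically (dense grid + L-BFGS-B polish).
* **Crow search algorithm (CSA)**: a from-scratch population metaheuristic
  (`xᵢ ← xᵢ + r·fl·(mⱼ − xᵢ)` or a random restart with probability AP) as a
  global cross-check, with seeded multi-run spread statistics.
* **Kinetics**: batch mass balance `q_t = V(C₀−C_t)/m`, removal efficiency
  `R = (Cᵢ−C_f)/Cᵢ·100`, and linearized pseudo-first-order
  (`log₁₀(q_e−q_t)` vs `t`) and pseudo-second-order (`t/q_t` vs `t`) fits.
* **Synthetic generators** for both the design responses and kinetic traces,
  used throughout the tests for round-trip and parameter-recovery checks.

## Worked example

```r
library(sorbRSM)

design <- pb_design()            # packaged 15-run Pb(II) experiment
fit <- fit_quadratic(design)
round(coef(fit$model), 3)
#> (Intercept)           A           B           C         A*A         B*B
#>      94.653       6.101      -2.180       7.239     -11.239      -3.552
#>         C*C         A*B         A*C         B*C
#>      -2.844      -0.907      -2.400       0.718

opt <- maximize_desirability(fit$model, lower = min(design$runs$response),
                             upper = 100, factors = design$factors)
opt
#> Desirability optimum
#>   coded:     pH = 0.1739, temperature = -0.2281, dose = 1.0000
#>   actual:    pH = 6.348, temperature = 27.72, dose = 1.5
#>   predicted response: 99.5365
#>   desirability d = 0.9868, composite D = 0.9868
```

Read: the fitted surface predicts maximum Pb(II) removal (~99.5%) at pH 6.35
and 27.7 °C with the dose at its upper bound 1.5 g/L, and that operating
point is near-ideal on the 0–1 desirability scale (D = 0.987). Running 50
seeded crow searches on the same surface lands on the same point with
spread ~10⁻¹¹:

```r
cfg <- csa_config(rbind(rep(-1, 3), rep(1, 3)), seed = 0, n_runs = 50)
csa_multirun(function(x) predict(fit$model, x), cfg)$stats
#>         best        worst         mean          std
#> 9.953648e+01 9.953648e+01 9.953648e+01 2.154624e-11
```

The numbered drivers under `analysis/` run the complete workflow and write
their tables under `results/`: `01_fit_surface.R` (fit, ANOVA, Pareto
ranking, surface grids), `02_optimize.R` (desirability + 50-run CSA),
`03_kinetics.R` (rate-law fits and the mass-balance consistency check),
`04_recovery_simulation.R` (200-experiment parameter-recovery study).

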