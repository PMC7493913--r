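---
title: "Optimizing heavy-metal biosorption: response surfaces, desirability, and the crow search algorithm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing heavy-metal biosorption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorbRSM)
```

## The problem

Dried microalgal biomass passively binds heavy-metal cations from solution
(biosorption), and how much it removes depends strongly on a handful of
batch parameters. The packaged study system is Pb(II) removal by dried
*Chlorella kessleri* biomass, with three controllable factors: initial
solution pH (4–8), temperature (20–40 °C) and biomass dose (0.5–1.5 g/L).
sorbRSM implements the full desk analysis for such an experiment: design the
runs, fit and diagnose a second-order response surface, locate the best
operating point two independent ways, and characterize the uptake kinetics.

## Design and coding

A three-factor Box–Behnken design (BBD) places runs at the 12 edge midpoints
of the coded cube \([-1,1]^3\) plus replicated center points (3 by default,
matching the packaged experiment, giving 15 runs). Each factor is coded
affinely,

\[ x = \frac{\text{actual} - \text{center}}{(\text{high}-\text{low})/2}, \]

so `to_coded(low) = -1` and `to_coded(high) = +1` exactly. `factor_spec()`
rejects a center that is not the midpoint of the range, because the
transform above assumes it. All fitting is done on coded values: the coded
columns are mean-zero and pairwise orthogonal (each with
\(\sum x_i^2 = 8\)), so linear and interaction effects are estimated
independently of one another. `bbd_design()` emits edge runs in a fixed
lexicographic block order; the packaged `pb_design()` table keeps its
original reporting order instead, which is immaterial to any fit.

## The quadratic surface and its ANOVA

`fit_quadratic()` estimates the 10-coefficient full quadratic model by
ordinary least squares. For the 15-run BBD this leaves 5 residual degrees of
freedom. `rsm_anova()` reports per-term *adjusted* (extra) sums of squares —
the residual-SS increase from deleting the term from the full model — which
for the orthogonal linear and interaction columns equal sequential SS, and
for the three pure-quadratic columns do not sum to the Square group's SS
(the squares are collinear with the intercept and each other; grouped rows
use the drop-the-whole-group extra SS, as standard DoE software does).

Residual error is split using the center replicates: pure error is the
within-replicate scatter about the replicate mean (2 df here), and the
remainder is lack of fit, tested against pure error. Every other row's F
ratio uses MS(Error). When a fit is numerically exact (synthetic noiseless
data), the error variance is reported as zero and F ratios as infinite
rather than as meaningless large numbers.

`standardized_effects()` ranks terms by \(|t| = |\hat\beta|/\mathrm{se}\),
the quantity a Pareto chart of standardized effects displays; for 1-df terms
\(t^2\) equals the ANOVA F. The significance threshold is the two-sided
\(t\) critical value at a configurable \(\alpha\) (default 0.05; the
analysis scripts also report the 0.1 level, at which the pH × dose
interaction becomes significant). We deliberately do not hard-code any other
reference line: published Pareto charts sometimes carry thresholds that
match no standard critical value for the residual df, so the level is left
to the caller.

On the packaged data the refit reproduces the reported coefficients to
within ±0.005. That slack is not looseness of the method: the packaged
responses are recorded to two decimals, and that rounding alone perturbs
third-decimal coefficients by up to ~0.005 (and SS rows by a few
hundredths). The package reports its own recomputed \(R^2\) (0.986) and
adjusted \(R^2\) rather than echoing any published value.

## Desirability optimization

For a single larger-is-better response the Derringer desirability is

\[ d = 0 \ (y < L), \qquad \left(\frac{y-L}{U-L}\right)^w \ (L \le y \le U),
   \qquad 1 \ (y > U), \]

and the composite desirability \(D\) is the geometric mean across responses
(here one response, so \(D = d\)). The bounds are tunable with defaults
\(L =\) the minimum observed response in the design (64.88% for the packaged
data), \(U = 100\) (the natural ceiling of a percent-removal response) and
\(w = 1\); with these, the optimum of the packaged surface scores
\(D = 0.9868\).

`maximize_desirability()` is deterministic: a dense grid scan over the coded
box (step 0.01; first-encountered maximum wins ties in row-major order)
followed by an L-BFGS-B polish. Because \(d\) is monotone in \(y\),
maximizing \(D\) is exactly maximizing the predicted response, and the
polish works on the response directly; tests verify the result is never
beaten by any point of a 201³ verification grid by more than 10⁻⁶.

On the packaged surface the optimum sits on the dose = +1 face (1.5 g/L) at
coded pH ≈ 0.174 and temperature ≈ −0.228 — pH 6.35, 27.7 °C — with
predicted removal ≈ 99.54%. These coordinates are the analytic stationary
point of the fitted surface restricted to that face (solve the 2×2 gradient
system to confirm). Published profile-optimizer output for the same kind of
surface can differ from the true stationary point by a few thousandths of a
coded unit; within that flat neighbourhood the predicted response changes
by less than 0.001, so the operating recommendation is unaffected. The
decoded temperature is reported as decoded (−0.228 → 27.72 °C) rather than
reconciled with any differently rounded summary figure.

## Crow search

The crow search algorithm (CSA) is the package's global cross-check on the
local desirability optimum — authored from scratch, since no installed R
package provides it. Each of \(N\) crows keeps a memory of its best
position. Per iteration, crow \(i\) picks a random crow \(j\); with
probability \(1-AP\) it pursues \(j\)'s memory,

\[ x_i \leftarrow x_i + r \cdot fl \cdot (m_j - x_i), \quad r \sim U(0,1), \]

otherwise (the "awareness" event) it restarts uniformly in the search box.
Positions are clamped to the box component-wise — clamping rather than
resampling keeps the evaluation count deterministic — and a memory is
replaced only by a strictly better position, so each crow's memory fitness
and the best-so-far trace are non-decreasing. The two limits are sanity
checks exercised in tests: \(AP = 1\) is pure random search, \(AP = 0\)
pure pursuit.

Hyperparameters default to the canonical CSA settings \(N = 50\),
\(fl = 2\), \(AP = 0.1\), 150 iterations — the flock size and flight length
of the algorithm's original formulation — because the packaged study's
report does not state its own. With them, 50 independent runs (per-run seed
= master seed + run index) on the packaged surface all land on the same
optimum with spread ~10⁻¹¹, reproducing the qualitative robustness claim
(spread ≪ 0.01) without asserting any seed-dependent iteration count at
which convergence happened.

## Adsorption kinetics

`qt_series()` converts residual concentrations to per-gram uptake via the
batch mass balance \(q_t = V (C_0 - C_t)/m\), and `removal_efficiency()`
computes \(R = (C_i - C_f)/C_i \times 100\); the two are consistent
(\(R = 100\, m q_t / (V C_0)\)) and the package surfaces rather than hides
the fact that a capacity of 3.727 mg/g at 1.5 g/L dose and 10 mg/L initial
Pb(II) corresponds to ~56% removal — capacity and the ~97% optimum removal
figure cannot come from the same batch conditions.

Both classical rate laws are fitted in their linearized forms:
pseudo-first-order \(\log_{10}(q_e - q_t) = \log_{10} q_e - (k_1/\ln 10)t\)
(slope → \(k_1\), intercept → \(q_{e,calc}\); \(\ln 10\) = the conventional
"2.303") and pseudo-second-order \(t/q_t = 1/(k_2 q_e^2) + t/q_e\). The
first-order fit needs the observed plateau \(q_{e,exp}\) from the caller
(the pipeline falls back to the final \(q_t\) with a logged note), and
points with \(q_t \ge q_{e,exp}\) are excluded from the log transform with
a count. A second-order fit with non-positive slope or intercept is
rejected as inapplicable instead of returning negative rate constants.

No raw uptake trace is published for the packaged experiment, so kinetic
correctness is established by round-trip: `simulate_kinetic_trace()`
generates data from the closed forms \(q_t = q_e(1-e^{-k_1 t})\) and
\(q_t = q_e^2 k_2 t/(1 + q_e k_2 t)\), and the fits recover the generating
parameters — exactly at \(\sigma = 0\), and to well under 10% relative error
at noise worth 1% of \(q_e\). For the first-order model that noise property
is evaluated on the pre-plateau window (times up to ~4 half-lives): the log
transform amplifies noise without bound as \(q_t \to q_e\), which is an
intrinsic property of the linearization, not of the implementation.

## The synthetic generator

`simulate_bbd_responses()` emulates exactly the data-generating process the
analysis assumes: a true quadratic surface (default: the packaged reference
surface `pb_removal_surface()`) observed with i.i.d. Gaussian noise, center
replicates drawing independent noise — which is precisely what creates pure
error. The default \(\sigma = \sqrt{3.725}\) is the replicate-level error
variance estimated from the packaged experiment, so simulated tables are
statistically comparable to the real one. What the generator does *not*
emulate — and what passing recovery tests therefore cannot certify about
real data — includes heteroscedastic or non-Gaussian measurement error,
drift between runs, model inadequacy (a true surface that is not quadratic;
the packaged data's own lack-of-fit ratio is large), and responses hitting
the 100% ceiling.

`rank_by_electronegativity()` covers the mixed-metal side experiment: in
competitive biosorption, higher Pauling electronegativity generally means
stronger binding, and descending order over (Pb 2.33, Cu 1.90, Co 1.88,
Cd 1.69, Cr 1.66) predicts Pb first and Cr last. The prediction matches the
observed removal ordering except for swapping Cu and Co, whose
electronegativities differ by 0.02 — removal efficiencies there are
experimentally comparable, and the docs say so rather than overclaiming.

## Numerical choices and problem sizes

* Extra SS that comes out a tiny negative by floating-point cancellation is
  clamped at 0; anything materially negative is a hard failure.
* Grid tie-breaks: first encountered in row-major order, then polished.
* Monte-Carlo checks in the tests use 100–200 replicates at the study's
  15-run design size, and the optimizer tests verify against dense-grid and
  closed-form stationary-point oracles; these sizes give the assertions
  comfortable margins while keeping the whole suite around a minute.
* All randomness flows from explicit integer seeds; repeated pipeline runs
  with the same seed produce byte-identical machine-readable outputs.

## Limitations

Only 3-factor Box–Behnken designs are generated (no central-composite or
larger designs); only the maximize desirability goal is wired (the composite
machinery accepts \(n\) responses but the pipeline optimizes one); CSA
handles box bounds only; and the kinetic module fits the two linearized
classical models, not nonlinear least squares or diffusion/isotherm models.
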