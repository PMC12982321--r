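---
title: "Phenology model selection under climate-scenario uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenology model selection under climate-scenario uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Projecting crop phenology into future climates mixes two error sources that
pull model design in opposite directions. A phenology model fitted to
observations gets better (up to overfitting) as environmental covariates are
added. Climate-scenario input data get *worse*: each projected covariate
carries its own simulation uncertainty, and an additive model accumulates
those uncertainties. `phenoselect` makes the trade-off operational for
winter wheat with four phases (sowing–emergence, emergence–jointing,
jointing–heading, heading–senescence) and up to seven daily covariates
(tasmin, tas, tasmax, RH, SPI, VPD, GR).

## Model structure

Development inside a phase is a sum of daily dose-response curve (DRC)
responses, one curve per covariate. Four families are available; their
parameters and constraints:

| family | parameters | notes |
|---|---|---|
| linear | intercept, slope | may be negative |
| broken stick | psi_base, slope | zero below the base threshold |
| asymptotic | psi_base, lrc, Asym | clipped at zero, saturates at Asym |
| Wang–Engel | psi_base < psi_opt < psi_max, r | zero outside (base, max), peak r at the optimum |

Temperatures and radiation are always modelled with the Wang–Engel family
(its base/maximum bounds stop the response exploding at extremes under
warming); RH, SPI and VPD try all four families, giving 16 covariate–family
candidates per phase. One winner per covariate is kept by Pearson
correlation between observed and modelled durations.

Accumulated doses enter a binomial-logit GLM whose binary response is
"phase reached by day d". The daily training design runs from the phase
start to twice the observed duration, so the two classes are balanced by
construction. The decision threshold is the probability maximizing Youden's
J in a ROC scan. Chained phase predictions give whole-season phenology;
a phase that never crosses its threshold within the horizon is *censored*,
and censoring propagates to later phases — it is never silently imputed.

## Calibration choices

The DRC objective is a design decision of this package: the literature the
framework descends from scores models by duration error, so each candidate
parameter set is scored by the RMSE between observed durations and the
first day the accumulated dose reaches a common required dose (the median
over training environments of the dose at the observed phase end). Two
numerical details matter:

* Optimization is a two-step local search. The coarse pass is
  `nloptr::auglag` with COBYLA (derivative-free, box bounds) from
  quantile-based starts (0.05 / 0.5 / 0.95 of the observed covariate for
  base/optimum/maximum parameters; documented defaults for unit-free ones),
  at most 500 evaluations, relative tolerance 1e-2. The fine pass restarts
  at the coarse optimum with per-parameter bounds `v ± |v|` (`±0.1` for a
  zero-valued optimum), 1000 × n_parameters evaluations and relative
  tolerance 1e-8 — but runs a bounded Nelder-Mead simplex rather than
  COBYLA: the base and optimum parameters compensate along a curved valley
  of the duration loss, where COBYLA's linear approximations stall a few
  degrees from the minimum while the simplex walks the valley down (this is
  measurable: the stalled loss exceeds the loss at the generator's true
  parameters). The absolute tolerance is 1e-24 throughout, and the better
  of the two optima is kept, so refinement cannot lose ground.
* Inside the optimizer the crossing day is linearly interpolated within the
  crossing day. Whole-day crossings make the loss piecewise constant, and
  COBYLA stalls on the plateaus; the interpolated surface is piecewise
  smooth and recovers generator parameters reliably. Reported losses and
  predictions remain whole days.

Robustness comes from an ensemble of 20 fits on random 80% subsamples of
the training data (with the 80/20 train/validation split, each run sees 64%
of all data); the final parameters are the elementwise ensemble median. The
peak rate `r` of a Wang–Engel curve trades off exactly against the required
dose, so only the curve's *shape* (base, optimum, maximum) is identified —
a harmless gauge freedom the GLM coefficients absorb.

## The three selections

* **Max_GT** evaluates every covariate subset (127 per phase for seven
  covariates; 2^k − 1 in general) on held-out validation environments and
  keeps the RMSE-best model per complexity, the global minimum overall.
* **Max_CS** takes those best-per-complexity models and drives each once
  with observed weather and once with every simulation of a scenario
  ensemble over a shared reference period, from a fixed phase-start day of
  year (the median observed start by default) so phases are decoupled.
  Per-simulation RMSEs between the two predictions are averaged within each
  regional climate model (RCM) and then across RCMs, so over-represented
  RCMs cannot dominate; the alternative of averaging predictions first is
  available as a switch. The winner is the smallest ensemble RMSE.
* **Opt** computes, per complexity, the mean of the Max_GT and Max_CS
  RMSEs and takes the minimum inside the closed complexity interval between
  the two winners. Its complexity provably stays inside that interval.

All ties, everywhere, resolve towards fewer covariates and then the
lexicographically smallest subset id — selection is a pure function of its
inputs. RMSEs on the day scale can be made comparable across phases by
dividing by the observed duration SD (`relative_uncertainty()`).

Scenario uncertainty itself propagates over a covariate subset by
root-sum-of-squares of per-covariate standardized errors. This assumes
uncorrelated, roughly homoscedastic errors; the package asserts this in
documentation rather than enforcing it. Because the norm is monotone, the
propagated uncertainty never decreases when a covariate is added — the
structural counterpart of Max_CS preferring small models.

## What the synthetic generator emulates — and what it does not

The generator states a world, not a tuning knob: sinusoidal seasonal cycles
with AR(1) daily anomalies (annual mean 9 °C, amplitude 9 °C, anomaly SD
2 °C, phi = 0.7 by default), a regional gradient of station annual means
(±2 °C by default), zero-inflated gamma rainfall (~45% wet days), winter-
peaking humidity, summer-peaking radiation; phenology generated by a known
additive dose model with (0, 25, 35) °C Wang–Engel cardinal values —
plausible wheat values chosen once and documented as test constructs — and
rounded Gaussian duration noise of SD 2 days; scenario ensembles equal to
the observed climate in the reference period up to per-covariate additive
bias, AR(1) noise and an optional post-reference warming trend, with
seasonal structure recycled beyond the observed years.

It does *not* emulate spatial correlation between stations, inter-variable
dependence beyond the temperature ordering, frost/stress events that
lengthen phases, or the bias structure of any specific scenario product. A
green test therefore establishes that the estimation and selection machinery
is correct under a well-specified additive world — not that the framework
resolves real-world phenology to any particular accuracy.

Three world choices deserve a note. Parameter recovery is tested in a warmer
configuration (station means 6–16 °C, amplitude 11 °C) whose summer phase
samples both sides of the 25 °C optimum: in a climate that never reaches the
optimum the decline side of the curve is unidentifiable from durations, and
no optimizer can recover it. The selection trade-off property (Max_CS
preferring fewer covariates than Max_GT under ensemble noise) is tested in a
world whose three true covariates carry strong *independent* information, so
the ground-truth selection genuinely favors multi-covariate models — with
nearly collinear covariates one covariate suffices, both strategies pick
complexity 1, and the trade-off premise is vacuous. And the end-to-end
worlds use a calibration ensemble of 5 runs rather than 20 purely to keep
the test suite inside its time budget; ensemble size enters no tested claim.

## Numerical and degenerate-input policy

* Weather tables must be gap-free per station; `fill_weather_gaps()`
  interpolates gaps of ≤ 3 days, longer gaps are errors.
* SPI: trailing 30-day sums, gamma fitted per calendar month pooled across
  years with a point mass at zero (`F = q + (1−q)G`), probit transform;
  probabilities are clamped to [1e-8, 1−1e-8]. All-zero or constant sums in
  a stratum are errors. Whether the original implementation pooled by month
  is unknown; this choice is not claimed to match it numerically.
* VPD uses the Magnus saturation pressure `6.1078·exp(17.27T/(T+237.3))` hPa.
* Infeasible or dose-degenerate parameters get a large finite loss sentinel
  (1e10), keeping the optimizer inside a well-defined surface.
* Complete separation in the logistic fit falls back to a ridge penalty
  (λ = 1e-6 on slopes) after an unpenalized attempt.
* The two-sided 30-season rolling mean uses the classical even-order
  centered weighting (half weight on the outermost seasons), which
  reproduces a linear trend exactly; at the series ends the window truncates
  symmetrically.
* Dose windows are half-open `[start, end)` so chained phases never double
  count a day; a Wang–Engel curve evaluated exactly at its base or maximum
  returns 0 (strict inequalities).

## Known limitations

The composite model is purely additive: no covariate interactions, no
cross-phase cascades, no feedback loops, no genotype specificity, and no
negative (damage) responses — the DRCs only model forward development.
Selection considers a single 80/20 stratified split rather than full
cross-validation, and the Max_CS station×year comparison pools environments
(a per-station variant is exposed as configuration but not the default).
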