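---
title: "Partitioning silver nanoparticle toxicity into ionic and particulate contributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning silver nanoparticle toxicity into ionic and particulate contributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agmix)
```

## The problem

Soluble metallic nanoparticles expose an organism to two toxicants at once:
the particulate fraction and the dissolved ionic fraction continuously shed
from it. In acute immobilization tests with *Daphnia magna* neonates the
observed dose–response of a nanoparticle suspension therefore confounds two
curves. When the host's microbiome sequesters silver ions, the dissolved
fraction — and with it the balance of the two routes — changes between
germfree, colonized, and mono-associated animals. `agmix` implements the
statistical machinery that separates the two routes from three data streams:

1. immobility counts for the suspension dilution series (nominal µg/l),
2. immobility counts for an AgNO~3~ dilution series (fully dissolved Ag),
3. ICP-MS measurements of total and dissolved silver per nominal
   concentration (dissolved = supernatant after centrifugation;
   particulate = total − dissolved).

## Model and estimation

### Dose–response curves

Every curve is a log-logistic with the lower and upper limits fixed at 0 and
1 — no immobility without silver, complete immobility at saturating dose:

$$E(c) = \frac{1}{1 + (e/c)^{h}},$$

with EC50 $e > 0$ and slope $h > 0$ in the increasing-effect convention
(equal to $-b$ of the classical four-parameter log-logistic parameterization;
mortality rises with dose, and an always-positive slope avoids sign bugs).
$E(e) = 0.5$ identically and $E(0) = 0$ by continuity, so wells at
concentration 0 carry no likelihood information; they are only screened
against the 10% control-immobility acceptability bound customary for acute
immobilization tests, with a warning when exceeded.

`fit_ll4()` maximizes the per-well binomial log-likelihood
$\sum_i y_i \log p(c_i) + (n_i - y_i)\log(1 - p(c_i))$ over
$(\log h, \log e)$. Working on the log scale makes the positivity
constraints implicit and the fit invariant to the $(h, e)$ vs
$(\log h, \log e)$ parameterization. The optimizer is BFGS with an analytic
gradient from twelve starts — a fixed 3×3 grid spanning the dose range plus
the three best cells of a coarse likelihood scan over a widened
(slope, EC50) box — followed by Newton polishing of the gradient norm
towards 1e-10. The scan-derived starts matter: on ridge-shaped surfaces
(see the particle fit below) every fixed start can drift onto the
$e \to \infty$ plateau even when an interior optimum with strictly higher
likelihood exists.

Wells are the sampling unit. Overdispersion is estimated as Pearson
$\chi^2 / (\text{wells} - 2)$ and reported raw, but floored at 1 wherever it
scales a variance — extra-binomial clustering (animals share a well) should
widen intervals, never narrow them. `compare_ec50()` tests EC50 equality on
the log scale: a two-sided t statistic from the difference of log EC50s with
dispersion-scaled Wald variances and the summed residual degrees of freedom.
The ratio scale is a fixed package choice; a difference-scale test on raw
EC50s would give slightly different p-values, which is a known source of
discrepancy when comparing against other software.

### Response-additivity decomposition

The suspension effect combines the two components by independent action:

$$E_{total}(c) = 1 - \bigl(1 - E_p(d_p(c))\bigr)\bigl(1 - E_i(d_i(c))\bigr),$$

where $d_i(c), d_p(c)$ are the measured ion and particle doses at nominal
concentration $c$, taken from the speciation table (replicate/timepoint
means, linearly interpolated in $c$; linear, not log-linear, because doses
enter toxic units linearly; never extrapolated). The ion curve $E_i$ is
fitted on the AgNO~3~ series, whose nominal mass is treated as fully
dissolved — no speciation correction is applied to it. The particle curve is
then estimated by maximizing the binomial likelihood of the *combined*
effect over $(\log h_p, \log e_p)$ with the ion parameters frozen.

The alternative — algebraically inverting
$E_p = 1 - (1 - E_{total})/(1 - E_i)$ per well and refitting — divides by
$1 - E_i$ and explodes as the ion effect saturates, and discards the
binomial error model; `invert_particle_effect()` is retained for
diagnostics only, clipping negative residual effects to 0 with a warning
(expected under sampling noise when the ion effect already explains a
well's immobility). When the ion effect meets or exceeds the observed
immobility at every concentration the particle parameters are unidentifiable
and the fit refuses with an explicit error instead of returning a boundary
estimate.

At the fitted suspension EC50 $c^*$ (fitted on *nominal* concentration, as
the experiment defines its exposure levels), the measured doses are
converted to toxic units $TU_i = d_i(c^*)/e_i$, $TU_p = d_p(c^*)/e_p$, and
the relative contributions are $TU/(TU_i + TU_p)$. The nominal/measured
asymmetry — suspension curve on nominal doses, toxic units on measured
speciation doses — mirrors the experimental procedure and is deliberate.

## The synthetic-data generator

`synthetic_truth()` fixes the generating model; `generate_experiment()`
draws one in-silico experiment. Defaults reproduce the study design:

| parameter | default | meaning |
|---|---|---|
| `np_concentrations` | 5, 10, 20, 30, 50 µg/l | nominal suspension series |
| `agno3_concentrations` | 10 → 0.625 µg/l | two-fold AgNO~3~ series |
| `n_per_well`, `wells_per_concentration` | 5, 4 | 20 neonates per concentration |
| `timepoints` | 24, 48 h | scoring times |
| `dissolved_fraction` | 0.25 | share of total Ag present as ions |
| `recovery_factor` | 1 | measured total / nominal |
| `icpms_cv` | 0.05 | ICP-MS relative measurement noise |
| `n_icpms_replicates` | 3 | replicate measurements per level |
| `control_mortality`, `overdispersion_rho` | 0, 0 | baseline death, intra-well correlation |

Choices the design left open, fixed once here: the dissolved fraction is
constant over the exposure (ion levels in the medium are stable over 48 h;
a per-timepoint override hook exists for sensitivity analyses); ICP-MS noise
is multiplicative lognormal with unit mean — concentrations are positive and
instrument error is relative, and no other noise model is implied by the
data; 0.05 is a typical relative precision for ICP-MS at these
concentrations; a dissolved fraction of 0.25 is a realistic mid-range value
for a partially dissolving nanosilver suspension; three ICP-MS replicates
per level mirror the routine triplicate-measurement convention.
Overdispersion, when enabled, enters as beta-binomial wells with intra-class
correlation `overdispersion_rho` — wells of five neonates are a natural
clustering unit. Mortality and ICP-MS noise use separately seeded streams,
so toggling one leaves the other's draws unchanged.

Ground truths are closed-form: `true_suspension_ec50()` solves
$E_{total}(c^*) = 1/2$ by bracketed root finding to relative tolerance
1e-9, and `true_contributions()` evaluates the toxic-unit ratio at $c^*$.
`calibrate_to_contribution()` finds, by monotone root search over the ion
EC50, a truth whose exact ion contribution equals a requested target —
the backbone of the recovery tests (the search agrees with the closed form
$e_i = f\,e_p(1-t)/(t(1-f))$, which the tests use as an independent oracle).

What the generator does **not** emulate: dissolution kinetics (the
dissolved fraction is imposed, not mechanistically produced), bacterial
sequestration dynamics, time-dependent dose–response (both timepoints share
one truth unless overridden), and centrifugation losses. Passing recovery
tests therefore show that the estimation chain inverts the assumed
data-generating model correctly — not that real suspensions satisfy
response additivity or a constant dissolved fraction.

## Numerical choices and degenerate inputs

* Concentration 0 is handled by the closed-form limit $E(0)=0$, never
  `log(0)`.
* Fits require ≥ 3 distinct positive concentrations; all-zero or
  all-complete immobility is rejected as uninformative (complete
  separation).
* Fewer than 3 wells leaves no residual degrees of freedom and errors.
* Dissolved > total ICP-MS replicates are clipped to the total (with a
  warning), not dropped — dropping one tail of the noise biases the
  dissolved fraction.
* The speciation table refuses to extrapolate outside the measured
  concentration range; a suspension EC50 outside that range is an error, not
  a silent extension.
* Convergence is declared at gradient norm below 1e-10 after Newton
  polishing; a persistent norm above 1e-3 of the objective scale triggers a
  flat-likelihood warning.

## Test and simulation sizes

The suite's simulation-based checks use sizes chosen to balance Monte-Carlo
error against runtime on a single CPU: 120 replicates for dispersion
calibration, 240 for null uniformity of the EC50 comparison (KS test at
α = 0.01), 120 for its power against a 2-fold EC50 difference, 160 for Wald
coverage, 15–25 replicates per cell for contribution-recovery grids, and
100 replicates per condition in `scripts/acceptance.R`. Recovery of the
particle-curve parameters is asserted on the median over 30 replicates:
under the study design the particle slope is weakly identified (ions
dominate the low doses and both components saturate the high ones), so
single-replicate slope estimates scatter widely even at 50-fold occupancy —
a property of the design, not of the optimizer, which matches exhaustive
grid search on the same data.

## Known limitations

* Ion-curve uncertainty is not propagated into the particle-curve
  covariance or the contribution estimates; contributions are reported
  without standard errors.
* The recovered ion contribution is slightly biased upward when the ion
  EC50 lies near or above the top of the AgNO~3~ series (the contribution
  is a convex function of the ion EC50 estimate); averaging replicates at
  ten-fold occupancy keeps the bias within a few percentage points.
* One ion curve per timepoint is shared across conditions; if the true
  ionic potency differs between microbiome states the decomposition
  attributes that difference to the particle component.
* No alternative mixture models (concentration addition, interaction
  terms): response additivity is the fixed modelling frame.
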