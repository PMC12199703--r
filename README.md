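# agmix

Silver nanoparticles are toxic to aquatic organisms through two routes at
once: the particles themselves, and the silver ions they shed into the
medium. `agmix` implements the statistical chain used to separate those two
routes in acute immobilization tests with *Daphnia magna*, where the balance
between ionic and particulate toxicity shifts with the host's microbiome
(germfree, naturally colonized, or mono-associated animals). It is aimed at
ecotoxicologists analysing immobilization counts together with ICP-MS
speciation measurements, and at methodologists who want to stress-test the
decomposition on simulated data.

## The model

Each dose-response curve is a log-logistic with limits fixed at 0 and 1:

```
E(c) = 1 / (1 + (EC50 / c)^h),    h > 0
```

fitted to per-well binomial immobile counts by maximum likelihood, with a
Pearson quasi-binomial dispersion scale and Wald covariance on
`(log h, log EC50)`. EC50s are compared with a two-sided t-test on the
log-EC50 difference, variances scaled by the dispersion (floored at 1).

Suspension toxicity is decomposed by **response additivity** (independent
action): with ion effect `E_i` and particle effect `E_p`,

```
E_total = 1 - (1 - E_p)(1 - E_i)
```

The ion curve comes from an AgNO3 dilution series (dissolved-silver dose);
the particle curve is then estimated from the suspension data by maximizing
the binomial likelihood of the combined effect with the ion parameters held
fixed, on the particulate dose scale given by ICP-MS speciation
(particulate = total − dissolved). At the fitted suspension EC50, the
measured ion and particle concentrations are converted to **toxic units**
(`TU = C / EC50`) and each component's **relative contribution** is its share
of the summed toxic units.

A synthetic-data generator (`synthetic_truth()`, `generate_experiment()`)
reproduces the experimental design — 5 suspension concentrations of 5–50
µg/l, a two-fold AgNO3 series from 10 to 0.625 µg/l, wells of 5 neonates
with 20 animals per condition, scoring at 24 and 48 h, multiplicative ICP-MS
noise — together with closed-form ground truths, so every stage of the
pipeline can be checked by parameter recovery.

## Worked example

```r
library(agmix)

truth <- synthetic_truth(condition = "colonized", dissolved_fraction = 0.25,
                         ion_ec50 = 4, particle_ec50 = 30, seed = 2024)
ex  <- generate_experiment(truth)
ion <- fit_ll4(ex$immobility, condition = "agno3", timepoint = 48)
ion
#> Log-logistic dose-response fit (limits fixed at 0 and 1)
#>   condition: agno3   timepoint: 48 h
#>   slope h  : 5.411
#>   EC50     : 4.697 ug/l (SE of log EC50: 0.077)
#>   dispersion: 0.432 on 18 df (20 wells)

tab <- build_speciation_table(ex$speciation)
np  <- subset(ex$immobility, condition == "colonized" & timepoint_h == 48)
partition_condition(np, ion, tab)
#> Response-additivity partition of suspension toxicity
#>   condition colonized at 48 h
#>   suspension EC50: 14.346 ug/l nominal
#>   ion EC50 4.697, particle EC50 33.467 ug/l
#>   doses at EC50: ion 3.515, particle 10.686 ug/l
#>   toxic units: ion 0.748, particle 0.319
#>   contributions: ion 70.1%, particle 29.9%

true_contributions(truth)
#>       ion  particle
#> 0.7142857 0.2857143
```

The fitted ion EC50 (4.70 µg/l dissolved Ag) and particle EC50 (33.5 µg/l
particulate Ag) bracket the suspension EC50 of 14.3 µg/l nominal; at that
concentration the medium holds 3.5 µg/l ions and 10.7 µg/l particles, i.e.
0.75 vs 0.32 toxic units, so ions carry about 70% of the toxicity — close to
the generator's exact value of 71.4%. At the paper-scale design (20 animals
per concentration) a single experiment recovers the contribution to within a
few percentage points; averaging replicates tightens this (see the methods
vignette).

`run_pipeline()` drives the same analysis from CSV files (immobility
records, ICP-MS measurements, optional bacterial uptake records) through a
JSON/YAML config and writes curve, partition, and EC50-comparison tables
plus a run log.

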