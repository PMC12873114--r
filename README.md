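# ttrkinetics

Kinetic modelling of transthyretin (TTR) homeostasis and the effect of
kinetic stabilisers such as tafamidis.

TTR is a homotetrameric plasma transport protein. Its dissociated monomers
can misfold and aggregate into amyloid fibrils, causing transthyretin
amyloidosis (cardiomyopathy and neuropathy). Kinetic stabilisers bind the
tetramer's thyroxine sites and slow its dissociation — yet patients on
stabilisers also show a rise of more than 30% in circulating TTR, which is
not obviously explained by slower dissociation alone. This package implements
a minimal turnover model that makes the question quantitative, for
modellers and pharmacometricians working on TTR or on analogous
protein-homeostasis problems.

## The model

Tetramers `T` and monomers `M` (both in μM; tetramer concentration counts
tetramer particles, monomer concentration counts monomer particles) obey

    dT/dt = r + ka·M⁴ − (krem,T + kd)·T
    dM/dt = 4·kd·T − 4·ka·M⁴ − krem,M·M

with constitutive hepatic synthesis `r`, dissociation `kd`, effective
fourth-order reassociation `ka`, and first-order removal of each species.
At steady state, two fluxes compete for monomers: reassociation `4·ka·M⁴`
and elimination `krem,M·M`. Three regimes follow, each with its own closed
form and its own ceiling on what abolishing dissociation (kd → 0) can do to
the steady tetramer level:

| regime                  | Tst                  | maximal relative gain |
|-------------------------|----------------------|-----------------------|
| reassociation-dominated | r / krem,T           | 0                     |
| intermediate            | r / (krem,T + kd/2)  | kd / (2·krem,T)       |
| degradation-dominated   | r / (krem,T + kd)    | kd / krem,T           |

At the reference values (kd = 0.0024 h⁻¹, krem,T = 0.016 h⁻¹) the best case
is a 15% rise — half the clinical observation, which is the model's central
point: dissociation suppression alone cannot explain the clinical TTR rise.

Around this core the package provides:

* a two-compartment oral PK model of the stabiliser (simulation and
  least-squares fitting to plasma profiles),
* the phenomenological exponential link `kd(c1) = kd0·exp(−λ·c1)`
  (λ = 0.112 μM⁻¹ for tafamidis) estimated from subunit-exchange
  measurements, which absorbs all plasma binding competition without
  modelling it,
* a coupled therapy simulator (PK → kd(c1(t)) → turnover),
* a mechanistic simulator of the subunit-exchange assay itself (tetramers
  with 0–4 labelled subunits) and a kd estimator for assay time courses,
* seeded synthetic-data generators for every input, so all estimators are
  testable end to end by parameter recovery.

## Worked example

```r
library(ttrkinetics)
rep <- run_ttr_analysis(default_analysis_config(seed = 1),
                        simulate_therapy_pk = FALSE)
print(rep)
```

```
TTR stabilisation analysis (ttrkinetics 0.1.0 | seed 1 )

Regime analysis:
  reassociation_dominated   r = 0.10304 uM/h, krem_M = negligible /h, gain bound = 0.0%
  degradation_dominated     r = 0.11850 uM/h, krem_M = 100 /h, gain bound = 15.0%
  intermediate              r = 0.11077 uM/h, krem_M = 50.02 /h, gain bound = 7.5%

PK: average steady-state c1 = 25.00 uM -> kd_eff = 0.000146 /h
Therapy (degradation-dominated): TTR rise = 13.96% (baseline 6.440 -> 7.339 uM)
Clinical comparison (observed rise > 30%):
  reassociation_dominated   bound 0.0% -> additional mechanisms required
  degradation_dominated     bound 15.0% -> additional mechanisms required
  intermediate              bound 7.5% -> additional mechanisms required
```

Reading this: from the observed serum tetramer level (6.44 μM) and the
independently measured rates, each regime implies its own synthesis rate
(0.103–0.119 μM·h⁻¹; the reassociation value is the one conventionally
printed as 0.1) and monomer removal rate. A 61 mg daily tafamidis regimen
gives an average steady plasma exposure of ~25 μM, which cuts the
dissociation rate ~16-fold and — in the most favourable, degradation-dominated
regime — raises steady-state TTR by 13.96%, just under the 15% theoretical
ceiling and well short of the >30% seen clinically. Every regime's bound
falls short, hence the "additional mechanisms required" flags.

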