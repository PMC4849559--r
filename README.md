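# stablecad

A lifetime decision model for patients with **stable coronary artery disease
(stable-CAD)** — people who are at least six months past an acute coronary
event, or who have stable angina or another chronic coronary diagnosis. The
package answers two questions a health system planner asks about this large,
heterogeneous population:

1. **What do these patients cost, and what health do they accrue, over the
   rest of their lives** — stratified by their baseline cardiovascular risk?
2. **What is the most a payer should pay per year for a new treatment** that
   reduces cardiovascular risk by a given fraction, at a given
   cost-effectiveness threshold, for each risk stratum?

It is written for health economists and biostatisticians who want a fully
synthetic, reproducible version of this analysis: real linked-EHR datasets
of this kind are access-restricted, so the package ships a synthetic-cohort
generator whose marginals emulate a published stable-CAD baseline table, and
every downstream stage is estimated from (and validated against) that known
data-generating process.

## The model

**Risk equations.** Five primary endpoints — non-fatal myocardial infarction
(MI), non-fatal ischaemic stroke, non-fatal haemorrhagic stroke, CVD death
and non-CVD death — are modelled with cause-specific parametric
accelerated-failure-time equations with location
μ<sub>i</sub> = x<sub>i</sub>'β over the full baseline covariate vector
(demographics, CAD subtype, severity, risk factors, comorbidities,
psychosocial factors, biomarkers). Four families are fitted by maximum
likelihood and the best is selected per endpoint by AIC:

- exponential: S(t) = exp(−t·e<sup>−μ</sup>)
- Weibull: S(t) = exp(−(t·e<sup>−μ</sup>)<sup>1/σ</sup>)
- lognormal: S(t) = 1 − Φ((ln t − μ)/σ)
- generalised gamma (Prentice μ, σ, Q), which nests the Weibull at Q = 1 and
  the lognormal as Q → 0.

Six further equations model CVD and non-CVD death after each non-fatal
event, with sex and age at event as the only covariates (clock reset at the
event). Non-CVD mortality beyond 10 years of model time is spliced to an
age/sex life table via the rate −ln(1 − q<sub>x</sub>). That makes **11 risk
equations** in total.

**Competing risks.** Cause-specific cumulative hazards H<sub>k</sub>(t) are
composed into cumulative incidence functions
F<sub>k</sub>(t) = ∫ h<sub>k</sub>(u) S(u) du with
S(t) = exp(−Σ<sub>k</sub> H<sub>k</sub>(t)), by splitting each fine-step
survival drop between causes in proportion to their cumulative-hazard
increments — exact for constant hazards and mass-conserving
(S + Σ F<sub>k</sub> = 1) to machine precision.

**Markov cohort model.** Six states (stable-CAD, post-MI, post-ischaemic
stroke, post-haemorrhagic stroke, CVD death, non-CVD death) in 90-day
cycles, run to extinction with a 110-year age cap. Per-cycle costs come from
a two-component (CVD-attributable + other) log-link panel cost model;
utilities come from a sex/age-band EQ-5D-style catalogue with condition,
post-event and acute-cycle multipliers. Costs, life years and QALYs are
discounted at 3.5% per year. An individual-level **microsimulation oracle**
samples the same per-cycle transition probabilities and must agree with the
cohort expectations within Monte Carlo error — this is the package's central
correctness check.

**Stratification, PSA, pricing.** Patients are ranked by their 5-year
composite CVD risk (the sum of the four CVD CIFs at 5 years) and split into
tenths; the model runs at each group's mean covariate vector and for a
median-risk representative patient. Parameter uncertainty is propagated by
Monte Carlo (multivariate normal on coefficient vectors, beta perturbations
on utilities; 1,000 iterations by default). The maximum annual price for a
treatment that multiplies CVD hazards by (1 − ρ) is

p\* = max(0, (λ·ΔQALY − ΔCost) / E),

with ΔQALY and ΔCost discounted increments versus standard care and E the
treated arm's discounted years of treatment exposure.

## Worked example

```r
library(stablecad)

truth   <- default_true_parameters()
cohort  <- generate_cohort(20000, seed = 1)
events  <- simulate_event_histories(cohort, truth, seed = 2)
panel   <- simulate_cost_panel(cohort, events, truth, seed = 3)

set  <- fit_risk_equations(cohort, events)     # 11 equations, AIC-selected
cost <- fit_cost_model(panel, cohort)
util <- default_utility_catalogue()

groups <- assign_risk_groups(cohort, set, k = 10)
low  <- run_cohort(groups[[1]]$mean_covariates,  set, cost, util)$outputs
high <- run_cohort(groups[[10]]$mean_covariates, set, cost, util)$outputs
print(low)
```

On this synthetic world (the `analysis/` defaults: n = 20,000, seed
20260918) the cohort's mean 5-year composite CVD risk is 17.2% while the
risk at the mean covariate vector is 15.0% — the convexity gap a
heterogeneous cohort produces. The lowest-risk tenth (5-year risk 5.2%) has
30.5 remaining life years, 13.0 discounted QALYs, £55,545 discounted
lifetime costs and 20.4% lifetime CVD mortality; the highest-risk tenth
(risk 37.0%) has 5.6 life years, 3.0 discounted QALYs, £27,719 discounted
costs and 38.1% CVD mortality. That is the characteristic gradient of this
analysis: lower risk means more remaining life, more QALYs and *higher*
lifetime healthcare costs (more years alive to accrue them) — and even the
highest-risk tenth is more likely to die of non-CVD than CVD causes.
Pricing (`analysis/06_price.R`) then prints, for a 20% hazard reduction at
£20,000/QALY, a maximum annual price of £218/yr in the lowest tenth rising
to £530/yr in the highest; all four effect sizes order the same way
(£110–£265 at 10% up to £427–£1,060 at 40%).

The `analysis/` directory holds the full numbered workflow
(`01_simulate.R` … `06_price.R`); each stage reads the previous stage's
outputs from `results/` and prints a short narrative summary.

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch against the
installed package — simulate a cohort, fit the 11 equations and the cost
model, stratify into risk tenths, run the lifetime model, the PSA and the
pricing grid — and writes its report to the path given by `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All pipeline artefacts (cohort, fitted equations, group results, PSA
summaries, pricing grid, manifest) are written next to the report.
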