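---
title: "The stable-CAD lifetime decision model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The stable-CAD lifetime decision model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stablecad)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the known limitations. It states no empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## 1. The decision problem

Patients with stable coronary artery disease (stable-CAD) — stable angina,
other chronic coronary diagnoses, or at least six months event-free after an
acute coronary syndrome — form a large population whose future is dominated
by five competing first events: non-fatal myocardial infarction (MI),
non-fatal ischaemic stroke, non-fatal haemorrhagic stroke, cardiovascular
(CVD) death and non-CVD death. A payer deciding whether (and at what price)
to fund a risk-reducing treatment needs, per baseline-risk stratum, the
remaining lifetime costs and quality-adjusted life years (QALYs) under
standard care and under the treatment. The package estimates both from a
cohort with linked baseline covariates, event histories and per-cycle costs,
and — because real linked-EHR datasets of this kind are access-restricted —
ships a synthetic-data module that plays the role of that dataset with a
fully known data-generating process.

## 2. Model structure

Six states: **stable-CAD** (entry), **post-MI**, **post-ischaemic-stroke**,
**post-haemorrhagic-stroke**, **CVD death**, **non-CVD death**. Only first
occurrences of non-fatal events are explicit states; later non-fatal events
are captured implicitly through time-since-event effects on post-event
mortality, costs and utilities. The cycle length is 90 days
(`90/365.25` years everywhere; a single constant prevents unit drift), and
the model runs until the living occupancy is extinct, with an attained-age
cap of 110 (the life table's terminal row has q = 1, so extinction follows
within a few cycles of the cap).

### The 11 risk equations

Five cause-specific equations govern exit from the stable state, each an
accelerated-failure-time (AFT) model with location `mu = x'beta` over the
full baseline covariate vector. Four families are fitted by maximum
likelihood — exponential, Weibull, lognormal, and generalised gamma in the
Prentice (mu, sigma, Q) form, which nests the Weibull at Q = 1 and the
lognormal as Q → 0 — and the per-endpoint family is chosen by AIC, with ties
(ΔAIC < 1e-6) broken toward fewer parameters. Six further equations govern
CVD/non-CVD death after each non-fatal event, with the clock reset at the
event and **only sex and age at event** as covariates (post-event event
counts are an order of magnitude smaller, so the covariate set is
deliberately minimal). That makes 11 equations; the constructor refuses any
other count.

Non-CVD mortality beyond the splice time (default 10 years, the follow-up
horizon the equations can be estimated on) comes from an age/sex life table
as the rate `-log(1 - q_x)` at the attained integer age. The splice applies
in *every* live state: the post-event parametric non-CVD hazard is used only
while cohort time is inside the splice window. A terminal-age q of 1 is
mapped to a large finite rate (`-log(1e-12)` per year) so that "certain
death within the year" needs no infinity arithmetic.

### Competing-risks composition

Within each fine step the exact survival drop `S(t1) - S(t2)`, with
`S = exp(-sum_k H_k)`, is split between causes in proportion to their
cumulative-hazard increments. This is exact for constant hazards,
second-order accurate otherwise, needs no within-cycle event-ordering
assumption, and conserves `S + sum_k F_k = 1` to machine precision — the
conservation tolerance in the tests (1e-8) is loose relative to what the
construction achieves. Cumulative hazards (closed-form for all four
families, piecewise-linear for the life-table part) are used instead of
hazards so that singular hazards (Weibull with sigma > 1 at t = 0) integrate
exactly. The default within-cycle subdivision is 64: halving the step at
that resolution moves no CIF value by more than 1e-7 (the adequacy rule the
tests enforce).

### Accrual conventions

Costs accrue per full cycle to the cycle-start state — the panel-billing
convention matching how the cost model is estimated (90-day cost windows).
Person-time (life years, QALYs, treatment exposure) accrues by within-cycle
trapezoid: mass that transitions to death during a cycle accrues half a
cycle, valued at its starting state's utility. The trapezoid removes the
+half-cycle bias a pure cycle-start rule would put on life expectancy
(about +1.85% at a total hazard of 0.15/year) and brings the engine within
0.5% of closed-form life expectancy at 90-day cycles; it is the one place
this implementation deviates from a literal "Delta per live state-cycle"
rule, and the microsimulation mirrors it exactly. Discounting is 3.5% per
annum applied at cycle-start time; expected time to first event uses the
plain cycle-start sum `sum_j S(t_j) * Delta` (its half-cycle bias is part of
the quantity's definition here, identical in both engines).

### Semi-Markov bookkeeping

Post-event mortality depends on age at event and time since event, so
post-event occupancy is tracked per entry cycle (a "slice" ledger). Events
are dated mid-cycle: mass leaving stable during cycle e enters the
post-event state at cycle e+1 with age-at-event `age_entry + (e + 1/2)Delta`.
Acute-cycle cost uplifts and utility decrements apply in the first cycle
occupied post-event (`cycles_since_event = 0`).

### The microsimulation oracle

`microsim_oracle()` samples individual trajectories from the *same*
per-cycle transition probabilities, costs and utilities the cohort engine
uses, so the two agree in expectation by construction — any systematic
discrepancy is a bug, not discretisation. The acceptance suite checks every
output field over 10 random parameter draws at n = 100,000 within 3 Monte
Carlo standard errors, with a binomial fallback tolerance for percentage
fields whose simulated count is zero.

## 3. The synthetic world

`generate_cohort()` draws covariates from the marginal distributions of a
published stable-CAD baseline table (44% female; mean entry age 67 for men
and 72 for women; stable angina 47% of subtypes; hypertension 76%;
heart failure 26%; and so on), with continuous biomarkers from a Gaussian
copula (default correlation 0 — the source table publishes only marginals)
with truncated-normal marginals so positivity is exact.
`simulate_event_histories()` draws independent latent cause-specific AFT
times (which reproduces the intended cause-specific hazards exactly),
exponential administrative censoring with a median follow-up of 4.2 years,
and post-event mortality with the clock reset at the event.
`simulate_cost_panel()` emits one row per 90-day cycle while alive and
uncensored, with two non-negative cost components (CVD-attributable and
other) and multiplicative mean-one gamma noise.

The ground-truth coefficients are the package's own choices — the source
material gives marginals and qualitative gradients, not a data-generating
process. They were fixed once, before the test expectations were frozen, to
match the published cohort's anchors: a mean 5-year composite CVD risk in
the mid-teens of percent, roughly an eight-fold spread between the lowest
and highest risk tenths, about one patient in five dying during follow-up,
and risk at the mean covariate vector below the mean risk (the convexity
signature of a heterogeneous cohort). What the generator does **not**
emulate: missingness and imputation, practice-level entry/exit, covariate
drift over time, repeat non-fatal events, and any correlation structure
beyond the configurable biomarker copula. A green test therefore
establishes that the estimation and decision machinery is faithful to a
known world of this structure — not that the synthetic numbers are
clinically calibrated.

## 4. Estimation choices

* **Optimisation.** BFGS on the free parameters (beta, log sigma, Q) with
  analytic gradients for exponential/Weibull/lognormal and numeric gradients
  for the generalised gamma, multi-started from the fitted Weibull (Q = 1)
  and lognormal (Q ≈ 0) solutions. Initial values come from the closed-form
  exponential rate. The variance-covariance matrix is the inverse observed
  information (numeric Hessian), with an eigenvalue pseudo-inverse fallback.
  The generalised gamma is only attempted with at least 30 events — below
  that Q is poorly identified.
* **Small-sample fallbacks.** A primary endpoint with fewer than 10 events
  falls back to an exponential with (intercept, age, sex), then to an
  intercept-only exponential; post-event equations pool the three post-event
  strata first. Fallbacks are visible in the returned AIC table via their
  endpoint labels. This keeps a 2,000-patient smoke cohort estimable
  (haemorrhagic stroke is rare) without touching the large-sample path.
* **Cost model.** Two quasi-Poisson log-link GLMs (CVD component, other
  component; their sum is the total, making "CVD cost ≤ total cost" an
  identity) over baseline covariates, state indicators, an acute-cycle
  indicator, a time-since-event band (acute / cycles 1-3 / later) and
  current age, with cluster-by-patient sandwich variances (within-patient
  cost series are serially correlated). Chosen because per-cycle costs are
  non-negative and right-skewed; the estimator needs only the mean to be
  correctly specified.
* **Utilities.** Multiplicative composition: sex/age-band base utility ×
  condition multiplier × post-event multiplier × acute multiplier in the
  event cycle. The catalogue gives levels, not a composition rule;
  multiplicative is the standard convention and keeps utilities inside the
  EQ-5D range by construction. The shipped catalogue is a synthetic
  stand-in (no licensed value set is redistributed) with the published
  catalogues' structure.

## 5. Stratification, PSA and pricing

Baseline risk is the sum of the four CVD CIFs at 5 years under the
competing risk of non-CVD death. Patients are ranked (stable sort, ties by
patient id) and split into contiguous tenths whose sizes differ by at most
one. Group-level runs use the mean covariate vector with categorical
covariates entered as level proportions — fractional indicator rows are
first-class inputs throughout the engine — plus a median-risk
representative patient (lower of the two central members at even sizes).

PSA draws coefficient vectors from multivariate normal distributions on the
estimation scale (survival: beta, log sigma, Q jointly from the full vcov;
costs: each component's coefficients from the cluster-robust vcov) and
perturbs utilities with beta distributions matched to mean and a small
standard deviation (default 0.02). Draws are clamped to ±30 around the
estimate on the location scale: a shift of 30 log-years is already
"immediately/never", and unclamped draws from non-identified coefficients
(zero-event sparse indicators in small cohorts) would overflow the hazard
arithmetic. Non-positive-semi-definite vcov matrices are repaired by
eigenvalue clipping, with a warning. Intervals are 2.5/97.5 percentiles of
1,000 iterations by default.

One behaviour worth knowing: lifetime outputs are convex in the
log-scale survival parameters, so the Monte Carlo mean sits above the
deterministic point estimate (Jensen's inequality), by an amount that grows
with the coefficient uncertainty. With a large estimation cohort the shift
is negligible; with a few thousand patients it can push the deterministic
point below the percentile interval for the most extreme risk tenths. Read
the intervals against the probabilistic mean — standard practice in
cost-effectiveness reporting — and treat a visible gap as a flag that the
estimation cohort is small relative to the covariate dimension.

Pricing: for hazard reduction rho, the treatment multiplies the four CVD
cause-specific hazards by (1 - rho); non-CVD mortality is never touched.
Two open questions in the source are exposed as configuration switches and
defaulted as follows: haemorrhagic stroke **is** treated (the treated
composite groups "MI, stroke and CVD death"), and post-event CVD-death
hazards **are** treated (they are CVD risks). The maximum annual price is
`p* = max(0, (lambda * dQALY - dCost) / E)` with discounted increments and
`E` the treated arm's discounted treatment years — paid in all live states
by default (a switch restricts payment to the event-free state), and
annualised over *discounted* years; the undiscounted alternative would
change p* by roughly the ratio of discounted to undiscounted life
expectancy.

## 6. Numerical and degenerate-input behaviour

* Hazard-increment caps at 700 per fine step keep `Inf - Inf` out of the
  cause split under pathological PSA draws (an increment of 700 is already
  certain transition).
* An unreachable stable state (`S(t_j) = 0`) yields an absorbing self-loop
  with a logged warning rather than 0/0.
* A horizon cap that binds with live mass above 1e-6 triggers a warning
  reporting the residual; lifetime mortality percentages then sum to less
  than 100 by that residual.
* Life tables must be contiguous in age with a terminal q of 1; utility
  lookups outside the band range fall back to the nearest band with a
  warning.
* All randomness is seed-scoped (`with_seed` restores the caller's RNG
  state), and the pipeline fans one master seed into per-stage substreams
  so stages can be re-run independently yet reproducibly.

## 7. Known limitations

* Baseline covariates (including age) stay frozen in the primary risk
  equations over model time; ageing enters through the life-table splice,
  utilities and costs. The alternative — advancing age inside the primary
  equations — would double-count ageing already implicit in the baseline
  hazard's time dependence.
* No repeat non-fatal events; a second MI neither moves the patient nor
  resets the clock (its cost/utility consequences are only as captured by
  the time-since-event terms).
* The cost model's acute/recent banding is coarse (0, 1-3, 4+ cycles).
* PSA treats the 11 equations as independent blocks (no cross-equation
  correlation), which understates joint uncertainty where equations share
  patients.
* Synthetic-world caveats in Section 3 apply to every empirical number the
  analysis scripts print.
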