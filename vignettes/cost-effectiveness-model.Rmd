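---
title: "A Markov cohort cost-effectiveness model for mepolizumab in severe eosinophilic asthma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort cost-effectiveness model for mepolizumab in severe eosinophilic asthma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mepoCEA)
```

## The decision problem

Severe eosinophilic asthma exposes patients to recurrent clinically
significant exacerbations (CSEs) — episodes needing systemic
corticosteroids, an emergency-department (ED) visit, or hospitalization.
Mepolizumab, an anti-IL-5 biologic given as 100 mg subcutaneously every
4 weeks on top of standard of care, cuts the exacerbation rate to roughly a third but
carries a high acquisition price.  `mepoCEA` implements a
societal-perspective Markov cohort model that weighs that price against
avoided exacerbation management costs, avoided adverse-event (AE) burden,
avoided productivity losses, and quality-adjusted survival gains, for a
Chinese cohort entering at a mean age of 52.2 years.

## Model structure

The cohort occupies one of five states on a 2-week cycle (26 cycles per
model year):

* `NO_CSE` — exacerbation-free, on maintenance therapy;
* `CSE_OCS`, `CSE_HOSP_ED`, `CSE_HOSP` — one-cycle *tunnel* states for an
  exacerbation managed with oral corticosteroids only, requiring an ED
  visit, or requiring hospitalization.  A typical exacerbation resolves
  within two weeks, which motivates both the cycle length and the tunnel
  design; survivors return to `NO_CSE` after one cycle;
* `DEATH` — absorbing.

Each cycle, patients in `NO_CSE` die with the age-specific
exacerbation-free asthma mortality probability, or (surviving) enter an
exacerbation with the per-cycle exacerbation probability apportioned
across the three substates by a fixed severity split.  Occupants of an
exacerbation state face a higher, age-specific exacerbation mortality.
The stay probability is always computed as the row remainder, so the
transition matrix remains row-stochastic for any (even perturbed) split.

Two rate conversions coexist deliberately:

* **Exacerbation rates** are event rates (events/person-year) and are
  divided by 26: annual rates 0.45 and 1.31 become 0.01731 and 0.05038
  per cycle — the only conversion consistent with those published
  per-cycle values.
* **Mortality probabilities** use the compound formula
  $p_{cycle} = 1 - (1 - p_{annual})^{1/26}$, so that compounding over a
  year recovers the annual probability exactly.

Costs and QALYs accrue on the trapezoidal average of entry and exit
occupancy (half-cycle correction, on by default) and are discounted at 5%
per year via $(1+r)^{-k/26}$ for cycle $k$.  The simulation runs from age
52.2 until a terminal age of 100 years — a conventional cap chosen
because asthma-specific mortality alone would never fully absorb the
cohort — or until living occupancy falls below $10^{-9}$.

Age advances continuously (52.2 + $k$/26); mortality and employment
lookups use the containing half-open age band, the last band being
open-ended.

## Mortality derivation

Exacerbation-free asthma mortality is derived stepwise from three
age- and gender-stratified tables: asthma death counts, survey asthma
rates, and census population.  Per stratum the annual probability is
`deaths / (rate × population)` — deaths among the implied asthma cases —
and gender-specific values are averaged with population weights.
`derive_mortality_table()` is agnostic about whether the survey rate is
an incidence or a prevalence; it consumes whatever case-rate table is
supplied.  Exacerbation-state mortality is supplied as its own
age-indexed table and must dominate the exacerbation-free channel in
every band.  `toy_mortality_inputs()` fabricates source tables whose
derivation recovers known true rates exactly, which is how the stage is
tested without the original national datasets.

Background non-asthma mortality is not included by default — the model
follows the disease-specific channel only — and this is the main reason
absolute life expectancy here should not be read as general-population
life expectancy.

## Rewards

Per cycle and state, five cost ledgers are assembled (all USD; CNY inputs
are divided by 7.0467):

* **drug** — dose price amortized over the dosing interval
  ($682.02 / 2 = \$341.01$ per cycle for mepolizumab).  Acquisition cost
  accrues over a configurable `treatment_duration_years` window (fixture:
  1 year, mirroring the 52-week dosing horizon of the pivotal trial;
  `Inf` gives lifelong dosing).  Amortization rather than pulsed dosing
  is used because, under half-cycle correction, the two differ
  negligibly while amortization keeps the reward schedule smooth;
* **monitoring** — a flat per-cycle routine cost in all alive states;
* **ae** — $\sum_j f_j c_j / 26$ over the arm's AE table, the 52-week
  trial incidence spread evenly over a year of cycles.  AE burden attaches
  to every alive state in the arm (it follows treatment, not the
  exacerbation state) and accrues for life by default;
* **cse_management** — per-event management cost of the occupied substate;
* **indirect** — human-capital productivity loss on exacerbation cycles
  only: (missed workdays + presenteeism day-equivalents) × daily wage ×
  age-band employment rate, with 1 missed day for the outpatient tier and
  6.4 for both hospital tiers (the ED-only share is not separately
  reported, so both hospital tiers use the hospitalized figure).

Utilities start from the exacerbation-free baseline of 0.84; exacerbation
substates subtract their decrement for the cycle, and every alive state
subtracts the frequency-weighted AE disutility $\sum_j f_j d_j / 26$.
The per-cycle utility is floored at 0 so that extreme sensitivity draws
cannot produce negative quality weights.

## Comparison statistics

`ce_compare()` reports incremental cost $\Delta C$, incremental QALYs
$\Delta E$, and either the ICER $\Delta C / \Delta E$ or a dominance
classification ("dominant": cheaper and more effective; "dominated":
dearer and less effective).  Incremental net monetary benefit is
$\lambda \Delta E - \Delta C$ at willingness-to-pay $\lambda$; the
evaluation band is \$15,217–\$38,042 per QALY (1.2–3.0 × China's 2023
per-capita GDP).

## Uncertainty analyses

* **Subgroups** keep a uniform comparator exacerbation rate and set the
  intervention rate to comparator rate × subgroup rate ratio (RR).
* **Deterministic sensitivity (tornado)**: each annotated parameter is
  pushed to the ends of its range (±20% by default; RRs over their 95%
  CIs; the baseline utility over its literature range 0.78–0.90), one at
  a time, restoring and re-verifying the base case.  Out-of-domain range
  ends are clamped with a warning.  Dominant outcomes have no ICER, so
  entries are ordered by the spread of the *ordering value* — the raw
  $\Delta C/\Delta E$, which extends the ICER continuously (negatively)
  through dominance.
* **Probabilistic sensitivity**: each annotated parameter is drawn from
  its distribution — beta for probabilities and utilities, gamma for
  costs and disutility magnitudes, lognormal for rate ratios (all
  parameterized so the sampling mean equals the point estimate; a load
  check rejects specs whose mean drifts more than 5%) — and both arms are
  re-run per iteration.  Every parameter owns an independent random
  stream derived from the master seed and a stable hash of its path, so
  results are bitwise reproducible and adding a parameter never
  reshuffles the others' draws.  Out-of-domain draws are rejected and
  re-drawn (at most 100 rounds).  The substate split is excluded from
  the PSA list: its three proportions form a sum-to-one partition, and
  none of the prescribed distribution families respects that constraint
  jointly (a Dirichlet would; it is not part of the standard assignment),
  so perturbing them independently would distort the partition rather
  than express parameter uncertainty.
* **CEAC**: the probability of cost-effectiveness is the fraction of
  draws with positive incremental net monetary benefit, on a default grid
  of \$0–\$45,000 in \$500 steps.

CSE-rate uncertainty is expressed on the annual scale and re-converted
per draw, keeping parameters on their reported scale.  The placebo rate
and the intervention rate are sampled independently (the alternative —
sampling placebo rate and RR — is a one-line change in the sampling-spec
list).

## The synthetic fixture

No supplementary data ship with the package.  `reference_fixture()` sets
every parameter printed in the main analysis text to its printed value
(annual rates 0.45/1.31, utility 0.84, \$682.02 per dose every 4 weeks,
missed days 1/6.4, 7.0467 CNY/USD, 5% discount, start age 52.2, WTP band
15,217–38,042, per-cycle AE costs \$33.54/\$39.56) and tags them
`published`; everything that only appeared in supplementary tables —
the substate split (0.62/0.23/0.15), management costs (30/350/1000),
monitoring (\$18/cycle), the 14-row AE tables, substate disutilities
(0.10/0.16/0.20), the mortality tables, wages and employment (daily wage
\$46.50; employment 0.78 to age 50, 0.62 to 60, 0.30 to 65, 0 after),
presenteeism (10 day-equivalents per exacerbation) and the subgroup RRs —
carries plausible `assumed` values.  The AE tables are the one calibrated
element: assumed incidence patterns are scaled per arm so the
frequency-weighted per-cycle cost equals the printed per-arm aggregates
exactly, since those aggregates *are* main-text values.

The assumed values were chosen once so the fixture lands in the published
regime — extra cost, extra QALYs, an ICER below the lower WTP bound, and
dominance emerging in low-RR subgroups through the productivity and AE
offsets — without tuning toward the published totals.  Consequently the
fixture reproduces the published *regime and mechanics*, not the exact
base-case numbers (\$399.17, 0.47028, \$848.79), which require the
original supplementary tables.  A user holding those tables can write
them into the fixture via `write_parameters()` / `load_parameters()` and
re-run everything unchanged.

What passing tests on this fixture do **not** show about real data: the
fixture's mortality, management costs and AE tables are stand-ins, so
absolute totals have no external validity; only the printed parameters,
the conversion arithmetic, and the model mechanics are anchored.

`random_parameters()` draws fully valid parameter sets from wide legal
ranges (utilities 0.3–1, rates 0–4/year, costs up to \$10,000, RR
0.1–1.5) with 15–30-year horizons, which keeps the 100-set invariant
sweep and the 50,000-individual microsimulation comparisons fast.

## Numerical choices and verification

* Cohort runs assert occupancy conservation (rows sum to 1 within
  $10^{-9}$) and monotone death occupancy every cycle.
* An individual-level microsimulation (`microsim_oracle()`) re-implements
  the trajectory sampling independently of the cohort algebra; cohort
  totals agree within 3 Monte-Carlo standard errors at $n = 50{,}000$
  across random parameter sets, and exactly on deterministic parameters.
* An immortal, undiscounted, exacerbation-free cohort accrues exactly
  utility × years — the closed form the engine must hit to machine
  precision.
* Probability conversions round-trip through compounding to $10^{-12}$.
  Note that $1-(1-p)^{1/26}$ is convex in $p$ (its slope diverges as
  $p \to 1$), and its agreement with the linear rate conversion is ~1%
  at an annual probability of 0.02 and ~2.5% at 0.05.
* Halving the cycle length (1-week cycles, 52 per year) changes lifetime
  QALYs by about 1.3% on the fixture.  The residual is structural, not
  numerical: exacerbations are one-cycle tunnels, so shortening the cycle
  also shortens the modelled exacerbation, halving disutility and
  excess-mortality exposure per event.  This is a known limitation of the
  tunnel design.
* Problem sizes used in the shipped checks — 100 random parameter sets
  for invariants, 5 × 50,000 individuals for oracle agreement, 1,000 PSA
  iterations — are the package's chosen verification sizes; the full
  10,000-iteration PSA is a single argument change.

## Known limitations

* Exacerbation duration is locked to one cycle; multi-cycle or
  history-dependent exacerbations are out of scope.
* Treatment efficacy (the exacerbation rate) is constant for life,
  extrapolating the 52-week trial.
* Background all-cause mortality is omitted by default (an optional
  competing channel can be added by raising the state-specific tables).
* The friction-cost alternative to human-capital indirect costing is not
  implemented.
* Only two arms are compared; no frontier analysis or EVPI.

## A worked run

```{r base-case}
params <- reference_fixture()$parameters
params

res <- run_base_case(params)
res
head(cost_composition(res))
```

```{r subgroups}
run_subgroups(params)[, c("name", "rr", "icer", "classification")]
```

```{r dsa}
dsa <- run_dsa(params)
head(dsa[, c("parameter", "value_low", "value_high", "spread")])
```

```{r psa}
psa <- run_psa(params, n = 500, seed = 42)
cc <- ceac(psa)
cc[cc$wtp %in% c(0, 5000, 15000, 25000), ]
```
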