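---
title: "Multi-perspective cost-effectiveness analysis with perspecta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-perspective cost-effectiveness analysis with perspecta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perspecta)
```

## The problem

Cost-effectiveness analyses (CEAs) of health programs in low- and
middle-income countries usually adopt a *health sector* perspective: the
costs counted are those paid by governments and donors. Patients, however,
face their own costs — transport fares, hours of travel and waiting — and
those costs shape whether people actually use a service. perspecta
implements a companion methodology: run the same CEA under a *patient*
perspective alongside the health-sector one, convert each strategy's
lifetime patient cost into an equivalent annual cost, compare it with an
affordability threshold, and classify how the two perspectives align.

The packaged case study compares six antiretroviral (ARV) delivery
strategies for adults living with HIV in Mozambique: monthly clinic refills
(the pre-Covid standard), 3-month clinic refills (status quo), 6-month
clinic refills, 3-month clinic refills with loss-to-follow-up (LTFU) case
management, 3-month community distribution by mobile brigade, and a 50/50
mix of 6-month clinic and 3-month community distribution.

## The disease model

The state space has 17 states: four CD4 bands (>500, 350–500, 200–349,
<200 cells/µL) crossed with four care statuses (on first-line ART, off ART
but first-line eligible, on second-line ART, off ART second-line only), plus
an absorbing death state. Everyone enters on ART with a CD4 band drawn from
the initiation distribution and a treatment line drawn
Bernoulli(`pct_first_line`).

Each monthly cycle resolves events by sequential conditional draws in a
fixed order — death, then LTFU or re-engagement, then line switch or
second-line failure, then CD4 band drift — so outgoing probability mass per
state sums to one by construction (staying put is the residual). The
conversions are the standard decision-analysis ones:

* rates $r$ per 100 person-years become monthly probabilities
  $1 - e^{-r/1200}$ (constant hazard);
* an $m$-month risk $P$ becomes $1 - (1-P)^{1/m}$ (geometric
  de-compounding), which compounds back to $P$ exactly;
* odds ratios act on the odds scale,
  $P' = \mathrm{OR}\,o/(1+\mathrm{OR}\,o)$ with $o = P/(1-P)$.

The multi-month LTFU odds ratios are reported against the 1-month clinical
distribution over two years, so the baseline they adjust is the 20%
12-month risk compounded to 24 months (0.36); the adjusted 2-year risk is
then de-compounded to a monthly hazard. The community arm's LTFU enters as
a rate (5.1/100 person-years). Tracing (the case-management arm) raises the
12-month re-engagement probability from 15.1% to 37.1%.

CD4 is modelled as bands, not counts, so annual drift $D$ (gain 205 on
suppressive ART, decline 14 on failing second-line ART, decline 60 off ART)
becomes a monthly band-crossing probability $\min(1, |D|/(12W))$ with $W$
the current band's width (150 cells/µL; 200 for the <200 band) — an
expected-crossing-time approximation. There is no upward exit from the top
band and no downward exit from the bottom one.

Choices the sources leave open, and what we did:

* **Mortality on ART.** The published table gives untreated mortality by
  CD4 band only. All survival benefit of treatment is routed through CD4
  dynamics: everyone faces the band-specific untreated rate, and ART helps
  by moving people up bands. There is no background (non-HIV) mortality,
  which is why simulated survival runs longer than the published means;
  orderings between strategies are unaffected.
* **Second-line failure.** Failure (15/100 person-years) flips a persistent
  per-person flag: the person stays on second-line ART but CD4 drifts down
  at the on-ART failure rate (14 cells/µL/yr) instead of rising. There is
  no third line; the flag survives LTFU and re-engagement.
* **Severe disease proxy.** WHO clinical stage III/IV — which forces
  monthly clinic refills in every strategy — is proxied by CD4 < 200. The
  forced 1-month schedule also applies during the first three months on
  ART, cumulatively counted (re-engaging after LTFU does not restart it).
  While on the forced schedule the person also faces the 1-month-strategy
  LTFU hazard, since the hazard is tied to the distribution modality.
* **Mixed strategy.** Persons are assigned permanently at baseline, 50/50,
  to the 6-month clinic arm or the 3-month community arm.

## The microsimulation engine

The engine is an individual-level Monte Carlo over monthly cycles to a
100-year horizon, written in C++ (Rcpp). Costs and DALYs are half-cycle
corrected by evaluating each cycle's accrual at its midpoint,
$(t - 0.5)/12$ years, and discounted at 5%/yr. DALYs are years lived
weighted by the CD4- and treatment-specific disability weights (YLD) plus
one full weight for every cycle not lived before the horizon (YLL). A death
in cycle $t$ credits survival of $(t-0.5)/12$ years and starts YLL in the
same cycle, so a dying person contributes half a month to both — a
deliberate, tested convention. The published table's "DALYs averted" has an
unstated baseline, so absolute DALY levels are not a comparison surface;
internally, effects are expressed relative to the highest-burden arm, which
leaves every incremental quantity unchanged.

Randomness comes from R's RNG seeded once per cohort; the engine consumes
the stream person by person, making results bit-reproducible given
`(seed, n, params, strategy)`. Both perspectives' costs accrue in the same
run, so health outcomes are identical across perspectives by construction.

## Costs

**Health sector** (per on-ART month): the ARV price for the person's
regimen (dolutegravir \$5.55, efavirenz \$6.40, second-line \$23.15), plus
a service component — the \$134/yr 1-month-clinic facility cost divided by
12 and scaled by visit frequency for 3- and 6-month intervals, or the flat
\$160/yr community distribution cost — plus \$26/yr viral-load testing,
plus \$37.97/month case management in the tracing arm. Nothing accrues off
ART or after death. The visit-frequency scaling of the facility cost is an
inference (the published cost workbook is not available); it is
cross-checked against the published per-person-year ordering
(6-month < 3-month < 1-month).

**Patient** (per visit): a travel-mode mixture. With probability 0.575 the
patient rides a minibus taxi: fare \$0.28/h times the expected round-trip
transit time (1.63 h — the expectation over the reported <60 / 60–240 /
>240 minute bands using midpoints 0.5 and 2.5 h, and 5 h for the open
band), plus travel and 1 h waiting time valued at an hourly wage proxy.
Otherwise the patient walks 6 h round trip, with only time valued. The time
value is adjusted net national income per capita over 2,000 working hours
(\$393/2000 ≈ \$0.20/h). Community visits scale travel time and fare by the
brigade distance fraction (0.33); waiting is unchanged. Monthly patient
cost is expected visits per month (1, 1/3 or 1/6, with the forced monthly
phase above) times the per-visit cost.

This patient cost model is a *reconstruction*: the original per-visit
workbook is unavailable. Its calibration target is the published
*orderings* and approximate magnitudes of annual patient costs — which it
meets (annual cost ranking 1-month ≫ 3-month > case-management >
6-month > mixed > community) — not the exact dollars.

## Uncertainty

Every parameter with a published sensitivity range carries a PERT
(min, mode, max) specification, converted to a beta distribution with the
classic λ = 4 parameterization:
$\alpha = 1 + 4(m - a)/(b - a)$, $\beta = 1 + 4(b - m)/(b - a)$ on support
$[a, b]$, so the mean is $(a + 4m + b)/6$. Base-case values are the modes.
The PSA draws whole parameter sets (point parameters fixed), simulates
every strategy on each draw with common random numbers — the same cohort
seed within a draw — and summarizes decisions as cost-effectiveness
acceptability curves (CEACs): at each willingness-to-pay value λ the
strategy maximizing net monetary benefit λ·effect − cost gets the draw's
vote. NMB ties break toward the cheaper strategy.

## Frontier, affordability and congruence

`build_icer_table()` sorts by cost, removes strict dominance (costlier, no
more effective), iteratively removes extended dominance (a step ICER that
meets or exceeds the next step's), and reports ICERs along the frontier;
dominated rows still show increments against the previous non-dominated
strategy, matching the published league-table convention.
`optimal_at_wtp()` picks the frontier strategy with the largest ICER not
exceeding λ, which equals NMB maximization (at λ exactly equal to an ICER
the two strategies tie in NMB; the table rule keeps the more effective one,
the CEAC vote the cheaper — both conventions are stated and tested where
they are used).

Affordability converts the discounted lifetime patient cost $C_T$ into an
equivalent annual cost over the average years on treatment $Y_T$:
$C_A = C_T \big/ \frac{1 - (1+d)^{-Y_T}}{d}$. The published equation prints
a positive exponent, which would make the annuity factor negative; the
standard negative exponent reproduces the published annual costs (e.g.
$26.82 / 13.33 = 2.01$), so that is what is implemented. $Y_T$ is the
undiscounted mean years on ART, which is what the printed values are
consistent with. A strategy is affordable when $C_A$ is at or below the
threshold — by default the average annual out-of-pocket health expenditure
(\$4.14).

The five-pattern classifier compares the perspectives: with the
health-sector optimum affordable for patients, the pattern is *perfectly
congruent* (same optimum), *weakly congruent* (on the patient frontier but
not optimal) or *incongruent* (off the frontier); unaffordable, it is
*consistent* (on the frontier, possibly the shared optimum) or
*inconsistent* (off it). A shared optimum is by construction on the
frontier, so six of the 2×2×2 cells are reachable; all six are tested
exhaustively. One λ is shared by both perspectives by default
(0.3 × GDP per capita ≈ \$140 per DALY averted); a payer-specific
`patient_lambda` can be passed when thresholds plausibly differ.

## What the tests do and do not establish

Deterministic analytics (ICER ladder, annualization, affordability,
classification) are tested *exactly* against the published league table,
which ships with the package as data. The published health-sector annual
costs are printed to whole dollars from rounded inputs and reconstruct only
to within about \$1; the patient column reconstructs to within \$0.04.

The simulation is tested by properties, not by reproducing published
dollars: engine ≡ closed-form annuity under degenerate parameters (1e-9);
probability conversions invert exactly; the frontier algorithm agrees with
a brute-force NMB oracle on 1000 random instances; and a desk-scale run
(n = 10,000, five seeds averaged) reproduces the published qualitative
results — survival ordering, annual patient cost ordering, 1-month refills
dominated under both perspectives, and (at the default seed) the weakly
congruent verdict with 6-month clinic refills as the health-sector optimum.
CEAC modal switch points are checked against the model's *own* deterministic
frontier ICERs within a factor-of-two Monte Carlo band: with 100 draws and
1,000 persons per draw, the razor-thin steps of the published table (\$2.71
vs \$2.89) are not separately resolvable, and the case-management step's
incremental effect is comparable to its noise, so only the low-λ switch is
asserted.

Synthetic fixtures (`make_fixture()`) randomize all parameters within
admissible bounds for property tests; they emulate the *structure* of the
case study (simplex distributions, ordered LTFU odds ratios, valid PERT
supports), not its epidemiology — a green fixture test establishes internal
consistency, not realism.

## Numerical choices

* Tolerances: probability-sum and CEAC-share invariants at 1e-9; PERT mean
  identity at 1e-12; closed-form engine equivalences at 1e-9.
* Ties: cost sort ties break by effect descending; equal-cost, equal-effect
  duplicates keep the first row; NMB ties in CEAC votes go to the cheaper
  strategy.
* Degenerate inputs rejected with named errors: PERT with min = max, risks
  of exactly 1 (infinite hazard), odds ratios at 0, nonpositive
  affordability thresholds, empty willingness-to-pay grids.
* The >80 starting-age mass is folded into the 75–80 band (entry ages are
  15–80); the printed age column sums to 100.01% and is renormalized at
  load. Ages are recorded per person but drive no dynamics (no
  age-specific mortality), so they only document the cohort.
* Desk-scale defaults: the full-scale configuration (200,000 persons, 1000
  draws) is packaged; `run_full_analysis(..., scale = 0.05)` runs 10,000
  persons and 50 draws in well under a minute. PSA cohorts default to
  2,000 persons per draw.

## Known limitations

The cohort is closed: no HIV transmission, so population-level benefits of
better retention are understated. No background mortality, so absolute
survival is optimistic. The patient cost model is a documented
reconstruction; absolute patient dollars carry that uncertainty. Case
management is modelled only as an add-on to 3-month clinic refills, costing
\$37.97/month for everyone on ART in that arm — the published \$486/yr
suggests the original applied it more narrowly, which is part of why that
arm's absolute health-sector cost runs high here. Stigma and adverse-event
costs are out of scope.
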