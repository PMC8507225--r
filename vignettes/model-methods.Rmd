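---
title: "Model structure, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asthmaCE)
```

asthmaCE implements a weekly-cycle Markov cohort cost-utility model
comparing two treatment strategies for mild asthma from a Canadian
public-payer perspective (2019 CAD): as-needed budesonide-formoterol
(anti-inflammatory reliever) versus low-dose maintenance inhaled
corticosteroid (ICS) plus as-needed short-acting beta2-agonist (SABA). This
vignette is the package's own account of the model: the health states and
transitions, every tunable input with its units and default, the numerical
choices made where the published description of the source analysis was
silent or ambiguous, and the known limits of what the bundled synthetic
inputs can demonstrate.

## Health states and transitions

The cohort starts, in full, in a **non-exacerbation** state at age 41. Each
weekly cycle a patient can:

* suffer a **severe exacerbation**, entering one of three transient
  sub-states by management type — systemic corticosteroids only (SCS),
  emergency-department visit plus SCS (ED+SCS), or inpatient
  hospitalization — with a time-constant split across types;
* die (**death** is absorbing); or
* remain in the non-exacerbation state.

Exacerbation states last exactly one cycle: the only exits are death or
return to non-exacerbation, and exacerbation-to-exacerbation persistence is
not modelled. Two optional structural variants add states used only in
sensitivity analyses: a transient **moderate exacerbation** state, and an
absorbing (except for death) **treatment withdrawal** state in which
patients stop their randomized therapy and accrue a step-up drug cost
instead.

Severe exacerbations are modelled as three typed sub-states rather than one
state with expected-value costs. The two formulations are equivalent in
expectation for costs and QALYs; the typed form is clearer once
asthma-related mortality differs by exacerbation type.

### Rate and probability conversions

Annual severe exacerbation rates \(r\) (events/person-year; 0.11 for the
reliever arm, 0.12 for the maintenance arm) become weekly transition
probabilities with the exponential formula
\[p = 1 - e^{-r/52}.\]
Annual *probabilities* — background mortality, asthma-related death risks,
withdrawal risks — are instead compounded:
\[p_{\mathrm{week}} = 1 - (1-p_{\mathrm{year}})^{1/52},\]
so that surviving 52 weekly cycles reproduces the annual probability
exactly. The source description states the exponential formula only for
rates; compounding is this package's choice for probabilities because it
preserves probability semantics at every cycle length.

### Mortality

Transitions to death combine two components. Background mortality comes
from an age- and sex-specific life table: the annual probability at
`floor(age)` for each sex is converted to a weekly probability and the two
are averaged with the cohort's sex mix (default 0.5; the source trials
report no sex split, and a mixed-cohort weighted average differs from two
parallel cohorts only at second order). Asthma-related mortality applies
*only* in the severe-exacerbation states, as an additive weekly-converted
annual risk per exacerbation type, clamped so no probability exceeds 1.
Near the terminal age of the life table, where the annual probability
reaches 1, death takes priority and the remaining exit probabilities are
scaled into the mass it leaves — a corner case that matters only for cohorts
started in late middle age or older.

The per-type annual asthma-death risks are not publicly available from the
source analysis; the bundled values are study-assumption placeholders,
ordered as clinical severity dictates (inpatient 5% ≫ ED+SCS 2% ≫ SCS-only
0.5%, all small against background mortality at the cohort's ages). Every
headline number produced with the bundled inputs is conditional on these
placeholders, which move incremental QALYs far more than incremental costs.

## Accrual

Per cycle \(t\), with cost discount \(v_t = 1.015^{-t/52}\) and the same
factor for outcomes (both rates default to 1.5%/year and are configurable):

* **Drug costs**: on-treatment occupancy × daily drug cost × 7 days. Daily
  drug cost is `price / doses per inhaler x doses per day x utilization`,
  kept *unrounded* internally (0.39156 for the reliever; 0.716667 + 0.01225
  for maintenance ICS plus SABA); rounding to cents happens only in display
  tables. A cycle is exactly 7.0 days (52 cycles/year), matching the weekly
  cycle definition literally rather than 365.25/52.
* **Routine (non-exacerbation) care**: the $38.40 routine cost is accrued
  by *all alive* patients — exacerbating patients still incur their routine
  monitoring. Its basis is configurable: the default reads it as an annual
  amount ($38.40/52 per cycle), because over ≈29.9 discounted life-years an
  annual reading reproduces the published non-exacerbation category
  (~$1,146) whereas a literal weekly reading would be 52-fold larger. The
  `per_week` reading remains selectable via
  `economic_inputs(nonexac_cost_basis = "per_week")`.
* **Severe exacerbation costs**: occupancy of each typed sub-state × its
  direct event cost ($155.14 / $490.81 / $9,399.94).
* **Adverse events (AEs)**: the seven most common treatment-period AEs are
  charged on non-exacerbation occupancy only (both their costs and any
  disutility), to avoid double counting with exacerbation inputs. Each
  annual proportion is treated as an annual event *rate* and converted with
  the exponential formula; this conservative reading does not inflate
  expected events above the annual proportion, which compounding would.
  AE disutilities default to 0 (none are published; the published QALY
  decomposition shows 0.000 for AEs).
* **QALYs**: state occupancy × (utility + state disutility) / 52. The
  non-exacerbation utility is 0.867; exacerbation disutilities −0.10 /
  −0.15 / −0.20 apply for the single exacerbation cycle; the moderate
  variant uses −0.05 (half the SCS-only decrement) by default.
* **Societal perspective** (scenario analysis only) adds productivity
  losses: 0.19 work-days lost per patient-year × a daily wage, for all
  alive patients in both arms. No wage is published; the default $166.90
  was back-solved so that 0.19 days/year reproduces the published ≈$948
  per-arm lifetime productivity cost, and is flagged as calibrated and
  overridable.

No half-cycle correction is applied by default (the source description is
silent); `run_config(half_cycle_correction = TRUE)` enables averaging of
start- and end-of-cycle occupancy. Death accrues nothing; death-related
costs are excluded.

## The synthetic life table

No national life table ships with the package (users can supply one as
`age,sex,qx` CSV). The bundled stand-in is generated from a
Gompertz–Makeham law,
\[h(x) = \lambda + a\,e^{bx},\qquad q_x = 1 - e^{-h(x)},\]
with a male/female hazard ratio of 1.5, Makeham term \(\lambda = 4\times
10^{-4}\), slope \(b = 0.0955\), and \(a\) calibrated (deterministic
bisection) so that discounted life expectancy from age 41 at 1.5%/year over
the 50-year horizon is 29.9 years — the value implied by the published
drug-cost categories divided by the unrounded daily drug costs. The
calibration tolerance is 0.5%; `calibrate_life_table()` re-derives \(a\)
for any other target. The shape is realistic for a high-income population
(life expectancy at birth ≈ 82 undiscounted), but it is *not* a fitted
national table: age-specific detail (infant mortality, accident hump) is
absent, so results with the bundled table demonstrate correctness of the
machinery and approximate — not exact — reproduction of published totals.

## Probabilistic sensitivity analysis

`run_psa()` draws each uncertain parameter from its published distribution:
beta for exacerbation rates, AE proportions and the non-exacerbation
utility; negated beta for disutilities; gamma for inhalations/day and
starting age; Dirichlet for the exacerbation-type shares. Where no
distribution parameters are published, `moments_to_spec()` builds a gamma
(or beta) spec from the point estimate with a 10% coefficient of variation
— this convention reproduces the published gamma shapes of 100 exactly, so
it is the default reading of the "10% variance-to-mean" rule; the literal
variance/mean reading is available behind an option. Published shape
parameters take precedence over re-derivation wherever both exist.

Further sampling choices:

* Drug acquisition prices are never sampled (treated as known and fixed).
* AE *unit costs* are sampled once per iteration and shared across arms:
  they are common provincial unit costs, not arm-specific observations.
* Dirichlet concentrations for the share vectors default to shares × 100
  (none are published), configurable per spec.
* Each PSA iteration runs on its own seed derived from the master seed, so
  extending the spec list does not reshuffle other iterations, and the same
  seed reproduces results bit-identically.

Two published distribution inconsistencies are used verbatim and documented
rather than repaired: the reliever arm's viral-URTI beta (95.53, 1157.83)
has analytic mean 0.0762 against a printed point estimate of 7.4%, and the
disutility betas (e.g. 110.1, 1211.1 for −0.10) have analytic means around
−0.083 / −0.115 / −0.143, noticeably smaller in magnitude than the point
estimates. Both pull the PSA mean incremental cost slightly toward zero
relative to the deterministic base case.

The CEAC counts draws with strictly positive net monetary benefit
(\(\lambda \Delta Q - \Delta C > 0\)); an NMB of exactly zero counts as not
cost-effective — a deterministic, conservative tie rule. The default
willingness-to-pay grid runs $0–$200,000 in $1,000 steps and always
contains the $50,000 and $100,000 thresholds.

## One-way DSA and scenarios

`run_one_way_dsa()` re-runs the deterministic model at each parameter's
published lower/upper bound, all else at base, and ranks parameters by the
absolute swing in incremental cost (with the NMB swing at a reference
threshold reported alongside). Paths beginning `config.` vary the run
configuration; `config.discount_rate` moves both discount rates together.

`build_scenario()` encodes the eight published scenario analyses as
declarative overrides (discount 0%/3%, horizons 2y/10y, societal
perspective, budesonide as the maintenance ICS, 62.8% ICS utilization, AE
removal). Scenario 7 scales only the *acquisition cost* of the maintenance
ICS — efficacy is untouched. Scenario 6 requires a budesonide inhaler
price, which is not published: the default ($113.40 per 200-dose inhaler)
is a placeholder of realistic magnitude, so numeric reproduction of that
scenario is qualitative (dominance direction), not exact. Scenario tables
default to the published presentation (PSA means over 1,000 iterations per
scenario, scenario *i* seeded at `seed + i`); a deterministic mode gives
point estimates.

## What the bundled inputs can and cannot show

With the built-in parameter tables and the calibrated synthetic life table,
the deterministic base case reproduces the published non-exacerbation,
severe-exacerbation and drug-cost categories to well within 1%, per-arm
QALYs to <0.1%, and an incremental QALY that prints as 0.002; the
intervention is dominant in the base case and in all eight scenarios, as
published. Two published quantities are *not* recovered, and the package
makes no attempt to force them:

* the published adverse-event cost decomposition (≈$28.0k / $34.4k,
  incremental −$6.4k) is not derivable from the published AE proportions ×
  unit costs × discounted life-years, which give ≈$30.0k / $33.3k
  (incremental ≈ −$3.3k). Per-arm AE totals therefore agree only to
  ~7% / ~3%, and every quantity downstream of the AE *incremental* — the
  headline incremental cost, the undiscounted and short-horizon scenario
  savings — is smaller in magnitude here than published;
* the published CEAC heights (94%/95%) imply a wider spread of incremental
  costs relative to their mean than the published distributions generate
  around ours (we obtain ≈97%).

Problem sizes used throughout the test suite and the reproduction script
are the model's natural ones: 2,600 weekly cycles for 50-year runs, 1,000
PSA iterations, 10,000 draws for distribution-mean checks; shorter horizons
(2–10 years) are used where a property does not depend on the full horizon.

## Known limitations

* Cohort (not individual) simulation: no time-in-state or event-history
  dependence, no treatment-effect waning, in line with the source design.
* The synthetic life table and placeholder asthma-death risks stand in for
  national and registry mortality data; users reproducing a jurisdictional
  analysis should supply both (`read_life_table()`, and the
  `annual_asthma_death_risk` fields).
* Moderate exacerbations and treatment withdrawal are sensitivity-only
  structures, as in the source analysis; their cost inputs (moderate event
  cost, step-up drug cost) are documented assumptions.
* Only two strategies are compared; there is no efficiency frontier or
  EVPI machinery.
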