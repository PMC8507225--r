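# asthmaCE

A Markov cohort cost-utility model for mild asthma reliever strategies:
as-needed budesonide-formoterol (anti-inflammatory reliever) versus
low-dose maintenance inhaled corticosteroid (ICS) plus as-needed
short-acting beta2-agonist (SABA), from a Canadian public-payer
perspective in 2019 CAD.

Mild asthma is common, and adherence to daily maintenance ICS is typically
poor, leaving many patients effectively on SABA monotherapy with its excess
exacerbation risk. Symptom-driven low-dose ICS-formoterol removes the
adherence burden; the economic question is whether it also saves money and
quality-adjusted life years (QALYs) relative to guideline maintenance
therapy. This package implements that comparison as a tested, reusable
model for health-economics practitioners: the deterministic base case,
probabilistic sensitivity analysis (PSA) with cost-effectiveness
acceptability curves (CEAC), one-way deterministic (tornado) sensitivity
analysis, eight scenario analyses, and structural variants (treatment
withdrawal, moderate exacerbations).

## The model

A discrete-time cohort model with weekly cycles over a 50-year horizon,
discounted at 1.5%/year for costs and outcomes. States: non-exacerbation;
three transient severe-exacerbation sub-states (systemic corticosteroids
only, ED visit + SCS, inpatient); absorbing death. Annual severe
exacerbation rates *r* (0.11 vs 0.12 events/person-year) convert to weekly
transition probabilities as *p* = 1 − exp(−*r*/52); annual mortality and
withdrawal probabilities compound as *p*₅₂ = 1 − (1 − *p*)^(1/52).
Asthma-related death occurs only from the exacerbation states, additively
to age- and sex-specific background mortality. Per-cycle accruals (drugs,
routine care, exacerbation events, adverse events, QALYs) are discounted
and summed per category; strategies are compared by incremental cost ΔC,
incremental QALYs ΔQ, the ICER ΔC/ΔQ where defined, dominance otherwise,
and net monetary benefit λΔQ − ΔC across willingness-to-pay values λ.

Because neither a national life table nor the registry asthma-mortality
risks are redistributable, the package generates a calibrated
Gompertz–Makeham life table (discounted life expectancy from age 41 at
1.5%/yr ≈ 29.9 years) and documents placeholder asthma-death risks; both
are replaceable through plain-text interfaces. See
`vignettes/model-methods.Rmd` for every assumption and numerical choice.

## Worked example

```r
library(asthmaCE)

params <- default_parameter_set()   # built-in input tables
lt     <- generate_life_table()     # calibrated synthetic life table
res    <- run_base_case(params, run_config(), lt)
print(res)
```

```
<ce_result>
  intervention: As-needed budesonide-formoterol
  comparator:   Low-dose maintenance ICS + as-needed SABA
       category cost_intervention cost_comparator incremental_cost
        nonexac           1147.69         1147.64             0.05
    severe_exac           3014.94         2852.20           162.74
          drugs           4259.83         7929.65         -3669.82
 adverse_events          30006.64        33292.43         -3285.80
          total          38429.09        45221.93         -6792.84
 qaly_intervention qaly_comparator incremental_qaly
            25.858          25.852            0.006
             0.048           0.052           -0.004
...
            25.905          25.904            0.002
  verdict: dominant (As-needed budesonide-formoterol)
```

Reading the output: the reliever strategy costs less in every
difference-driving category (drug acquisition, adverse events) while
gaining 0.002 QALYs per patient over 50 years, so it *dominates* the
maintenance strategy — no ICER is reported for a dominant strategy. The
uncertainty analyses follow the same pattern:

```r
psa <- run_psa(params, run_config(), lt, n = 1000, seed = 1)
ceac_at(psa$ceac, 50000)    # probability cost-effective at $50,000/QALY
#> [1] 0.966
tor  <- run_one_way_dsa(params, run_config(), lt)      # tornado table
scen <- run_scenarios(1:8, params, run_config(), lt,
                      mode = "deterministic")           # eight scenarios
```

A thin command-line wrapper over the same functions ships in
`inst/cli/asthmace.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","asthmace.R",package="asthmaCE"))')" \
  base-case --out-dir results/
```

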