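# vfscreen

A deterministic Markov cohort model comparing population screening
strategies for prevalent vertebral fractures (VF) against no screening, with
an individual-level microsimulation as a Monte-Carlo cross-check.

Vertebral fractures are the most common osteoporotic fracture and are
frequently asymptomatic, so an existing ("prevalent") fracture — the
strongest predictor of further fractures — often goes undiagnosed.
Screening can find these patients and start anti-osteoporotic therapy,
which lowers the risk of a *new* fracture. The model weighs three ways of
screening adults aged 50 and older every two years over a 10-year horizon:

* **radiography after VFA** — low-dose vertebral fracture assessment (VFA)
  on a densitometer, positives confirmed by spine radiography;
* **VFA only** — treat on the VFA result alone (cheapest test, imperfect
  accuracy, occasional unreadable images);
* **radiography only** — gold-standard accuracy at 24× the radiation dose.

Each strategy is scored on three per-capita outcomes against no screening:
cumulative new-VF incidence (%), discounted cost (€, 5%/year with
half-cycle correction), and cumulative radiation exposure (μSv). The
package ships every input (sex-specific prevalence, incidences, treatment
relative risk, test accuracy, costs, doses) as versioned YAML
configurations, so all analyses run with zero external data.

## Worked example

```r
library(vfscreen)

women <- load_parameter_set(NULL, "female", "base_case")
men   <- load_parameter_set(NULL, "male",   "base_case")

res <- run_base_case(women, men)
print(res)
#> <vf_results> scenario base_case
#>       sex       strategy effectiveness_pct delta_e cost_eur delta_c delta_re
#> 1  female   no_screening              30.1              359                0
#> 2  female   do_screening              22.1    -8.1      579     221     1496
#> 3  female xray_after_vfa              23.0    -7.1      562     203     1095
#> 4  female       vfa_only              23.0    -7.1      566     207      125
#> 5  female      xray_only              20.1   -10.0      610     251     3268
#> 6    male   no_screening              15.3              203                0
#> 7    male   do_screening               8.8    -6.5      348     145     1463
#> 8    male xray_after_vfa               9.6    -5.7      328     125      770
#> 9    male       vfa_only               9.6    -5.7      355     153      134
#> 10   male      xray_only               7.1    -8.1      360     158     3486
#> 11  total   do_screening                      -7.3              185     1481
```

A single strategy run exposes the full cycle-by-cycle trace:

```r
xv <- run_cohort("xray_after_vfa", women)
print(xv)
#> <vf_cohort_trace> xray_after_vfa | female/base_case
#>   new-VF incidence 23.0% | cost EUR 562 | dose 1095 uSv | 5.02 screens per capita
incremental(xv, run_cohort("no_screening", women))$delta_cost
#> [1] 203.305
```

The microsimulation validates the deterministic engine within Monte-Carlo
error:

```r
validate_against_cohort("vfa_only", women, n = 20000, seed = 1)$pass
#> [1] TRUE
```

## Analysis workflow

Numbered drivers under `analysis/` write tables and manifests to
`results/`:

| script | output |
| --- | --- |
| `01_base_case.R` | base-case results table, both sexes |
| `02_univariate_sensitivity.R` | one-way sensitivity tables and strategy rank orders |
| `03_scenarios.R` | one-year-cycle and old-age-subgroup results |
| `04_replication_search.R` | convention search scores, winning configuration, residuals |
| `05_microsim_validation.R` | microsimulation-versus-cohort validation table |

Each output CSV is paired with a YAML manifest recording the package
version, scenario, convention switches, and seed, so any run is
reproducible from its manifest alone.

## Package layout

* `R/` — parameters and configs, screening cascade, cohort engine,
  outcomes/replication, microsimulation, reporting.
* `inst/extdata/config/` — shipped scenario inputs (YAML).
* `analysis/`, `scripts/`, `results/` — drivers, acceptance script, outputs.
* `tests/testthat/` — unit, property, and acceptance tests.
* `vignettes/model-methods.Rmd` — model structure, conventions, validation.
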