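---
title: "Model structure, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfscreen)
```

## The model

`vfscreen` implements a deterministic Markov cohort model of population
screening for prevalent vertebral fractures (VF) in adults aged 50 and
older. Four strategies are compared over a 10-year horizon with two-year
cycles:

* **no screening** — fractures surface only as clinical events;
* **radiography after VFA** — vertebral fracture assessment (VFA) on a
  densitometer, positives confirmed by spine radiography;
* **VFA only** — treatment decided on the VFA result alone;
* **radiography only** — every screen is a (gold-standard) radiograph.

The health states are *No VF*, *Prevalent VF* (undiagnosed existing
fracture), *Post VF* (diagnosed and treated, no new fracture yet), *New VF*
(the outcome event), and *VFA impossible* (the unreadable-image stratum, in
which screening stops but disease progression continues). Patients whose
screen is positive receive one year of anti-osteoporotic therapy, which
multiplies the per-cycle new-fracture probability by the relative risk
`rr_treatment`. The engine tracks these states crossed with treatment
strata in a 12-compartment occupancy vector (`vf_compartments()`); mass is
conserved exactly at every cycle and this is asserted at run time.

Three outcomes accrue per capita: cumulative new-VF incidence (%),
discounted cost (euros; 5% per year with a half-cycle correction; only
costs are discounted), and cumulative radiation dose (microsievert).
Incremental outcomes are differences against the no-screening run, and the
"Do screening" summary is the unweighted mean of the three screening
strategies, with a combined total weighted by the registration populations
(`vf_population_weights()`).

## Parameters

All inputs ship as YAML configuration files (`vf_config_path()`): the base
case, a one-year-cycle variant, and an old-age subgroup (women 70+, men
80+), each with sex-specific blocks, so every analysis runs with zero
external inputs. `load_parameter_set()` validates every field: probabilities
in [0, 1], relative risk in (0, 1], non-negative costs and doses, and a
cycle length that divides the horizon. The base-case file also carries the
bracketed alternative values driving `run_univariate_sensitivity()`, one
field at a time via `univariate_variants()`.

Two derivation utilities are exposed for documentation rather than used in
the pipeline: `adjust_symptomatic_incidence()` (the 2.8
asymptomatic-to-symptomatic ratio that the shipped incidence values already
include) and `convert_cycle_probability()` (constant-hazard conversion
between cycle lengths; shipped cycle lengths use their tabulated values
directly).

```{r params}
women <- load_parameter_set(NULL, "female", "base_case")
women
```

## Modelling conventions and the replication search

Several structural choices of the published model this package re-implements
cannot be recovered uniquely from its description. Each is an explicit
switch in `vf_conventions()`:

* `schedule` — five transition cycles with six screening events
  (*fencepost*, the default), five events (*closed*), or six cycles
  (*extra_cycle*);
* `rr_timing` — therapy shields the whole cycle it starts in, or only a
  prorated first year;
* `counting` — cumulative incidence counts persons with at least one new
  fracture, or every fracture event;
* `untreated_exit` — whether an untreated new fracture removes the subject
  from the at-risk population;
* `unreadable_combined` — in the confirmation strategy, unreadable VFA
  images either enter the absorbing VFA-impossible stratum (default,
  matching the VFA-only strategy and keeping the two strategies clinically
  identical) or are resolved by an immediate radiograph;
* `vf_cost` — fracture costs charged per event, per event plus the
  symptomatic-fraction procedure cost, or at first positive classification
  (*diagnosis*; the only rule that reproduces the published incremental
  costs, including a most-expensive VFA-only strategy driven by false
  positives);
* `reconfirm_known` — whether previously diagnosed subjects are re-confirmed
  radiographically on later screens;
* `confirm_dose` — confirmatory radiograph dose conditional on referral or
  charged per protocol to every screened subject.

`replication_search()` runs the full base case under all 288 combinations
(`convention_grid()`), scores each against the published per-strategy
outcomes, and returns the best configuration with a residual table. The
score is frozen and documented: per printed cell, the absolute discrepancy
divided by 1 percentage point (effectiveness), 25 euros (incremental cost),
or `max(5%` of the printed value`, 25)` microsievert (incremental dose),
summed; ties break by fixed grid order, so the search is deterministic.

No configuration reproduces every published headline simultaneously. The
women's screening-arm effectiveness is matched to the printed digit under
event counting with untreated subjects staying at risk, and the published
cost ordering and near-exact incremental costs emerge under the *diagnosis*
cost rule — but the published women's no-screening incidence (54.6%) and
the old-age subgroup reductions (41.0 / 32.8 points) lie outside the span
of the entire convention space. The residuals are reported, not hidden:

```{r replication, eval = FALSE}
men <- load_parameter_set(NULL, "male", "base_case")
rep <- replication_search(women, men)
rep$residuals
```

(The search takes about half a minute; it is run by
`analysis/04_replication_search.R` and its outputs are written to
`results/`.)

## Microsimulation cross-check

`simulate_cohort()` is a stochastic twin of the cohort engine: `n`
independent patient trajectories drawn under the same parameters and
conventions, using a single seeded Mersenne-Twister stream with a fixed
vectorised draw order, producing a tidy per-event log (patient, time,
event, cost, dose, counted). `validate_against_cohort()` compares the
Monte-Carlo estimates of all three outcomes with the deterministic engine
and passes when each lies within three standard errors.

```{r microsim}
v <- validate_against_cohort("vfa_only", women, n = 20000, seed = 1)
v$table
```

What a passing check shows: the deterministic occupancy arithmetic —
screening cascade, transition flows, cost and dose accrual, discounting —
agrees with an independently coded per-patient implementation of the same
assumptions, under the default and non-default conventions exercised in the
test suite. What it cannot show: that those shared assumptions are the ones
behind the published numbers; the replication residuals above quantify that
separately.

## Problem sizes and runtime

The cohort engine runs one strategy in milliseconds; the full 288-point
replication search takes ~30 s; the 100,000-patient, 8-run validation suite
takes ~1 min on one CPU.

## Limitations

* Health-related quality of life, cost-utility, and adverse effects of
  false-positive treatment are out of scope, as in the source analysis.
* The published women's no-screening incidence and the subgroup reductions
  could not be reconciled with any convention combination; the pattern of
  residuals (and duplicated no-screening rows in the published multivariate
  table) suggests inconsistencies in the published tables themselves. The
  package reports its own internally consistent values alongside the
  published targets rather than adjusting inputs to force agreement.
* Costs are the published 2013 euro figures; no re-conversion or inflation
  adjustment is attempted.
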