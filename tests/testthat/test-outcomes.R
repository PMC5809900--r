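w <- load_parameter_set(NULL, "female", "base_case")
m <- load_parameter_set(NULL, "male", "base_case")

test_that("incremental outcomes are differences against no screening", {
  ns <- run_cohort("no_screening", w)
  vfa <- run_cohort("vfa_only", w)
  inc <- incremental(vfa, ns)
  expect_s3_class(inc, "vf_incremental")
  expect_equal(inc$delta_effect, vfa$effectiveness - ns$effectiveness)
  expect_equal(inc$delta_cost, vfa$total_cost - ns$total_cost)
  expect_equal(inc$delta_dose, vfa$total_dose)
  expect_lt(inc$delta_effect, 0)
  expect_gt(inc$delta_cost, 0)
  # the comparator must be the no-screening run of the same stratum
  expect_error(incremental(vfa, vfa), "no-screening")
  ns_m <- run_cohort("no_screening", m)
  expect_error(incremental(vfa, ns_m), "share sex and scenario")
})

test_that("the Do-screening average is the unweighted strategy mean", {
  expect_equal(do_screening_average(c(25.2, 25.2, 19.6)), 70 / 3)
  expect_error(do_screening_average(c(1, 2)), "three")
  ns <- run_cohort("no_screening", w)
  incs <- lapply(setdiff(vf_strategies(), "no_screening"), function(s) {
    incremental(run_cohort(s, w), ns)
  })
  avg <- do_screening_average(incs)
  expect_equal(avg$delta_effect,
               mean(vapply(incs, `[[`, numeric(1), "delta_effect")))
  expect_equal(avg$strategy, "do_screening")
  # duplicated strategies are refused
  expect_error(do_screening_average(incs[c(1, 1, 2)]),
               "each screening strategy once")
})

test_that("population weighting uses the registration populations", {
  wts <- vf_population_weights()
  expect_equal(unname(wts), c(8649974, 7590057))
  expect_equal(population_weighted_total(1, 1), 1)
  expect_equal(population_weighted_total(1, 0),
               8649974 / (8649974 + 7590057))
})

test_that("the scenario results table has the published layout", {
  res <- run_base_case(w, m)
  expect_s3_class(res, "vf_results")
  expect_equal(nrow(res), 11)  # 5 rows per sex + weighted total
  expect_equal(res$strategy[res$sex == "total"], "do_screening")
  blk <- res[res$sex == "female", ]
  expect_equal(blk$strategy[1:2], c("no_screening", "do_screening"))
  expect_true(is.na(blk$delta_e[1]))
  expect_equal(blk$delta_re[1], 0)
  # Do-screening row is the mean of the three strategy rows
  expect_equal(blk$effectiveness[2], mean(blk$effectiveness[3:5]))
  expect_equal(blk$delta_c[2], mean(blk$delta_c[3:5]))
  # deltas are levels minus the no-screening level
  expect_equal(blk$delta_e[3:5], blk$effectiveness[3:5] - blk$effectiveness[1])
  # total row is the population-weighted Do-screening average
  tot <- res[res$sex == "total", ]
  mblk <- res[res$sex == "male", ]
  expect_equal(tot$delta_e,
               population_weighted_total(blk$delta_e[2], mblk$delta_e[2]))
})

test_that("univariate sensitivity reruns one variant at a time", {
  sens <- run_univariate_sensitivity(w)
  expect_equal(nrow(sens$table), 11 * 4)
  expect_equal(nrow(sens$ranks), 12)  # base + 11 variants
  prev <- sens$table[sens$table$variant == "vf_prevalence", ]
  # lower prevalence lowers incidence and cost in every strategy
  expect_true(all(prev$delta_e_vs_base < 0))
  expect_true(all(prev$delta_cost_vs_base < 0))
  # dose-only variation leaves effectiveness untouched
  dose <- sens$table[sens$table$variant == "dose_vfa", ]
  expect_true(all(abs(dose$delta_e_vs_base) < 1e-12))
})

test_that("replication scoring is zero at its own results", {
  res <- run_base_case(w, m)
  df <- as.data.frame(res)
  self <- df[df$strategy %in% vf_strategies() & df$sex != "total", ]
  targets <- data.frame(sex = self$sex, strategy = self$strategy,
                        effectiveness = self$effectiveness,
                        delta_c = self$delta_c, delta_re = self$delta_re)
  sc <- vfscreen:::score_results(res, targets)
  expect_equal(sc$score, 0)
  expect_gt(nrow(sc$residuals), 0)
})

test_that("printed target tables are complete", {
  tb <- printed_base_case()
  expect_equal(nrow(tb), 8)
  expect_equal(tb$effectiveness[tb$sex == "female" &
                                tb$strategy == "no_screening"], 54.6)
  expect_equal(tb$delta_c[tb$sex == "male" &
                          tb$strategy == "xray_only"], 515)
  h <- printed_headlines()
  expect_named(h, c("do_screening_eff_female", "do_screening_eff_male",
                    "subgroup_reduction_female", "subgroup_reduction_male"))
})

test_that("rendered tables apply the reporting rounding only at the edge", {
  res <- run_base_case(w, m)
  disp <- render_results_table(res)
  expect_equal(nrow(disp), nrow(res))
  expect_true(all(grepl("^-?[0-9]+\\.[0-9]$|^$", disp$effectiveness_pct)))
  expect_true(all(grepl("^-?[0-9]+$|^$", disp$cost_eur)))
  # underlying object keeps full precision
  expect_false(all(res$effectiveness[!is.na(res$effectiveness)] ==
                   round(res$effectiveness[!is.na(res$effectiveness)], 1)))
})

test_that("results CSVs round-trip at full precision", {
  res <- run_base_case(w, m)
  tmp <- tempfile(fileext = ".csv")
  paths <- write_results_csv(res, tmp)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(tmp)
  expect_equal(back$effectiveness, res$effectiveness)
  expect_equal(back$delta_c, res$delta_c)
  unlink(paths)
})

test_that("run manifests record the full configuration", {
  tmp <- tempfile(fileext = ".yaml")
  write_run_manifest(tmp, "base_case", vf_conventions(),
                     outputs = "x.csv", seed = 7L)
  man <- yaml::read_yaml(tmp)
  expect_equal(man$scenario, "base_case")
  expect_equal(man$conventions$schedule, "fencepost")
  expect_equal(man$seed, 7L)
  expect_equal(man$outputs, "x.csv")
  expect_equal(man$tool, "vfscreen")
  unlink(tmp)
})
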