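test_that("shipped base-case inputs load with the published values", {
  w <- load_parameter_set(NULL, "female", "base_case")
  expect_s3_class(w, "vf_parameters")
  expect_equal(w$vf_prevalence, 0.22)
  expect_equal(w$vf_incidence, 0.12)
  expect_equal(w$new_vf_incidence, 0.22)
  expect_equal(w$rr_treatment, 0.58)
  expect_equal(w$vfa_sensitivity, 0.82)
  expect_equal(w$vfa_specificity, 0.93)
  expect_equal(w$p_vfa_unreadable, 0.03)
  expect_equal(w$xray_sensitivity, 1)
  expect_equal(w$cost_vfa, 17)
  expect_equal(w$cost_xray, 24)
  expect_equal(w$cost_vf_treatment, 1526)
  expect_equal(w$cost_physician_visit, 9)
  expect_equal(w$cost_drug_year, 180)
  expect_equal(w$cost_procedure, 809)
  expect_equal(w$dose_xray, 600)
  expect_equal(w$dose_vfa, 25)
  expect_equal(w$discount_rate, 0.05)
  expect_equal(w$cycle_length, 2)
  expect_equal(w$horizon, 10)
  expect_equal(w$asymptomatic_ratio, 2.8)
  expect_equal(w$population_weight, 8649974)

  m <- load_parameter_set(NULL, "male", "base_case")
  expect_equal(m$vf_prevalence, 0.11)
  expect_equal(m$vf_incidence, 0.05)
  expect_equal(m$rr_treatment, 0.38)
  expect_equal(m$cost_vf_treatment, 1707)
  expect_equal(m$cost_drug_year, 194)
  expect_equal(m$population_weight, 7590057)
})

test_that("shipped alternative scenarios load correctly", {
  c1 <- load_parameter_set(NULL, "female", "cycle_1y")
  expect_equal(c1$cycle_length, 1)
  expect_equal(c1$vf_incidence, 0.06)
  expect_equal(c1$new_vf_incidence, 0.11)
  expect_equal(c1$cost_vf_treatment, 1458)

  sw <- load_parameter_set(NULL, "female", "subgroup_old_age")
  expect_equal(sw$vf_prevalence, 0.43)
  expect_equal(sw$vf_incidence, 0.29)
  expect_equal(sw$new_vf_incidence, 0.32)
  expect_equal(sw$rr_treatment, 0.60)
  expect_equal(sw$vfa_sensitivity, 0.88)
  expect_equal(sw$vfa_specificity, 0.99)
  expect_equal(sw$cost_vf_treatment, 1513)

  sm <- load_parameter_set(NULL, "male", "subgroup_old_age")
  expect_equal(sm$vf_prevalence, 0.46)
  expect_equal(sm$vf_incidence, 0.17)
  expect_equal(sm$cost_vf_treatment, 1675)
})

test_that("configuration errors name the missing piece", {
  expect_error(vf_config_path("bogus"), "should be one of")
  expect_error(load_parameter_set(NULL, "female", "bogus"), "should be one of")
  expect_error(
    load_parameter_set(list(scenario = "other"), "female", "base_case"),
    "base_case"
  )
  expect_error(
    load_parameter_set(list(scenario = "base_case", women = list()),
                       "male", "base_case"),
    "men"
  )
  expect_error(load_parameter_set(42, "female", "base_case"),
               "file path or a configuration list")
  expect_error(load_parameter_set("/nonexistent/x.yaml", "female", "base_case"),
               "does not exist")
})

test_that("parameter invariants are enforced and violations name the field", {
  w <- load_parameter_set(NULL, "female", "base_case")
  bad <- function(field, value) {
    p <- unclass(w)
    p[[field]] <- value
    class(p) <- "vf_parameters"
    validate_parameters(p)
  }
  expect_error(bad("vf_prevalence", 1.2), "vf_prevalence")
  expect_error(bad("vfa_sensitivity", -0.1), "vfa_sensitivity")
  expect_error(bad("rr_treatment", 0), "rr_treatment")
  expect_error(bad("rr_treatment", 1.5), "rr_treatment")
  expect_error(bad("cost_vfa", -1), "cost_vfa")
  expect_error(bad("dose_xray", NA_real_), "dose_xray")
  expect_error(bad("cycle_length", 3), "cycle_length")
})

test_that("symptomatic-incidence adjustment applies the 2.8 ratio", {
  expect_equal(adjust_symptomatic_incidence(0.05), 0.14)
  expect_equal(adjust_symptomatic_incidence(0.1, ratio = 2), 0.2)
  expect_error(adjust_symptomatic_incidence(0.5), "exceeds 1")
  expect_error(adjust_symptomatic_incidence(-0.1), "non-negative")
  expect_error(adjust_symptomatic_incidence(0.1, ratio = 0), "positive")
})

test_that("cycle-length probability conversion is a constant-hazard map", {
  expect_equal(convert_cycle_probability(0.12, 2, 1), 1 - sqrt(0.88))
  # identity and round trip
  expect_equal(convert_cycle_probability(0.37, 2, 2), 0.37)
  p1 <- convert_cycle_probability(0.22, 2, 1)
  expect_equal(convert_cycle_probability(p1, 1, 2), 0.22, tolerance = 1e-12)
  # monotone in duration, bounded
  ps <- convert_cycle_probability(0.3, 1, c(0.5, 1, 2, 4, 8))
  expect_true(all(diff(ps) > 0))
  expect_true(all(ps > 0 & ps < 1))
  # edge cases and errors
  expect_equal(convert_cycle_probability(0, 2, 1), 0)
  expect_equal(convert_cycle_probability(1, 2, 1), 1)
  expect_error(convert_cycle_probability(0.5, 0, 1), "positive")
  expect_error(convert_cycle_probability(1.5, 2, 1), "\\[0, 1\\]")
})

test_that("univariate variants differ from the base in exactly one field", {
  w <- load_parameter_set(NULL, "female", "base_case")
  w_copy <- w
  vars <- univariate_variants(w)
  expect_length(vars, 11)
  expect_equal(vars$vf_prevalence$vf_prevalence, 0.08)
  expect_equal(vars$vfa_sensitivity$vfa_sensitivity, 0.74)
  expect_equal(vars$cost_vfa$cost_vfa, 40)
  expect_equal(vars$dose_vfa$dose_vfa, 2)
  # base object untouched
  expect_identical(w, w_copy)
  compare_fields <- setdiff(names(unclass(w)), c("scenario", "univariate"))
  for (f in names(vars)) {
    v <- vars[[f]]
    expect_equal(v$scenario, paste0("base_case_", f))
    differing <- compare_fields[vapply(compare_fields, function(g) {
      !identical(v[[g]], w[[g]])
    }, logical(1))]
    expect_identical(differing, f)
  }
})

test_that("variants are refused when no univariate block is shipped", {
  s <- load_parameter_set(NULL, "female", "subgroup_old_age")
  expect_error(univariate_variants(s), "no univariate alternatives")
})

test_that("a configuration list round-trips through YAML unchanged", {
  path <- vf_config_path("base_case")
  from_file <- load_parameter_set(path, "male", "base_case")
  from_list <- load_parameter_set(yaml::read_yaml(path), "male", "base_case")
  expect_identical(from_file, from_list)
})
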