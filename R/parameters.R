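#' Parameter sets for the vertebral-fracture screening model
#'
#' A `vf_parameters` object bundles every epidemiological, diagnostic, cost,
#' radiation-dose and run-control input the cohort model needs for one sex and
#' one scenario. The package ships the published input tables as YAML files
#' (see [vf_config_path()]): the base case for adults aged 50+, the one-year
#' cycle-length variant, and the old-age subgroup (women 70+, men 80+).
#'
#' @param sex `"female"` or `"male"`.
#' @param scenario Scenario label, e.g. `"base_case"`.
#' @param vf_prevalence Initial fraction of the cohort with a prevalent
#'   vertebral fracture (VF).
#' @param vf_incidence Per-cycle probability of a first VF (No VF to
#'   Prevalent VF).
#' @param new_vf_incidence Per-cycle probability of a new (subsequent) VF for
#'   anyone with an existing VF.
#' @param rr_treatment Relative risk multiplier on `new_vf_incidence` while on
#'   anti-osteoporotic therapy; in `(0, 1]`.
#' @param vfa_sensitivity,vfa_specificity Per-patient diagnostic accuracy of
#'   vertebral fracture assessment (VFA).
#' @param p_vfa_unreadable Per-patient probability that the VFA image is
#'   unreadable.
#' @param xray_sensitivity,xray_specificity Accuracy of spine radiography;
#'   1.0 in every published scenario (gold standard).
#' @param cost_vfa,cost_xray Cost per performed test in euros, inclusive of
#'   the physician visit.
#' @param cost_vf_treatment All-in treatment cost of a vertebral fracture,
#'   euros per patient.
#' @param cost_physician_visit,cost_drug_year,cost_procedure Component costs
#'   in euros: one physician visit, one year of anti-osteoporotic drugs, and
#'   the fracture-related procedure performed in symptomatic cases.
#' @param dose_xray,dose_vfa Effective radiation dose per performed test, in
#'   microsievert.
#' @param discount_rate Annual discount rate applied to future costs.
#' @param cycle_length Cycle (and screening interval) length in years.
#' @param horizon Time horizon in years; must be a multiple of
#'   `cycle_length`.
#' @param asymptomatic_ratio Asymptomatic-to-symptomatic VF ratio used when
#'   deriving total incidence from clinically diagnosed incidence.
#' @param population_weight Registration population used for the sex-weighted
#'   total row.
#' @param cohort_size Nominal cohort size for reporting (the engine works in
#'   fractions).
#' @param univariate Named list of single-parameter alternative values for the
#'   univariate sensitivity analysis, or `NULL`.
#'
#' @return An object of class `vf_parameters`.
#' @seealso [load_parameter_set()], [univariate_variants()]
#' @export
vf_parameters <- function(sex,
                          scenario,
                          vf_prevalence,
                          vf_incidence,
                          new_vf_incidence,
                          rr_treatment,
                          vfa_sensitivity,
                          vfa_specificity,
                          p_vfa_unreadable,
                          xray_sensitivity = 1,
                          xray_specificity = 1,
                          cost_vfa,
                          cost_xray,
                          cost_vf_treatment,
                          cost_physician_visit,
                          cost_drug_year,
                          cost_procedure,
                          dose_xray,
                          dose_vfa,
                          discount_rate = 0.05,
                          cycle_length = 2,
                          horizon = 10,
                          asymptomatic_ratio = 2.8,
                          population_weight = NA_real_,
                          cohort_size = 1000,
                          univariate = NULL) {
  p <- list(
    sex = match.arg(sex, c("female", "male")),
    scenario = as.character(scenario),
    vf_prevalence = vf_prevalence,
    vf_incidence = vf_incidence,
    new_vf_incidence = new_vf_incidence,
    rr_treatment = rr_treatment,
    vfa_sensitivity = vfa_sensitivity,
    vfa_specificity = vfa_specificity,
    p_vfa_unreadable = p_vfa_unreadable,
    xray_sensitivity = xray_sensitivity,
    xray_specificity = xray_specificity,
    cost_vfa = cost_vfa,
    cost_xray = cost_xray,
    cost_vf_treatment = cost_vf_treatment,
    cost_physician_visit = cost_physician_visit,
    cost_drug_year = cost_drug_year,
    cost_procedure = cost_procedure,
    dose_xray = dose_xray,
    dose_vfa = dose_vfa,
    discount_rate = discount_rate,
    cycle_length = cycle_length,
    horizon = horizon,
    asymptomatic_ratio = asymptomatic_ratio,
    population_weight = population_weight,
    cohort_size = cohort_size,
    univariate = univariate
  )
  class(p) <- "vf_parameters"
  validate_parameters(p)
}

#' @export
print.vf_parameters <- function(x, ...) {
  cat(sprintf("<vf_parameters> sex=%s scenario=%s\n", x$sex, x$scenario))
  cat(sprintf("  prevalence %.2f | incidence %.2f | new-VF %.2f | RR %.2f per %g-y cycle\n",
              x$vf_prevalence, x$vf_incidence, x$new_vf_incidence,
              x$rr_treatment, x$cycle_length))
  cat(sprintf("  VFA Se/Sp %.2f/%.2f unreadable %.2f | horizon %g y | discount %g\n",
              x$vfa_sensitivity, x$vfa_specificity, x$p_vfa_unreadable,
              x$horizon, x$discount_rate))
  invisible(x)
}

prob_fields <- c("vf_prevalence", "vf_incidence", "new_vf_incidence",
                 "vfa_sensitivity", "vfa_specificity", "p_vfa_unreadable",
                 "xray_sensitivity", "xray_specificity")
cost_fields <- c("cost_vfa", "cost_xray", "cost_vf_treatment",
                 "cost_physician_visit", "cost_drug_year", "cost_procedure")
dose_fields <- c("dose_xray", "dose_vfa")

#' Validate a parameter set against the model invariants
#'
#' Checks every probability field lies in `[0, 1]`, the treatment relative
#' risk in `(0, 1]`, costs and doses are non-negative, and the cycle length
#' divides the horizon evenly. Called by [vf_parameters()]; exported so
#' manually edited objects can be re-checked.
#'
#' @param p A [vf_parameters] object.
#' @return `p`, invisibly unchanged, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_parameters <- function(p) {
  stopifnot(inherits(p, "vf_parameters"))
  for (f in prob_fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("parameter '%s' must be a probability in [0, 1], got %s",
                   f, format(v)), call. = FALSE)
    }
  }
  if (!is.numeric(p$rr_treatment) || p$rr_treatment <= 0 || p$rr_treatment > 1) {
    stop("parameter 'rr_treatment' must lie in (0, 1]", call. = FALSE)
  }
  for (f in c(cost_fields, dose_fields)) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop(sprintf("parameter '%s' must be a non-negative number", f),
           call. = FALSE)
    }
  }
  if (p$discount_rate < 0) stop("parameter 'discount_rate' must be >= 0", call. = FALSE)
  if (p$cycle_length <= 0 || p$horizon < 0) {
    stop("'cycle_length' must be positive and 'horizon' non-negative", call. = FALSE)
  }
  n_cyc <- p$horizon / p$cycle_length
  if (abs(n_cyc - round(n_cyc)) > 1e-9) {
    stop(sprintf("parameter 'cycle_length' (%g) must divide 'horizon' (%g) evenly",
                 p$cycle_length, p$horizon), call. = FALSE)
  }
  p
}

#' Path to a shipped scenario configuration file
#'
#' @param scenario One of `"base_case"`, `"cycle_1y"`, `"subgroup_old_age"`.
#' @return Path to the YAML file installed with the package.
#' @export
vf_config_path <- function(scenario = c("base_case", "cycle_1y", "subgroup_old_age")) {
  scenario <- match.arg(scenario)
  path <- system.file("extdata", "config", paste0(scenario, ".yaml"),
                      package = "vfscreen", mustWork = FALSE)
  if (!nzchar(path)) {
    stop(sprintf("configuration file for scenario '%s' not found", scenario),
         call. = FALSE)
  }
  path
}

#' Load a parameter set from a configuration source
#'
#' Reads one sex block of one scenario configuration and returns a validated
#' [vf_parameters] object. The configuration may be a YAML file path, an
#' already-parsed list, or a scenario name shipped with the package.
#'
#' @param config_source A YAML file path, a parsed configuration list, or
#'   `NULL` to use the shipped file named by `scenario`.
#' @param sex `"female"` or `"male"`.
#' @param scenario Scenario label; must match the configuration's
#'   `scenario` field.
#' @return A [vf_parameters] object.
#' @examples
#' p <- load_parameter_set(NULL, "female", "base_case")
#' p$vf_prevalence
#' @export
load_parameter_set <- function(config_source = NULL, sex = c("female", "male"),
                               scenario = "base_case") {
  sex <- match.arg(sex)
  if (is.null(config_source)) {
    config_source <- vf_config_path(scenario)
  }
  cfg <- if (is.character(config_source)) {
    if (!file.exists(config_source)) {
      stop(sprintf("configuration file '%s' does not exist", config_source),
           call. = FALSE)
    }
    yaml::read_yaml(config_source)
  } else if (is.list(config_source)) {
    config_source
  } else {
    stop("'config_source' must be a file path or a configuration list",
         call. = FALSE)
  }
  if (is.null(cfg$scenario) || !identical(cfg$scenario, scenario)) {
    stop(sprintf("configuration does not provide scenario '%s' (found '%s')",
                 scenario, cfg$scenario %||% "<none>"), call. = FALSE)
  }
  sex_key <- c(female = "women", male = "men")[[sex]]
  blk <- cfg[[sex_key]]
  if (is.null(blk)) {
    stop(sprintf("configuration is missing the '%s' block for sex '%s'",
                 sex_key, sex), call. = FALSE)
  }
  shared <- cfg[setdiff(names(cfg), c("scenario", "women", "men"))]
  fields <- c(shared, blk)
  uni <- fields$univariate
  fields$univariate <- NULL
  do.call(vf_parameters,
          c(list(sex = sex, scenario = scenario, univariate = uni), fields))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total (clinical plus radiographic) incidence from symptomatic incidence
#'
#' Claims-derived fracture incidence only captures clinically diagnosed
#' (symptomatic) fractures. Multiplying by the asymptomatic-to-symptomatic
#' ratio recovers the total incidence the model needs. The shipped input
#' tables are already adjusted, so this is a documented derivation utility,
#' not part of the model pipeline.
#'
#' @param symptomatic_probability Per-cycle probability of a clinically
#'   diagnosed fracture.
#' @param ratio Asymptomatic-to-symptomatic ratio (2.8 in the shipped inputs).
#' @return `symptomatic_probability * ratio`.
#' @export
adjust_symptomatic_incidence <- function(symptomatic_probability, ratio = 2.8) {
  if (any(symptomatic_probability < 0)) {
    stop("'symptomatic_probability' must be non-negative", call. = FALSE)
  }
  if (any(ratio <= 0)) stop("'ratio' must be positive", call. = FALSE)
  out <- symptomatic_probability * ratio
  if (any(out > 1)) {
    stop(sprintf("adjusted incidence %.3f exceeds 1: not a probability",
                 max(out)), call. = FALSE)
  }
  out
}

#' Convert a per-cycle probability between cycle lengths
#'
#' Uses the constant-hazard assumption
#' `1 - (1 - p)^(to_years / from_years)`. Published cycle lengths (one and
#' two years) always use the printed values directly; this conversion exists
#' for exploring other cycle lengths.
#'
#' @param p Probability over `from_years`.
#' @param from_years,to_years Durations in years; both positive.
#' @return Probability over `to_years`.
#' @export
convert_cycle_probability <- function(p, from_years, to_years) {
  if (any(from_years <= 0) || any(to_years <= 0)) {
    stop("durations must be positive", call. = FALSE)
  }
  if (any(p < 0) || any(p > 1)) stop("'p' must lie in [0, 1]", call. = FALSE)
  1 - (1 - p)^(to_years / from_years)
}

#' Univariate sensitivity-analysis variants of a base-case parameter set
#'
#' Builds one variant per bracketed alternative value shipped with the
#' base-case inputs; each variant differs from the base set in exactly one
#' field. The base object is never modified.
#'
#' @param base A base-case [vf_parameters] object carrying a `univariate`
#'   block.
#' @return A named list of `vf_parameters`, one per varied field.
#' @export
univariate_variants <- function(base) {
  stopifnot(inherits(base, "vf_parameters"))
  uni <- base$univariate
  if (is.null(uni) || length(uni) == 0L) {
    stop(sprintf("parameter set '%s'/%s carries no univariate alternatives",
                 base$scenario, base$sex), call. = FALSE)
  }
  out <- vector("list", length(uni))
  names(out) <- names(uni)
  for (f in names(uni)) {
    if (!f %in% names(base)) {
      stop(sprintf("univariate block names unknown parameter '%s'", f),
           call. = FALSE)
    }
    v <- base
    v[[f]] <- uni[[f]]
    v$scenario <- paste0(base$scenario, "_", f)
    class(v) <- "vf_parameters"
    out[[f]] <- validate_parameters(v)
  }
  out
}
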