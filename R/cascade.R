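#' Screening strategies
#'
#' The four strategies compared by the model: no screening, vertebral
#' fracture assessment (VFA) with radiographic confirmation of positives,
#' VFA alone, and spine radiography alone.
#'
#' @return Character vector of the four strategy names.
#' @export
vf_strategies <- function() {
  c("no_screening", "xray_after_vfa", "vfa_only", "xray_only")
}

assert_strategy <- function(strategy) {
  if (!is.character(strategy) || length(strategy) != 1L ||
      !strategy %in% vf_strategies()) {
    stop(sprintf("unknown strategy '%s'; valid strategies: %s",
                 paste(strategy, collapse = ","),
                 paste(vf_strategies(), collapse = ", ")), call. = FALSE)
  }
  strategy
}

# Compartment bookkeeping -----------------------------------------------------
#
# Health states crossed with strata:
#   NOVF  no fracture           PREV  undiagnosed prevalent fracture
#   POST  diagnosed + treated, no new fracture yet
#   PEVT  had >= 1 new fracture but still in the model (only reachable when
#         untreated subjects stay after a new fracture)
#   EXIT  removed after a diagnosed new fracture (retains excluded mass)
# Strata: .u untreated & screenable, .t on therapy, .i VFA-impossible
# (absorbing for screening; disease progression continues).

#' Compartment labels of the cohort state vector
#' @return Character vector of compartment names.
#' @export
vf_compartments <- function() {
  c("NOVF.u", "NOVF.i",
    "PREV.u", "PREV.t", "PREV.i",
    "POST.u", "POST.t", "POST.i",
    "PEVT.u", "PEVT.t", "PEVT.i",
    "EXIT")
}

#' Occupancy vectors over the model compartments
#'
#' `empty_occupancy()` returns an all-zero named vector over
#' [vf_compartments()]; `initial_occupancy()` places the cohort at the
#' starting prevalence of undiagnosed fractures.
#'
#' @param params A [vf_parameters] object.
#' @return A named numeric vector over [vf_compartments()].
#' @export
empty_occupancy <- function() {
  stats::setNames(numeric(length(vf_compartments())), vf_compartments())
}

#' @rdname empty_occupancy
#' @export
initial_occupancy <- function(params) {
  occ <- empty_occupancy()
  occ["PREV.u"] <- params$vf_prevalence
  occ["NOVF.u"] <- 1 - params$vf_prevalence
  occ
}

check_occupancy <- function(occ) {
  if (any(occ < -1e-12)) {
    stop("negative compartment occupancy", call. = FALSE)
  }
  occ
}

#' Per-screen diagnostic profile of a strategy
#'
#' Collapses one screening event into arm-wise quantities: the probability of
#' starting therapy, the probability of exiting to the VFA-impossible state,
#' and the expected test cost and radiation dose, conditional on true
#' fracture status. Three arms are distinguished: subjects without a
#' fracture, subjects with an undiagnosed fracture, and previously diagnosed
#' subjects being re-screened (identical to the undiagnosed arm except when
#' `reconfirm_known` is off in the combined strategy).
#'
#' @param strategy One of [vf_strategies()].
#' @param params A [vf_parameters] object.
#' @param conventions A [vf_conventions] object.
#' @return An object of class `vf_screen_profile`: a list with elements
#'   `novf`, `vf_new`, `vf_known`, each holding `p_treat`, `p_unreadable`,
#'   `cost`, `dose`.
#' @export
screen_profile <- function(strategy, params, conventions = vf_conventions()) {
  assert_strategy(strategy)
  arm <- function(p_treat = 0, p_unreadable = 0, cost = 0, dose = 0) {
    stopifnot(p_treat >= 0, p_unreadable >= 0, p_treat + p_unreadable <= 1 + 1e-12)
    list(p_treat = p_treat, p_unreadable = p_unreadable,
         cost = cost, dose = dose)
  }
  se <- params$vfa_sensitivity
  sp <- params$vfa_specificity
  pu <- params$p_vfa_unreadable
  se_x <- params$xray_sensitivity
  sp_x <- params$xray_specificity

  prof <- switch(
    strategy,
    no_screening = list(novf = arm(), vf_new = arm(), vf_known = arm()),
    xray_only = {
      a_vf <- arm(p_treat = se_x, cost = params$cost_xray, dose = params$dose_xray)
      a_no <- arm(p_treat = 1 - sp_x, cost = params$cost_xray, dose = params$dose_xray)
      list(novf = a_no, vf_new = a_vf, vf_known = a_vf)
    },
    vfa_only = {
      # unreadable first, then classification of the readable fraction
      a_vf <- arm(p_treat = (1 - pu) * se, p_unreadable = pu,
                  cost = params$cost_vfa, dose = params$dose_vfa)
      a_no <- arm(p_treat = (1 - pu) * (1 - sp), p_unreadable = pu,
                  cost = params$cost_vfa, dose = params$dose_vfa)
      list(novf = a_no, vf_new = a_vf, vf_known = a_vf)
    },
    xray_after_vfa = {
      resolve_unreadable <- identical(conventions$unreadable_combined, "xray")
      # fraction of each arm sent on to the confirmatory radiograph
      conf_vf <- (1 - pu) * se + if (resolve_unreadable) pu else 0
      conf_no <- (1 - pu) * (1 - sp) + if (resolve_unreadable) pu else 0
      p_un <- if (resolve_unreadable) 0 else pu
      mk <- function(conf, p_treat) {
        dose <- params$dose_vfa + conf * params$dose_xray
        if (identical(conventions$confirm_dose, "flat625")) {
          dose <- params$dose_vfa + params$dose_xray
        }
        arm(p_treat = p_treat, p_unreadable = p_un,
            cost = params$cost_vfa + conf * params$cost_xray, dose = dose)
      }
      a_vf <- mk(conf_vf, conf_vf * se_x)
      a_no <- mk(conf_no, conf_no * (1 - sp_x))
      a_known <- if (conventions$reconfirm_known) {
        a_vf
      } else {
        # a known fracture re-screening positive (or unreadable) restarts
        # therapy on the VFA result alone
        arm(p_treat = (1 - pu) * se + pu, p_unreadable = 0,
            cost = params$cost_vfa, dose = params$dose_vfa)
      }
      list(novf = a_no, vf_new = a_vf, vf_known = a_known)
    }
  )
  prof$strategy <- strategy
  class(prof) <- "vf_screen_profile"
  prof
}

#' Apply one screening event to a cohort occupancy vector
#'
#' Splits the screened compartments into treated and untreated strata, moves
#' unreadable mass to the VFA-impossible stratum, and returns the per-capita
#' (undiscounted) screening-related cost and radiation dose accrued by the
#' event. Mass is conserved exactly. Subjects already diagnosed (POST/PEVT)
#' are re-screened and re-treated if positive; VFA-impossible and excluded
#' mass is not screened.
#'
#' @param profile A `vf_screen_profile`.
#' @param occupancy Named occupancy vector over [vf_compartments()].
#' @param params A [vf_parameters] object (therapy and diagnosis costs).
#' @param conventions A [vf_conventions] object (cost accrual rule).
#' @return A list with `occupancy`, `cost`, `dose` and `n_screened`
#'   (per-capita number of tests performed at this event).
#' @export
apply_screen <- function(profile, occupancy, params,
                         conventions = vf_conventions()) {
  stopifnot(inherits(profile, "vf_screen_profile"))
  occ <- check_occupancy(occupancy)
  if (identical(profile$strategy, "no_screening")) {
    return(list(occupancy = occ, cost = 0, dose = 0, n_screened = 0))
  }
  cost <- 0
  dose <- 0
  therapy_unit <- params$cost_drug_year + params$cost_physician_visit
  charge_dx <- identical(conventions$vf_cost, "diagnosis")

  screened <- c(NOVF.u = "novf", PREV.u = "vf_new",
                POST.u = "vf_known", PEVT.u = "vf_known")
  n_screened <- sum(occ[names(screened)])
  for (comp in names(screened)) {
    m <- occ[[comp]]
    if (m <= 0) next
    a <- profile[[screened[[comp]]]]
    cost <- cost + m * a$cost
    dose <- dose + m * a$dose
    treat <- m * a$p_treat
    unread <- m * a$p_unreadable
    state <- sub("\\..*$", "", comp)
    occ[[comp]] <- m - unread - if (state == "NOVF") 0 else treat
    occ[[paste0(state, ".i")]] <- occ[[paste0(state, ".i")]] + unread
    if (state != "NOVF") {
      occ[[paste0(state, ".t")]] <- occ[[paste0(state, ".t")]] + treat
    }
    cost <- cost + treat * therapy_unit
    if (charge_dx && comp %in% c("NOVF.u", "PREV.u")) {
      # first-time positive classification: all-in fracture treatment cost
      cost <- cost + treat * params$cost_vf_treatment
    }
  }
  list(occupancy = check_occupancy(occ), cost = cost, dose = dose,
       n_screened = n_screened)
}
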