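#' Per-cycle health-state transition probabilities
#'
#' Builds the row-stochastic transition matrix over the model's health states
#' for one cycle, for subjects on or off therapy. Fracture states never
#' return to the fracture-free state; subjects on therapy whose cycle passes
#' without a new fracture move to the post-fracture state when therapy ends.
#'
#' @param params A [vf_parameters] object.
#' @param on_therapy Logical; apply the treatment relative risk.
#' @param conventions A [vf_conventions] object (relative-risk timing).
#' @return A named matrix over `NO_VF`, `PREVALENT_VF`, `POST_VF`, `NEW_VF`;
#'   rows sum to one.
#' @export
build_cycle_transition <- function(params, on_therapy = FALSE,
                                   conventions = vf_conventions()) {
  p_new <- new_vf_prob(params, on_therapy, conventions)
  if (p_new < 0 || p_new > 1 || params$vf_incidence < 0 || params$vf_incidence > 1) {
    stop("effective transition probability outside [0, 1]", call. = FALSE)
  }
  states <- c("NO_VF", "PREVALENT_VF", "POST_VF", "NEW_VF")
  m <- matrix(0, 4, 4, dimnames = list(states, states))
  m["NO_VF", "PREVALENT_VF"] <- params$vf_incidence
  m["NO_VF", "NO_VF"] <- 1 - params$vf_incidence
  m["PREVALENT_VF", "NEW_VF"] <- p_new
  if (on_therapy) {
    m["PREVALENT_VF", "POST_VF"] <- 1 - p_new
  } else {
    m["PREVALENT_VF", "PREVALENT_VF"] <- 1 - p_new
  }
  m["POST_VF", "NEW_VF"] <- p_new
  m["POST_VF", "POST_VF"] <- 1 - p_new
  m["NEW_VF", "NEW_VF"] <- 1
  m
}

# Effective per-cycle new-fracture probability, honouring the relative-risk
# timing convention: the one-year therapy course either shields the whole
# cycle or only its first year.
new_vf_prob <- function(params, on_therapy, conventions) {
  p <- params$new_vf_incidence
  if (!on_therapy) return(p)
  rr <- params$rr_treatment
  if (identical(conventions$rr_timing, "prorated") && params$cycle_length > 1) {
    p1 <- convert_cycle_probability(p, params$cycle_length, 1)
    n_rest <- params$cycle_length - 1
    1 - (1 - p1 * rr) * (1 - p1)^n_rest
  } else {
    p * rr
  }
}

#' Discount factor for a payoff accrued during the simulation
#'
#' Annual compounding, `(1 + rate)^(-t)`. With the half-cycle correction the
#' event time is shifted to the midpoint of the cycle it opens, reducing the
#' discrete-time bias of charging everything at cycle boundaries. Only costs
#' are discounted in this model; effectiveness and radiation dose are not.
#'
#' @param event_time_years Nominal event time (cycle or screening-event
#'   start), years from model start.
#' @param rate Annual discount rate.
#' @param half_cycle Apply the half-cycle correction.
#' @param cycle_length Cycle length in years.
#' @return Unitless discount factor.
#' @export
discount_factor <- function(event_time_years, rate, half_cycle = TRUE,
                            cycle_length = 2) {
  if (any(event_time_years < 0)) stop("negative event time", call. = FALSE)
  if (any(rate < 0)) stop("negative discount rate", call. = FALSE)
  t_eff <- event_time_years + if (half_cycle) cycle_length / 2 else 0
  (1 + rate)^(-t_eff)
}

schedule_counts <- function(params, conventions) {
  n_cyc <- as.integer(round(params$horizon / params$cycle_length))
  switch(conventions$schedule,
         closed = list(n_cycles = n_cyc, final_screen = FALSE),
         fencepost = list(n_cycles = n_cyc, final_screen = TRUE),
         extra_cycle = list(n_cycles = n_cyc + 1L, final_screen = FALSE))
}

# One transition cycle over the stratified occupancy vector. Returns the new
# occupancy plus the counted new-fracture flow and the cost-bearing flows.
cycle_flows <- function(occ, params, conventions) {
  p_vfi <- params$vf_incidence
  p_u <- new_vf_prob(params, FALSE, conventions)
  p_t <- new_vf_prob(params, TRUE, conventions)
  stay <- identical(conventions$untreated_exit, "stay")
  events_counting <- identical(conventions$counting, "events")

  out <- empty_occupancy()
  counted <- 0       # new fractures entering the cumulative incidence
  ev_untreated <- 0  # new-fracture flow off therapy (cost accrual)
  ev_treated <- 0    # new-fracture flow on therapy

  add <- function(comp, m) out[[comp]] <<- out[[comp]] + m

  # fracture-free strata acquire a first fracture
  for (s in c("u", "i")) {
    m <- occ[[paste0("NOVF.", s)]]
    add(paste0("PREV.", s), m * p_vfi)
    add(paste0("NOVF.", s), m * (1 - p_vfi))
  }

  # untreated at-risk strata: PREV/POST (first new fracture) and PEVT (repeat)
  for (comp in c("PREV.u", "PREV.i", "POST.u", "POST.i")) {
    m <- occ[[comp]]
    f <- m * p_u
    ev_untreated <- ev_untreated + f
    counted <- counted + f  # first new fracture: counted in both conventions
    if (stay) {
      add(sub("^(PREV|POST)", "PEVT", comp), f)
    } else {
      add("EXIT", f)
    }
    add(comp, m - f)
  }
  for (comp in c("PEVT.u", "PEVT.i")) {
    m <- occ[[comp]]
    f <- m * p_u
    ev_untreated <- ev_untreated + f
    if (events_counting) counted <- counted + f
    if (stay) {
      add(comp, m)  # repeat fractures do not remove the subject
    } else {
      add(comp, m - f)
      add("EXIT", f)
    }
  }

  # on-therapy strata: a diagnosed new fracture removes the subject;
  # survivors revert to untreated post-fracture status when therapy ends
  for (comp in c("PREV.t", "POST.t", "PEVT.t")) {
    m <- occ[[comp]]
    f <- m * p_t
    ev_treated <- ev_treated + f
    first <- comp %in% c("PREV.t", "POST.t")
    if (first || events_counting) counted <- counted + f
    add("EXIT", f)
    dest <- if (comp == "PEVT.t") "PEVT.u" else "POST.u"
    add(dest, m - f)
  }

  add("EXIT", occ[["EXIT"]])
  list(occupancy = out, counted = counted,
       ev_untreated = ev_untreated, ev_treated = ev_treated)
}

cycle_event_cost <- function(flows, params, conventions) {
  ev_all <- flows$ev_untreated + flows$ev_treated
  sympt <- 1 / (1 + params$asymptomatic_ratio)
  switch(conventions$vf_cost,
         event = ev_all * params$cost_vf_treatment,
         event_plus_procedure = ev_all * params$cost_vf_treatment +
           ev_all * sympt * params$cost_procedure,
         diagnosis = flows$ev_untreated * sympt * params$cost_procedure)
}

#' Run the deterministic cohort model for one strategy
#'
#' Initialises the cohort at the prevalence of undiagnosed fractures, then
#' alternates screening events and transition cycles over the horizon,
#' accruing cumulative new-fracture incidence, discounted per-capita cost,
#' and cumulative radiation dose.
#'
#' @param strategy One of [vf_strategies()].
#' @param params A [vf_parameters] object.
#' @param conventions A [vf_conventions] object.
#' @param half_cycle Apply the half-cycle correction to cost discounting.
#' @return An object of class `vf_cohort_trace` with elements `strategy`,
#'   `params`, `conventions`, a per-cycle `trace` data frame (occupancy,
#'   cumulative incidence in percent, cumulative discounted cost, cumulative
#'   dose), and scalars `effectiveness` (%), `total_cost` (EUR, discounted),
#'   `total_dose` (microsievert) and `screens_per_capita`.
#' @export
run_cohort <- function(strategy, params, conventions = vf_conventions(),
                       half_cycle = TRUE) {
  assert_strategy(strategy)
  stopifnot(inherits(params, "vf_parameters"))
  sched <- schedule_counts(params, conventions)
  cl <- params$cycle_length
  prof <- screen_profile(strategy, params, conventions)

  occ <- initial_occupancy(params)
  cum_inc <- 0
  cum_cost <- 0
  cum_cost_undisc <- 0
  cum_dose <- 0
  screens <- 0
  rows <- vector("list", sched$n_cycles + 1L)

  snapshot <- function(cycle, time) {
    c(list(cycle = cycle, time = time,
           cum_incidence = 100 * cum_inc,
           cum_cost = cum_cost, cum_cost_undisc = cum_cost_undisc,
           cum_dose = cum_dose),
      as.list(occ))
  }

  for (k in seq_len(sched$n_cycles)) {
    t0 <- (k - 1) * cl
    sc <- apply_screen(prof, occ, params, conventions)
    occ <- sc$occupancy
    df <- discount_factor(t0, params$discount_rate, half_cycle, cl)
    cum_cost <- cum_cost + sc$cost * df
    cum_cost_undisc <- cum_cost_undisc + sc$cost
    cum_dose <- cum_dose + sc$dose
    screens <- screens + sc$n_screened

    fl <- cycle_flows(occ, params, conventions)
    occ <- check_occupancy(fl$occupancy)
    total <- sum(occ)
    if (abs(total - 1) > 1e-9) {
      stop(sprintf("mass not conserved at cycle %d (total %.15f)", k, total),
           call. = FALSE)
    }
    cum_inc <- cum_inc + fl$counted
    ev_cost <- cycle_event_cost(fl, params, conventions)
    cum_cost <- cum_cost + ev_cost * df
    cum_cost_undisc <- cum_cost_undisc + ev_cost
    rows[[k]] <- snapshot(k, t0 + cl)
  }
  if (sched$final_screen) {
    t_end <- sched$n_cycles * cl
    sc <- apply_screen(prof, occ, params, conventions)
    occ <- sc$occupancy
    df <- discount_factor(t_end, params$discount_rate, half_cycle, cl)
    cum_cost <- cum_cost + sc$cost * df
    cum_cost_undisc <- cum_cost_undisc + sc$cost
    cum_dose <- cum_dose + sc$dose
    screens <- screens + sc$n_screened
    rows[[sched$n_cycles + 1L]] <- snapshot(sched$n_cycles, t_end)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  trace <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))

  structure(list(
    strategy = strategy,
    params = params,
    conventions = conventions,
    half_cycle = half_cycle,
    trace = trace,
    effectiveness = 100 * cum_inc,
    total_cost = cum_cost,
    total_cost_undisc = cum_cost_undisc,
    total_dose = cum_dose,
    screens_per_capita = screens
  ), class = "vf_cohort_trace")
}

#' @export
print.vf_cohort_trace <- function(x, ...) {
  cat(sprintf("<vf_cohort_trace> %s | %s/%s\n", x$strategy,
              x$params$sex, x$params$scenario))
  cat(sprintf("  new-VF incidence %.1f%% | cost EUR %.0f | dose %.0f uSv | %.2f screens per capita\n",
              x$effectiveness, x$total_cost, x$total_dose, x$screens_per_capita))
  invisible(x)
}

#' Export a cohort trace as a tidy data frame
#'
#' One row per cycle and compartment, plus cumulative summary columns.
#'
#' @param trace A `vf_cohort_trace`.
#' @return A data frame with columns `cycle`, `time`, `compartment`,
#'   `occupancy`, `cum_incidence`, `cum_cost`, `cum_dose`.
#' @export
trace_as_tidy <- function(trace) {
  stopifnot(inherits(trace, "vf_cohort_trace"))
  tr <- trace$trace
  comps <- vf_compartments()
  out <- do.call(rbind, lapply(seq_len(nrow(tr)), function(i) {
    data.frame(cycle = tr$cycle[i], time = tr$time[i],
               compartment = comps,
               occupancy = as.numeric(tr[i, comps]),
               cum_incidence = tr$cum_incidence[i],
               cum_cost = tr$cum_cost[i], cum_dose = tr$cum_dose[i])
  }))
  rownames(out) <- NULL
  out
}
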