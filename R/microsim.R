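#' Individual-level microsimulation of the screening model
#'
#' Stochastic twin of the deterministic cohort engine: simulates `n`
#' independent patient trajectories under the same parameters and the same
#' active conventions, drawing every screening outcome and health-state
#' transition individually. Used as a Monte-Carlo oracle to validate the
#' cohort engine ([validate_against_cohort()]).
#'
#' Reproducibility: a single base-R Mersenne-Twister stream seeded with
#' `seed`; draws are made in a fixed vectorised order (per cycle, over all
#' patients), so identical `(params, n, seed)` yield identical trajectories.
#'
#' @param strategy One of [vf_strategies()].
#' @param params A [vf_parameters] object.
#' @param n Number of simulated patients.
#' @param seed Integer seed.
#' @param conventions A [vf_conventions] object.
#' @return An object of class `vf_microsim`: list with `events` (tidy event
#'   log: `patient_id`, `time`, `event`, `cost`, `dose`, `counted`),
#'   `final_state`, `n`, `strategy`, `params`, `conventions`, `seed`.
#' @export
simulate_cohort <- function(strategy, params, n, seed,
                            conventions = vf_conventions()) {
  assert_strategy(strategy)
  stopifnot(inherits(params, "vf_parameters"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 ||
      n != round(n)) {
    stop("'n' must be a non-negative integer", call. = FALSE)
  }
  n <- as.integer(n)
  set.seed(as.integer(seed), kind = "Mersenne-Twister")

  cl <- params$cycle_length
  sched <- schedule_counts(params, conventions)
  p_u <- new_vf_prob(params, FALSE, conventions)
  p_t <- new_vf_prob(params, TRUE, conventions)
  sympt <- 1 / (1 + params$asymptomatic_ratio)
  therapy_unit <- params$cost_drug_year + params$cost_physician_visit
  stay <- identical(conventions$untreated_exit, "stay")
  events_counting <- identical(conventions$counting, "events")
  vf_cost <- conventions$vf_cost

  # states: 1 no VF, 2 prevalent VF, 3 post VF, 4 post-event, 5 excluded
  state <- ifelse(stats::runif(n) < params$vf_prevalence, 2L, 1L)
  imp <- rep(FALSE, n)

  log <- vector("list", 64L)
  n_log <- 0L
  log_ev <- function(ids, time, event, cost = 0, dose = 0, counted = FALSE) {
    if (length(ids) == 0L) return(invisible(NULL))
    n_log <<- n_log + 1L
    if (n_log > length(log)) length(log) <<- 2L * n_log
    log[[n_log]] <<- data.frame(
      patient_id = ids, time = time, event = event,
      cost = rep_len(cost, length(ids)), dose = rep_len(dose, length(ids)),
      counted = rep_len(counted, length(ids)))
    invisible(NULL)
  }

  do_screen <- function(t0) {
    if (identical(strategy, "no_screening")) return(invisible(NULL))
    sc <- which(state != 5L & !imp)
    if (length(sc) == 0L) return(invisible(NULL))
    vf <- state[sc] != 1L
    known <- state[sc] %in% c(3L, 4L)
    pos <- rep(FALSE, length(sc))
    cost <- numeric(length(sc))
    dose <- numeric(length(sc))
    unread <- rep(FALSE, length(sc))

    if (strategy == "xray_only") {
      cost <- cost + params$cost_xray
      dose <- dose + params$dose_xray
      u <- stats::runif(length(sc))
      pos <- ifelse(vf, u < params$xray_sensitivity,
                    u < 1 - params$xray_specificity)
    } else {
      cost <- cost + params$cost_vfa
      dose <- dose + params$dose_vfa
      unread <- stats::runif(length(sc)) < params$p_vfa_unreadable
      u <- stats::runif(length(sc))
      vfa_pos <- !unread & ifelse(vf, u < params$vfa_sensitivity,
                                  u < 1 - params$vfa_specificity)
      if (strategy == "vfa_only") {
        pos <- vfa_pos
      } else { # xray_after_vfa
        resolve <- identical(conventions$unreadable_combined, "xray")
        # a previously diagnosed patient needs no repeat confirmation when
        # reconfirm_known is off: positive or unreadable VFA restarts therapy
        noconf <- known & !conventions$reconfirm_known
        direct <- noconf & (vfa_pos | unread)
        confirm <- !noconf & (vfa_pos | (unread & resolve))
        cost <- cost + confirm * params$cost_xray
        if (identical(conventions$confirm_dose, "flat625")) {
          dose <- dose + params$dose_xray
        } else {
          dose <- dose + confirm * params$dose_xray
        }
        u2 <- stats::runif(length(sc))
        conf_pos <- confirm & ifelse(vf, u2 < params$xray_sensitivity,
                                     u2 < 1 - params$xray_specificity)
        pos <- direct | conf_pos
        unread <- unread & !resolve & !noconf
      }
    }
    log_ev(sc, t0, "screen", cost, dose)
    log_ev(sc[unread], t0, "vfa_unreadable")
    imp[sc[unread]] <<- TRUE

    # under diagnosis-mode cost accrual, a first-time positive classification
    # carries the all-in fracture treatment cost
    dx <- numeric(length(sc))
    if (identical(vf_cost, "diagnosis")) {
      dx[pos & !known] <- params$cost_vf_treatment
    }
    log_ev(sc[pos], t0, "test_positive", dx[pos])
    start <- pos & vf
    tx[sc[start]] <<- TRUE
    log_ev(sc[start], t0, "therapy_start", therapy_unit)
    # false positives: therapy cost without clinical effect
    fp <- pos & !vf
    log_ev(sc[fp], t0, "therapy_start", therapy_unit)
    invisible(NULL)
  }

  tx <- rep(FALSE, n)
  counted_total <- 0

  for (k in seq_len(sched$n_cycles)) {
    t0 <- (k - 1) * cl
    do_screen(t0)

    # first fracture (takes effect next cycle: entrants are not yet at risk)
    nv <- which(state == 1L)
    inc <- nv[stats::runif(length(nv)) < params$vf_incidence]
    log_ev(inc, t0, "incident_vf")

    # new fracture among at-risk states
    risk <- which(state %in% c(2L, 3L, 4L))
    state[inc] <- 2L
    if (length(risk) > 0L) {
      p <- ifelse(tx[risk], p_t, p_u)
      hit <- risk[stats::runif(length(risk)) < p]
      if (length(hit) > 0L) {
        first <- state[hit] %in% c(2L, 3L)
        cnt <- first | events_counting
        treated <- tx[hit]
        ev_cost <- switch(vf_cost,
          event = rep(params$cost_vf_treatment, length(hit)),
          event_plus_procedure = rep(params$cost_vf_treatment +
            sympt * params$cost_procedure, length(hit)),
          diagnosis = ifelse(treated, 0, sympt * params$cost_procedure))
        exits <- treated | !stay
        log_ev(hit[exits], t0, "new_vf_exit", ev_cost[exits], 0, cnt[exits])
        log_ev(hit[!exits], t0, "new_vf", ev_cost[!exits], 0, cnt[!exits])
        state[hit[exits]] <- 5L
        state[hit[!exits]] <- 4L
      }
    }
    # therapy ends after one year; survivors move to post-fracture status
    done <- which(tx & state %in% c(2L, 3L))
    state[done] <- 3L
    log_ev(which(tx & state != 5L), t0 + 1, "therapy_end")
    tx[] <- FALSE
  }
  if (sched$final_screen) do_screen(sched$n_cycles * cl)

  events <- if (n_log > 0L) {
    do.call(rbind, log[seq_len(n_log)])
  } else {
    data.frame(patient_id = integer(), time = numeric(), event = character(),
               cost = numeric(), dose = numeric(), counted = logical())
  }
  events <- events[order(events$patient_id, events$time), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, final_state = state, n = n,
                 strategy = strategy, params = params,
                 conventions = conventions, seed = as.integer(seed)),
            class = "vf_microsim")
}

#' Summarise a microsimulation run
#'
#' Per-capita cumulative new-fracture incidence, mean discounted cost and
#' mean radiation dose, with Monte-Carlo standard errors, using the same
#' discounting rules as the cohort engine.
#'
#' @param sim A `vf_microsim` object.
#' @param half_cycle Apply the half-cycle correction when discounting costs.
#' @return A list with `n`, `incidence`, `cost`, `dose` and their standard
#'   errors `se_incidence`, `se_cost`, `se_dose`.
#' @export
summarize_microsim <- function(sim, half_cycle = TRUE) {
  stopifnot(inherits(sim, "vf_microsim"))
  if (sim$n == 0L) stop("cannot summarise an empty cohort", call. = FALSE)
  ev <- sim$events
  p <- sim$params
  per <- function(values, ids) {
    out <- numeric(sim$n)
    if (length(values) > 0L) {
      agg <- rowsum(values, ids)
      out[as.integer(rownames(agg))] <- agg[, 1]
    }
    out
  }
  df <- discount_factor(ev$time, p$discount_rate, half_cycle, p$cycle_length)
  cost_i <- per(ev$cost * df, ev$patient_id)
  dose_i <- per(ev$dose, ev$patient_id)
  count_i <- per(as.numeric(ev$counted), ev$patient_id)
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  list(
    n = sim$n,
    incidence = 100 * mean(count_i),
    cost = mean(cost_i),
    dose = mean(dose_i),
    se_incidence = 100 * sd0(count_i) / sqrt(sim$n),
    se_cost = sd0(cost_i) / sqrt(sim$n),
    se_dose = sd0(dose_i) / sqrt(sim$n)
  )
}

#' Validate the cohort engine against the microsimulation
#'
#' Runs both the deterministic cohort model and the microsimulation under
#' identical parameters and conventions and compares incidence, mean
#' discounted cost and mean dose. The check passes when every outcome lies
#' within `z_max` Monte-Carlo standard errors.
#'
#' @inheritParams simulate_cohort
#' @param z_max Pass threshold on the absolute z-score (default 3).
#' @return A list with `pass`, a per-outcome `table` (cohort value, microsim
#'   value, standard error, z), `n` and the inputs used.
#' @export
validate_against_cohort <- function(strategy, params, n, seed,
                                    conventions = vf_conventions(),
                                    z_max = 3) {
  trace <- run_cohort(strategy, params, conventions)
  sim <- simulate_cohort(strategy, params, n, seed, conventions)
  s <- summarize_microsim(sim)
  z <- function(micro, cohort, se) {
    if (se == 0) {
      if (abs(micro - cohort) < 1e-9) 0 else Inf
    } else {
      (micro - cohort) / se
    }
  }
  tab <- data.frame(
    outcome = c("incidence", "cost", "dose"),
    cohort = c(trace$effectiveness, trace$total_cost, trace$total_dose),
    microsim = c(s$incidence, s$cost, s$dose),
    se = c(s$se_incidence, s$se_cost, s$se_dose)
  )
  tab$z <- mapply(z, tab$microsim, tab$cohort, tab$se)
  wide <- s$se_incidence * stats::qnorm(0.975) > 2  # wide CI flag at small n
  list(pass = all(abs(tab$z) <= z_max), table = tab, n = n,
       wide_bounds = wide, strategy = strategy,
       sex = params$sex, scenario = params$scenario)
}
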