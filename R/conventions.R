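#' Modelling conventions for the cohort engine
#'
#' Several structural choices of the published model cannot be recovered
#' uniquely from its description: how many screening events and transition
#' cycles fit in the horizon, how a one-year course of therapy acts inside a
#' two-year cycle, whether an untreated patient leaves the model after a new
#' fracture, how unreadable VFA images are handled in the confirmation
#' strategy, and how fracture-treatment costs accrue. Each choice is exposed
#' here as an explicit switch so the replication harness
#' ([replication_search()]) can explore the full space and report which
#' combination best reproduces the published results.
#'
#' @param schedule Screening/cycle schedule.
#'   `"fencepost"` (default): `horizon / cycle_length` transition cycles with
#'   a screening event at the start of each cycle and one final event at the
#'   horizon (six events for the two-year base case).
#'   `"closed"`: same cycles, no final event.
#'   `"extra_cycle"`: one additional transition cycle, each preceded by a
#'   screening event (the off-by-one reading of a stage-indexed cohort run).
#' @param rr_timing `"full_cycle"` applies the treatment relative risk to the
#'   whole cycle in which therapy starts; `"prorated"` composes a treated
#'   year and an untreated year inside a two-year cycle,
#'   `1 - (1 - p1*rr) * (1 - p1)` with `p1` the one-year converted risk.
#' @param counting `"persons"` counts each subject's first new fracture only;
#'   `"events"` counts every new fracture.
#' @param untreated_exit `"exit"`: any new fracture removes the subject from
#'   the at-risk population; `"stay"`: only subjects on therapy at diagnosis
#'   are removed, untreated subjects remain at risk.
#' @param unreadable_combined In the radiography-after-VFA strategy,
#'   `"exit"` (default) sends unreadable VFA patients to the absorbing
#'   VFA-impossible state exactly as in the VFA-only strategy;
#'   `"xray"` resolves them with an immediate confirmatory radiograph.
#' @param vf_cost Accrual rule for fracture-treatment costs.
#'   `"event"` (default): the all-in treatment cost is charged once per new
#'   fracture. `"event_plus_procedure"`: additionally charges the procedure
#'   cost times the symptomatic fraction `1 / (1 + asymptomatic_ratio)`.
#'   `"diagnosis"`: the all-in cost is charged once when a subject is first
#'   classified test-positive (true or false positive), and untreated new
#'   fractures are charged the procedure cost times the symptomatic fraction.
#' @param reconfirm_known Whether previously diagnosed subjects who re-screen
#'   positive in the radiography-after-VFA strategy receive a repeat
#'   confirmatory radiograph (`TRUE`) or restart therapy on the VFA result
#'   alone (`FALSE`).
#' @param confirm_dose `"conditional"` (default): radiograph dose accrues only
#'   for subjects actually sent to confirmation; `"flat625"`: every screened
#'   subject in the combined strategy receives the VFA-plus-radiograph dose,
#'   the literal per-protocol reading.
#'
#' @return An object of class `vf_conventions`.
#' @export
vf_conventions <- function(schedule = c("fencepost", "closed", "extra_cycle"),
                           rr_timing = c("full_cycle", "prorated"),
                           counting = c("persons", "events"),
                           untreated_exit = c("exit", "stay"),
                           unreadable_combined = c("exit", "xray"),
                           vf_cost = c("event", "event_plus_procedure", "diagnosis"),
                           reconfirm_known = TRUE,
                           confirm_dose = c("conditional", "flat625")) {
  conv <- list(
    schedule = match.arg(schedule),
    rr_timing = match.arg(rr_timing),
    counting = match.arg(counting),
    untreated_exit = match.arg(untreated_exit),
    unreadable_combined = match.arg(unreadable_combined),
    vf_cost = match.arg(vf_cost),
    reconfirm_known = isTRUE(reconfirm_known),
    confirm_dose = match.arg(confirm_dose)
  )
  class(conv) <- "vf_conventions"
  conv
}

#' @export
print.vf_conventions <- function(x, ...) {
  cat("<vf_conventions>\n")
  for (f in names(unclass(x))) cat(sprintf("  %-20s %s\n", f, x[[f]]))
  invisible(x)
}

#' Enumerate the convention space searched by the replication harness
#'
#' @param include_reconfirm Include the `reconfirm_known` switch (doubles the
#'   grid); it only affects the combined strategy's cost and dose.
#' @return A data frame with one row per convention combination, in a fixed,
#'   documented order (earlier rows win score ties).
#' @export
convention_grid <- function(include_reconfirm = TRUE) {
  grid <- expand.grid(
    schedule = c("fencepost", "closed", "extra_cycle"),
    rr_timing = c("full_cycle", "prorated"),
    counting = c("persons", "events"),
    untreated_exit = c("exit", "stay"),
    unreadable_combined = c("exit", "xray"),
    vf_cost = c("event", "event_plus_procedure", "diagnosis"),
    reconfirm_known = if (include_reconfirm) c(TRUE, FALSE) else TRUE,
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )
  grid
}

conventions_from_row <- function(row) {
  vf_conventions(
    schedule = row$schedule,
    rr_timing = row$rr_timing,
    counting = row$counting,
    untreated_exit = row$untreated_exit,
    unreadable_combined = row$unreadable_combined,
    vf_cost = row$vf_cost,
    reconfirm_known = row$reconfirm_known
  )
}
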