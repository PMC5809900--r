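w <- load_parameter_set(NULL, "female", "base_case")

test_that("the four strategies are enumerated and guarded", {
  expect_identical(vf_strategies(),
                   c("no_screening", "xray_after_vfa", "vfa_only", "xray_only"))
  expect_error(screen_profile("pet_scan", w), "unknown strategy")
})

test_that("radiography-only profile reflects the gold standard", {
  p <- screen_profile("xray_only", w)
  expect_equal(p$vf_new$p_treat, 1)
  expect_equal(p$novf$p_treat, 0)
  expect_equal(p$vf_new$p_unreadable, 0)
  expect_equal(p$vf_new$dose, 600)
  expect_equal(p$vf_new$cost, 24)
  expect_identical(p$vf_known, p$vf_new)
})

test_that("VFA-only profile applies unreadable-first then accuracy", {
  p <- screen_profile("vfa_only", w)
  expect_equal(p$vf_new$p_treat, 0.97 * 0.82)
  expect_equal(p$vf_new$p_unreadable, 0.03)
  expect_equal(p$novf$p_treat, 0.97 * 0.07)
  expect_equal(p$novf$p_unreadable, 0.03)
  expect_equal(p$vf_new$dose, 25)
  expect_equal(p$vf_new$cost, 17)
})

test_that("combined-strategy profile matches its unreadable convention", {
  # default: unreadables absorbed, exactly as in VFA-only
  p <- screen_profile("xray_after_vfa", w)
  conf_vf <- 0.97 * 0.82
  conf_no <- 0.97 * 0.07
  expect_equal(p$vf_new$p_treat, conf_vf)
  expect_equal(p$vf_new$p_unreadable, 0.03)
  expect_equal(p$vf_new$dose, 25 + conf_vf * 600)
  expect_equal(p$novf$dose, 25 + conf_no * 600)
  expect_equal(p$novf$cost, 17 + conf_no * 24)

  # alternative: unreadables resolved by an immediate radiograph
  px <- screen_profile("xray_after_vfa", w,
                       vf_conventions(unreadable_combined = "xray"))
  expect_equal(px$vf_new$p_unreadable, 0)
  expect_equal(px$vf_new$p_treat, conf_vf + 0.03)
  expect_equal(px$novf$dose, 25 + (conf_no + 0.03) * 600)
  expect_equal(px$novf$dose, 83.74)
})

test_that("flat per-protocol dose and known-fracture shortcuts are honoured", {
  pf <- screen_profile("xray_after_vfa", w,
                       vf_conventions(confirm_dose = "flat625"))
  expect_equal(pf$novf$dose, 625)
  expect_equal(pf$vf_new$dose, 625)

  pk <- screen_profile("xray_after_vfa", w,
                       vf_conventions(reconfirm_known = FALSE))
  expect_equal(pk$vf_known$p_treat, 0.97 * 0.82 + 0.03)
  expect_equal(pk$vf_known$p_unreadable, 0)
  expect_equal(pk$vf_known$cost, 17)
  expect_equal(pk$vf_known$dose, 25)
  # default: known fractures are re-confirmed like new ones
  pd <- screen_profile("xray_after_vfa", w)
  expect_identical(pd$vf_known, pd$vf_new)
})

test_that("no-screening profile is inert", {
  p <- screen_profile("no_screening", w)
  for (a in c("novf", "vf_new", "vf_known")) {
    expect_equal(p[[a]]$p_treat, 0)
    expect_equal(p[[a]]$cost, 0)
    expect_equal(p[[a]]$dose, 0)
  }
  occ <- initial_occupancy(w)
  res <- apply_screen(p, occ, w)
  expect_identical(res$occupancy, occ)
  expect_equal(res$cost, 0)
  expect_equal(res$dose, 0)
  expect_equal(res$n_screened, 0)
})

test_that("applying a screen conserves mass exactly", {
  occ <- initial_occupancy(w)
  for (s in vf_strategies()) {
    for (conv in list(vf_conventions(),
                      vf_conventions(unreadable_combined = "xray",
                                     reconfirm_known = FALSE,
                                     vf_cost = "diagnosis"))) {
      res <- apply_screen(screen_profile(s, w, conv), occ, w, conv)
      expect_equal(sum(res$occupancy), 1, tolerance = 1e-12)
      expect_true(all(res$occupancy >= 0))
    }
  }
})

test_that("a perfect test classifies a half/half cohort exactly", {
  occ <- empty_occupancy()
  occ["NOVF.u"] <- 0.5
  occ["PREV.u"] <- 0.5
  res <- apply_screen(screen_profile("xray_only", w), occ, w)
  expect_equal(res$occupancy[["PREV.t"]], 0.5)
  expect_equal(res$occupancy[["PREV.u"]], 0)
  expect_equal(res$occupancy[["NOVF.u"]], 0.5)
  expect_equal(res$n_screened, 1)
  expect_equal(res$dose, 600)  # everyone radiographed
  therapy_unit <- w$cost_drug_year + w$cost_physician_visit
  expect_equal(res$cost, 24 + 0.5 * therapy_unit)
})

test_that("diagnosis-mode accrual charges treatment cost at classification", {
  occ <- empty_occupancy()
  occ["NOVF.u"] <- 0.5
  occ["PREV.u"] <- 0.5
  conv <- vf_conventions(vf_cost = "diagnosis")
  prof <- screen_profile("xray_only", w, conv)
  base <- apply_screen(prof, occ, w, vf_conventions())
  dx <- apply_screen(prof, occ, w, conv)
  # the 0.5 newly classified prevalent fractures carry the all-in cost;
  # the specificity-1 radiograph produces no false positives to charge
  expect_equal(dx$cost - base$cost, 0.5 * w$cost_vf_treatment)
})

test_that("treated and unreadable mass land in the right strata", {
  occ <- empty_occupancy()
  occ["PREV.u"] <- 1
  res <- apply_screen(screen_profile("vfa_only", w), occ, w)
  expect_equal(res$occupancy[["PREV.t"]], 0.97 * 0.82)
  expect_equal(res$occupancy[["PREV.i"]], 0.03)
  expect_equal(res$occupancy[["PREV.u"]], 1 - 0.97 * 0.82 - 0.03)
  # false positives without a fracture keep their stratum but pay therapy
  occ2 <- empty_occupancy()
  occ2["NOVF.u"] <- 1
  res2 <- apply_screen(screen_profile("vfa_only", w), occ2, w)
  expect_equal(res2$occupancy[["NOVF.u"]], 0.97)
  expect_equal(res2$occupancy[["NOVF.i"]], 0.03)
  therapy_unit <- w$cost_drug_year + w$cost_physician_visit
  expect_equal(res2$cost, 17 + 0.97 * 0.07 * therapy_unit)
})
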