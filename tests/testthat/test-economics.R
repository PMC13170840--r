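test_that("drug cost amortizes the dose price over the dosing interval", {
  p <- fixture_params()
  expect_equal(drug_cost_per_cycle(p$arms$mepolizumab, p$econ), 341.01)
  expect_identical(drug_cost_per_cycle(p$arms$placebo, p$econ), 0)
  weekly <- p$arms$mepolizumab
  weekly$dosing_interval_cycles <- 1L
  expect_equal(drug_cost_per_cycle(weekly, p$econ), 682.02)
})

test_that("per-cycle adverse-event cost reproduces the published per-arm
           figures on the fixture tables", {
  p <- fixture_params()
  expect_equal(ae_cost_per_cycle(p$arms$mepolizumab, 26), 33.54,
               tolerance = 1e-9)
  expect_equal(ae_cost_per_cycle(p$arms$placebo, 26), 39.56,
               tolerance = 1e-9)
  bare <- arm_profile("bare", 0.5)
  expect_identical(ae_cost_per_cycle(bare, 26), 0)
})

test_that("adverse-event disutility is the frequency-weighted sum per cycle", {
  one <- arm_profile("one", 0.5, ae_profile = data.frame(
    name = "x", trial_incidence = 0.4, cost_per_event = 10,
    disutility = 0.05))
  expect_equal(ae_disutility_per_cycle(one, 26), 0.4 * 0.05 / 26,
               tolerance = 1e-12)
  expect_identical(ae_disutility_per_cycle(arm_profile("none", 1), 26), 0)
  p <- fixture_params()
  expect_lt(ae_disutility_per_cycle(p$arms$mepolizumab, 26),
            ae_disutility_per_cycle(p$arms$placebo, 26))
})

test_that("indirect costs follow the human-capital arithmetic", {
  econ <- economic_inputs(
    drug_unit_price = 0, monitoring_cost_per_cycle = 0,
    cse_cost_by_substate = list(ocs = 0, hosp_ed = 0, hosp = 0),
    daily_wage = 50,
    employment_rate_by_age = data.frame(age_low = c(16, 65),
                                        age_high = c(65, 120),
                                        rate = c(1, 0)),
    presenteeism_days = 0)
  expect_equal(indirect_cost_per_cse("CSE_OCS", 50, econ), 1 * 50)
  expect_equal(indirect_cost_per_cse("CSE_HOSP", 50, econ), 6.4 * 50)
  expect_equal(indirect_cost_per_cse("CSE_HOSP_ED", 50, econ), 6.4 * 50)
  # past the employment horizon nothing is lost
  expect_identical(indirect_cost_per_cse("CSE_HOSP", 80, econ), 0)
  expect_error(indirect_cost_per_cse("NO_CSE", 50, econ),
               "exacerbation substates")
})

test_that("cycle rewards decompose as drug + monitoring + AE with substate
           add-ons, and utilities subtract decrements", {
  p <- fixture_params()
  r <- build_cycle_rewards(p$arms$placebo, 55, p)
  expect_equal(r$cost_by_state[["NO_CSE"]],
               p$econ$monitoring_cost_per_cycle +
                 ae_cost_per_cycle(p$arms$placebo, 26), tolerance = 1e-9)
  expect_gt(r$cost_by_state[["CSE_HOSP"]], r$cost_by_state[["CSE_OCS"]])
  expect_identical(r$cost_by_state[["DEATH"]], 0)
  expect_identical(r$utility_by_state[["DEATH"]], 0)
  ae_du <- ae_disutility_per_cycle(p$arms$placebo, 26)
  expect_equal(r$utility_by_state[["NO_CSE"]], 0.84 - ae_du,
               tolerance = 1e-12)
  expect_equal(r$utility_by_state[["CSE_HOSP"]],
               0.84 - p$util$disutility_by_substate$hosp - ae_du,
               tolerance = 1e-12)

  flat <- closed_form_params(u = 0.9, years = 1)
  r2 <- build_cycle_rewards(flat$arms$placebo, 52.5, flat)
  alive <- setdiff(health_states(), "DEATH")
  expect_equal(unname(r2$utility_by_state[alive]), rep(0.9, 4))
})

test_that("drug cost accrues only inside the treatment window", {
  p <- fixture_params()
  early <- build_cycle_rewards(p$arms$mepolizumab, 52.3, p)
  late <- build_cycle_rewards(p$arms$mepolizumab, 60, p)
  expect_equal(early$cost_by_state[["NO_CSE"]] -
                 late$cost_by_state[["NO_CSE"]], 341.01, tolerance = 1e-9)
})

test_that("ICER classification covers every sign combination of the
           incremental quantities", {
  r <- ce_result(399.17, 0, 0.47028, 0)
  expect_equal(r$icer, 848.79, tolerance = 0.01)
  expect_identical(r$classification, "icer")

  cases <- list(
    list(dc = -10, de = 0.1, class = "dominant", icer_na = TRUE),
    list(dc = 10, de = -0.1, class = "dominated", icer_na = TRUE),
    list(dc = 10, de = 0.1, class = "icer", icer_na = FALSE),
    list(dc = -10, de = -0.1, class = "icer", icer_na = FALSE),
    list(dc = 0, de = 0.1, class = "icer", icer_na = FALSE),
    list(dc = 0, de = -0.1, class = "dominated", icer_na = TRUE),
    list(dc = 10, de = 0, class = "dominated", icer_na = TRUE),
    list(dc = -10, de = 0, class = "dominant", icer_na = TRUE),
    list(dc = 0, de = 0, class = "equivalent", icer_na = TRUE)
  )
  for (cs in cases) {
    r <- ce_result(cs$dc, 0, cs$de, 0)
    expect_identical(r$classification, cs$class)
    expect_identical(is.na(r$icer), cs$icer_na)
    if (!cs$icer_na && cs$de != 0) {
      expect_equal(r$icer, cs$dc / cs$de, tolerance = 1e-12)
    }
  }
})

test_that("net monetary benefit is zero at the ICER, positive below-threshold
           costs, negative at zero willingness to pay", {
  r <- ce_result(399.17, 0, 0.47028, 0)
  expect_equal(net_monetary_benefit(r, r$icer), 0, tolerance = 1e-6)
  expect_gt(net_monetary_benefit(r, 15217), 0)
  expect_lt(net_monetary_benefit(r, 0), 0)
  expect_error(net_monetary_benefit(r, -5), "non-negative")
})

test_that("arm totals equal the sum of the exported component ledgers", {
  p <- fixture_params()
  res <- run_base_case(p)
  comp <- cost_composition(res)
  for (arm in unique(comp$arm)) {
    total <- if (arm == res$arm_a) res$cost_a else res$cost_b
    expect_equal(sum(comp$discounted_total[comp$arm == arm]), total,
                 tolerance = 1e-6)
  }
  f <- tempfile(fileext = ".csv")
  cost_composition(res, f)
  expect_equal(nrow(read.csv(f)), 10L)
})

test_that("raising the drug price raises intervention cost and the ICER;
           raising the comparator exacerbation rate lowers the ICER", {
  p <- fixture_params()
  base <- run_base_case(p)
  up <- run_base_case(set_parameter(p, "econ.drug_unit_price",
                                    682.02 * 1.2))
  expect_gt(up$cost_a, base$cost_a)
  expect_gt(up$icer, base$icer)

  worse <- run_base_case(set_parameter(p, "arms.placebo.annual_cse_rate",
                                       1.31 * 1.2))
  expect_lte(worse$delta_cost / worse$delta_qaly,
             base$delta_cost / base$delta_qaly)
})
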