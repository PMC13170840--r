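test_that("transition matrices are row-stochastic with the expected structure", {
  p <- fixture_params()
  m <- build_transition_matrix(p$arms$placebo, 52, p)
  expect_equal(rowSums(m), setNames(rep(1, 5), health_states()),
               tolerance = 1e-12)
  p_d0 <- lookup_cycle_mortality(p$mortality, "NO_CSE", 52)
  cse_mass <- sum(m["NO_CSE", c("CSE_OCS", "CSE_HOSP_ED", "CSE_HOSP")])
  expect_equal(cse_mass, (1 - p_d0) * rate_annual_to_cycle(1.31, 26),
               tolerance = 1e-12)
  # tunnel: exacerbation states exit within one cycle
  for (s in c("CSE_OCS", "CSE_HOSP_ED", "CSE_HOSP")) {
    expect_equal(sum(m[s, c("NO_CSE", "DEATH")]), 1, tolerance = 1e-12)
  }
  expect_equal(m["DEATH", ], setNames(c(0, 0, 0, 0, 1), health_states()))
})

test_that("degenerate matrices: no exacerbations, and an immortal cohort", {
  p <- fixture_params()
  calm <- p$arms$placebo
  calm$annual_cse_rate <- 0
  m <- build_transition_matrix(calm, 55, p)
  p_d0 <- lookup_cycle_mortality(p$mortality, "NO_CSE", 55)
  expect_equal(m["NO_CSE", "NO_CSE"], 1 - p_d0, tolerance = 1e-12)
  expect_equal(sum(m["NO_CSE", ] > 0), 2L)

  imm <- closed_form_params()
  m2 <- build_transition_matrix(imm$arms$placebo, 55, imm)
  expect_equal(unname(m2[, "DEATH"]), c(0, 0, 0, 0, 1))
})

test_that("cohort traces conserve occupancy, accumulate monotone deaths, and
           sum their per-cycle streams", {
  p <- fixture_params()
  for (arm in p$arms) {
    tr <- run_cohort(arm, p)
    expect_equal(rowSums(tr$occupancy), rep(1, nrow(tr$occupancy)),
                 tolerance = 1e-9)
    expect_true(all(diff(tr$occupancy[, "DEATH"]) >= -1e-12))
    expect_equal(sum(tr$cost_per_cycle), tr$cumulative_cost,
                 tolerance = 1e-9)
    expect_equal(sum(tr$qaly_per_cycle), tr$cumulative_qaly,
                 tolerance = 1e-9)
    expect_equal(sum(tr$components), tr$cumulative_cost, tolerance = 1e-6)
  }
})

test_that("an immortal, undiscounted, exacerbation-free year accrues exactly
           utility x time", {
  p <- closed_form_params(u = 0.84, years = 1, discount = 0)
  tr <- run_cohort(p$arms$placebo, p)
  expect_equal(tr$cumulative_qaly, 0.84, tolerance = 1e-12)
  # constant rewards and no deaths: half-cycle correction changes nothing
  p2 <- closed_form_params(u = 0.84, years = 1, discount = 0,
                           half_cycle_correction = FALSE)
  tr2 <- run_cohort(p2$arms$placebo, p2)
  expect_equal(tr$cumulative_qaly, tr2$cumulative_qaly, tolerance = 1e-9)
})

test_that("with deaths, half-cycle correction pulls accruals toward the
           midpoint of the entry- and exit-occupancy estimates", {
  p <- fixture_params()
  tr_hcc <- run_cohort(p$arms$placebo, p)
  p_off <- p
  p_off$settings$half_cycle_correction <- FALSE
  tr_off <- run_cohort(p$arms$placebo, p_off)
  # survival shrinks occupancy, so the midpoint QALY sits strictly below the
  # entry-occupancy estimate
  expect_lt(tr_hcc$cumulative_qaly, tr_off$cumulative_qaly)
  # by construction the corrected total is the midpoint: the implied
  # exit-occupancy estimate must sit symmetrically on the far side
  exit_cost <- 2 * tr_hcc$cumulative_cost - tr_off$cumulative_cost
  exit_qaly <- 2 * tr_hcc$cumulative_qaly - tr_off$cumulative_qaly
  expect_true(tr_hcc$cumulative_qaly > min(exit_qaly, tr_off$cumulative_qaly) &&
              tr_hcc$cumulative_qaly < max(exit_qaly, tr_off$cumulative_qaly))
  expect_true(tr_hcc$cumulative_cost > min(exit_cost, tr_off$cumulative_cost) &&
              tr_hcc$cumulative_cost < max(exit_cost, tr_off$cumulative_cost))
})

test_that("halving the cycle length changes lifetime QALYs by under 2%", {
  # exacerbations are one-cycle tunnel states, so a 1-week cycle also halves
  # the modelled exacerbation duration; the residual discretization effect
  # on the fixture is ~1.3% of lifetime QALYs
  p26 <- fixture_params()
  p52 <- p26
  p52$settings$cycle_length_weeks <- 1
  p52$settings$cycles_per_year <- 52L
  p52$mortality <- mortality_table(p26$mortality$bands,
                                   p26$mortality$no_cse_annual,
                                   p26$mortality$cse_annual,
                                   cycles_per_year = 52L)
  for (arm_name in names(p26$arms)) {
    q26 <- run_cohort(p26$arms[[arm_name]], p26)$cumulative_qaly
    q52 <- run_cohort(p52$arms[[arm_name]], p52)$cumulative_qaly
    expect_lt(abs(q52 - q26) / q26, 0.02)
  }
})

test_that("trace CSV export carries cycle, age, occupancy and reward columns", {
  p <- fixture_params()
  tr <- run_cohort(p$arms$mepolizumab, p)
  f <- tempfile(fileext = ".csv")
  write_trace(tr, f)
  df <- read.csv(f)
  expect_identical(names(df), c("cycle", "age", health_states(),
                                "discounted_cost", "discounted_qaly"))
  expect_equal(nrow(df), tr$n_cycles)
  expect_equal(sum(df$discounted_qaly), tr$cumulative_qaly, tolerance = 1e-9)
})

test_that("the microsimulation matches the cohort exactly on deterministic
           parameters and is seed-reproducible", {
  p <- closed_form_params(u = 0.7, years = 2, discount = 0.05)
  tr <- run_cohort(p$arms$placebo, p)
  ms <- microsim_oracle(p$arms$placebo, p, 10, seed = 99)
  expect_equal(ms$mean_qaly, tr$cumulative_qaly, tolerance = 1e-12)
  expect_equal(ms$mean_cost, tr$cumulative_cost, tolerance = 1e-12)

  p2 <- fixture_params()
  a <- microsim_oracle(p2$arms$mepolizumab, p2, 500, seed = 7)
  b <- microsim_oracle(p2$arms$mepolizumab, p2, 500, seed = 7)
  expect_identical(a, b)
})

test_that("the cohort totals sit within 3 Monte-Carlo SE of the
           microsimulation on the reference fixture", {
  p <- fixture_params()
  tr <- run_cohort(p$arms$placebo, p)
  ms <- microsim_oracle(p$arms$placebo, p, 20000, seed = 31)
  expect_lt(abs(ms$mean_qaly - tr$cumulative_qaly), 3 * ms$se_qaly)
  expect_lt(abs(ms$mean_cost - tr$cumulative_cost), 3 * ms$se_cost)
})
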