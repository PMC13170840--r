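# shared test fixtures, built in code

fixture_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- suppressMessages(reference_fixture()$parameters)
    cache
  }
})

# an immortal, undiscounted, exacerbation-free one-year model whose
# lifetime QALYs have the closed form utility * years
closed_form_params <- function(u = 0.84, years = 1, discount = 0,
                               half_cycle_correction = TRUE) {
  settings <- model_settings(annual_discount_rate = discount,
                             start_age = 52.2, max_age = 52.2 + years,
                             half_cycle_correction = half_cycle_correction)
  arms <- list(
    mepolizumab = arm_profile("mepolizumab", annual_cse_rate = 0,
                              drug_dose_mg = 100,
                              treatment_duration_years = 1),
    placebo = arm_profile("placebo", annual_cse_rate = 0)
  )
  zero_mort <- mortality_table(
    bands = data.frame(age_low = 0, age_high = 200),
    no_cse_annual = 0, cse_annual = 0)
  model_parameters(
    settings, arms,
    cse_split(0.6, 0.25, 0.15),
    economic_inputs(
      drug_unit_price = 0, monitoring_cost_per_cycle = 0,
      cse_cost_by_substate = list(ocs = 0, hosp_ed = 0, hosp = 0),
      daily_wage = 0,
      employment_rate_by_age = data.frame(age_low = 0, age_high = 200,
                                          rate = 0)),
    utility_inputs(u, list(ocs = 0, hosp_ed = 0, hosp = 0)),
    zero_mort
  )
}
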