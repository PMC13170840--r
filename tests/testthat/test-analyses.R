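test_that("the fixture base case yields extra cost, extra QALYs and an ICER
           below the willingness-to-pay band", {
  p <- fixture_params()
  res <- run_base_case(p)
  expect_identical(res$classification, "icer")
  expect_gt(res$delta_cost, 0)
  expect_gt(res$delta_qaly, 0)
  expect_lt(res$icer, p$settings$wtp_lower)
})

test_that("identical arms produce a flagged zero-increment comparison", {
  p <- closed_form_params()
  p$arms$mepolizumab <- p$arms$placebo
  p$arms$mepolizumab$name <- "mepolizumab"
  res <- run_base_case(p)
  expect_equal(res$delta_cost, 0, tolerance = 1e-9)
  expect_equal(res$delta_qaly, 0, tolerance = 1e-9)
  expect_true(is.na(res$icer))
  expect_identical(res$classification, "equivalent")
})

test_that("a subgroup at the base-case rate ratio reproduces the base case
           and a unit rate ratio equalises the exacerbation rates", {
  p <- fixture_params()
  base <- run_base_case(p)
  base_rr <- 0.45 / 1.31
  p$subgroups <- subgroup_spec(c("base", "null"), c(base_rr, 1),
                               c(base_rr, 1), c(base_rr, 1))
  sg <- run_subgroups(p)
  expect_equal(sg$delta_cost[1], base$delta_cost, tolerance = 1e-9)
  expect_equal(sg$delta_qaly[1], base$delta_qaly, tolerance = 1e-9)

  # rr = 1: any effectiveness gap is driven by the AE profiles alone
  null_res <- attr(sg, "results")[[2]]
  expect_equal(null_res$delta_components[["cse_management"]], 0,
               tolerance = 1e-6)
  expect_equal(null_res$delta_components[["indirect"]], 0, tolerance = 1e-6)
  expect_error(run_subgroups(model_parameters(
    p$settings, p$arms, p$split, p$econ, p$util, p$mortality)),
    "no subgroups")
})

test_that("fixture subgroups span dominant and below-threshold ICER outcomes", {
  p <- fixture_params()
  sg <- run_subgroups(p)
  expect_identical(nrow(sg), nrow(p$subgroups))
  expect_true(any(sg$classification == "dominant"))
  with_icer <- sg$icer[sg$classification == "icer"]
  expect_true(all(with_icer < p$settings$wtp_lower))
  # lower rate ratios can only help the intervention
  ord <- order(sg$rr)
  nmb <- p$settings$wtp_lower * sg$delta_qaly - sg$delta_cost
  expect_true(all(diff(nmb[ord]) <= 1e-6))
})

test_that("the tornado restores the base case, orders by spread, zeroes
           uninfluential parameters and moves with the drug price", {
  p <- fixture_params()
  base <- run_base_case(p)
  dsa <- run_dsa(p)
  expect_true(all(diff(dsa$spread) <= 1e-9))
  expect_identical(
    dsa$spread[dsa$parameter == "econ.exchange_rate_cny_per_usd"], 0)
  price <- dsa[dsa$parameter == "econ.drug_unit_price", ]
  # a cheaper drug can turn the comparison dominant (ICER undefined), so
  # compare the ordering values, which extend the ICER through dominance
  expect_gt(price$value_high, price$value_low)
  # base case untouched after all perturbations
  base2 <- run_base_case(p)
  expect_equal(base2$delta_cost, base$delta_cost, tolerance = 1e-12)
  expect_equal(base2$delta_qaly, base$delta_qaly, tolerance = 1e-12)
})

test_that("DSA ranges leaving a parameter's domain are clamped with a warning", {
  p <- fixture_params()
  p$dsa_ranges <- list("util.u_no_cse" = c(0.9, 1.2))
  expect_warning(dsa <- run_dsa(p), "clamped")
  expect_identical(nrow(dsa), 1L)
})

test_that("a PSA with point-collapsed distributions reproduces the base case
           in every iteration", {
  p <- fixture_params()
  base <- run_base_case(p)
  p$psa_specs <- lapply(names(p$psa_specs), function(pa)
    dist_spec("fixed", c(value = get_parameter(p, pa))))
  names(p$psa_specs) <- names(fixture_params()$psa_specs)
  psa <- run_psa(p, n = 3, seed = 5)
  expect_equal(psa$draws$delta_cost, rep(base$delta_cost, 3),
               tolerance = 1e-9)
  expect_equal(psa$draws$delta_qaly, rep(base$delta_qaly, 3),
               tolerance = 1e-9)
})

test_that("PSA draws are seed-reproducible and per-parameter streams are
           unaffected by adding another parameter", {
  p <- fixture_params()
  a <- run_psa(p, n = 20, seed = 123)
  b <- run_psa(p, n = 20, seed = 123)
  expect_identical(a$draws, b$draws)
  expect_identical(a$parameter_draws, b$parameter_draws)

  fewer <- p
  fewer$psa_specs <- p$psa_specs[1:4]
  c_ <- run_psa(fewer, n = 20, seed = 123)
  shared <- names(fewer$psa_specs)
  expect_identical(a$parameter_draws[, shared], c_$parameter_draws[, shared])
})

test_that("with distributions centred on the point estimates the PSA mean
           effect matches the base case within Monte-Carlo error", {
  p <- fixture_params()
  base <- run_base_case(p)
  p$psa_specs <- lapply(names(p$psa_specs), function(pa)
    default_dist_spec(get_parameter(p, pa), "symmetric", cv = 0.05))
  names(p$psa_specs) <- names(fixture_params()$psa_specs)
  psa <- run_psa(p, n = 200, seed = 9)
  se <- sd(psa$draws$delta_qaly) / sqrt(psa$n_iterations)
  expect_lt(abs(mean(psa$draws$delta_qaly) - base$delta_qaly), 3 * se)
})

test_that("the acceptability curve starts at the cost-saving fraction, is
           non-decreasing under uniformly positive effects, and reaches 1", {
  p <- fixture_params()
  psa <- run_psa(p, n = 100, seed = 77)
  cc <- ceac(psa, wtp_grid = seq(0, 45000, by = 1500))
  expect_equal(cc$prob_cost_effective[1], mean(psa$draws$delta_cost < 0))
  if (all(psa$draws$delta_qaly > 0)) {
    expect_true(all(diff(cc$prob_cost_effective) >= 0))
  }
  expect_equal(ceac(psa, wtp_grid = 1e9)$prob_cost_effective,
               mean(psa$draws$delta_qaly > 0))
  expect_error(ceac(psa, wtp_grid = numeric()), "non-empty")
})
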