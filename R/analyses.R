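#' @title Base-case, subgroup, deterministic and probabilistic analyses
#' @description Orchestration of the full evaluation: the base-case
#'   comparison, subgroup comparisons driven by exacerbation rate ratios,
#'   one-at-a-time deterministic sensitivity analysis (tornado), and the
#'   probabilistic sensitivity analysis with its cost-effectiveness
#'   acceptability curve.
#' @name analyses
NULL

# intervention first, comparator second
arm_pair <- function(params) {
  nms <- names(params$arms)
  if (all(c("mepolizumab", "placebo") %in% nms)) {
    list(a = params$arms$mepolizumab, b = params$arms$placebo)
  } else {
    list(a = params$arms[[1]], b = params$arms[[2]])
  }
}

#' Run the base-case comparison
#'
#' Runs both arms through the cohort engine and compares them.  The result
#' carries the per-arm cost-component breakdown.
#'
#' @param params A `cea_parameters` object.
#' @return A `ce_result`.
#' @export
run_base_case <- function(params) {
  p <- arm_pair(params)
  ce_compare(run_cohort(p$a, params), run_cohort(p$b, params))
}

#' Run subgroup comparisons
#'
#' A uniform comparator exacerbation rate is kept in every subgroup; the
#' intervention arm's annual rate is the comparator rate multiplied by the
#' subgroup's rate ratio.  All other parameters are shared.
#'
#' @param params A `cea_parameters` object with a non-empty `subgroups`
#'   table.
#' @return Data frame with one row per subgroup (`name`, `rr`,
#'   `delta_cost`, `delta_qaly`, `icer`, `classification`); the full
#'   `ce_result` objects are attached as the `"results"` attribute.
#' @export
run_subgroups <- function(params) {
  sg <- params$subgroups
  if (!nrow(sg)) stop("no subgroups defined", call. = FALSE)
  if (any(sg$rr <= 0)) stop("subgroup rate ratios must be positive",
                            call. = FALSE)
  p <- arm_pair(params)
  base_placebo <- p$b$annual_cse_rate
  results <- vector("list", nrow(sg))
  for (i in seq_len(nrow(sg))) {
    pi <- params
    pi$arms[[p$a$name]]$annual_cse_rate <- base_placebo * sg$rr[i]
    results[[i]] <- run_base_case(pi)
  }
  out <- data.frame(
    name = sg$name, rr = sg$rr,
    delta_cost = vapply(results, `[[`, numeric(1), "delta_cost"),
    delta_qaly = vapply(results, `[[`, numeric(1), "delta_qaly"),
    icer = vapply(results, `[[`, numeric(1), "icer"),
    classification = vapply(results, `[[`, character(1), "classification"),
    stringsAsFactors = FALSE
  )
  attr(out, "results") <- results
  out
}

# clamp a perturbed value into its natural domain, warning when it fires
domain_clamp <- function(path, value) {
  unit <- grepl(
    "u_no_cse|trial_incidence|^split\\.|employment_rate_by_age\\.rate|annual$|_annual\\.",
    path)
  lo <- 0
  hi <- if (unit) 1 else Inf
  if (value < lo || value > hi) {
    warning("DSA range for '", path, "' leaves its domain; clamped",
            call. = FALSE)
    value <- min(max(value, lo), hi)
  }
  value
}

#' One-at-a-time deterministic sensitivity analysis (tornado)
#'
#' Perturbs each annotated parameter to the low and high end of its range,
#' re-runs the comparison, and restores the base case between entries
#' (verified by re-running the base case at the end).  Dominant or
#' dominated outcomes carry no ICER; for ordering, every entry also records
#' the raw incremental cost-effectiveness ratio `value_low`/`value_high`
#' (negative under dominance) and the tornado is sorted by the absolute
#' spread between them.
#'
#' @param params A `cea_parameters` object with non-empty `dsa_ranges`.
#' @return Data frame sorted by decreasing `spread`, with columns
#'   `parameter`, `low`, `high`, `icer_at_low`, `icer_at_high`,
#'   `class_low`, `class_high`, `value_low`, `value_high`, `spread`.
#' @export
run_dsa <- function(params) {
  rng <- params$dsa_ranges
  if (!length(rng)) stop("no DSA ranges defined", call. = FALSE)
  base <- run_base_case(params)

  one <- function(path, value) {
    value <- domain_clamp(path, value)
    res <- run_base_case(set_parameter(params, path, value))
    list(icer = res$icer,
         class = res$classification,
         value = if (res$delta_qaly != 0) res$delta_cost / res$delta_qaly
                 else NA_real_)
  }
  rows <- lapply(names(rng), function(path) {
    lo <- one(path, rng[[path]][1])
    hi <- one(path, rng[[path]][2])
    data.frame(parameter = path, low = rng[[path]][1], high = rng[[path]][2],
               icer_at_low = lo$icer, icer_at_high = hi$icer,
               class_low = lo$class, class_high = hi$class,
               value_low = lo$value, value_high = hi$value,
               spread = abs(hi$value - lo$value),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)

  # paranoid restore check: the base case must be untouched
  base2 <- run_base_case(params)
  if (abs(base2$delta_cost - base$delta_cost) > 1e-9 ||
      abs(base2$delta_qaly - base$delta_qaly) > 1e-9) {
    stop("base case not restored after DSA perturbations", call. = FALSE)
  }
  out <- out[order(-out$spread), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base") <- base
  out
}

# deterministic per-parameter seed: a stable string hash combined with the
# master seed so adding a parameter never reshuffles the others' draws
param_seed <- function(master, path) {
  h <- 0
  for (cc in utf8ToInt(path)) h <- (h * 31 + cc) %% 2147483647
  as.integer((h + (master %% 2147483647) * 1000003) %% 2147483647)
}

#' Probabilistic sensitivity analysis
#'
#' Draws every annotated parameter from its distribution, re-runs both
#' arms, and records the incremental cost and QALY pair per iteration.
#' Each parameter has its own random stream derived from the master seed,
#' so runs are reproducible and adding a parameter does not change other
#' parameters' draws.  Draws that leave a parameter's natural domain
#' (e.g. a utility above 1) are re-drawn, up to 100 rounds.
#'
#' @param params A `cea_parameters` object with non-empty `psa_specs`.
#' @param n Number of Monte Carlo iterations.
#' @param seed Master seed.
#' @return A list of class `psa_result` with `draws` (data frame
#'   `delta_cost`, `delta_qaly`), `parameter_draws` (iterations x
#'   parameters matrix of sampled values), `n_iterations`, `seed`.
#' @export
run_psa <- function(params, n = 10000L, seed = 1L) {
  specs <- params$psa_specs
  if (!length(specs)) stop("no PSA specifications defined", call. = FALSE)
  stopifnot(n >= 1)
  paths <- names(specs)

  draw_one <- function(path) {
    set.seed(param_seed(seed, path))
    x <- dist_sample(specs[[path]], n)
    unit <- grepl(
      "u_no_cse|trial_incidence|^split\\.|employment_rate_by_age\\.rate|annual$|_annual\\.",
      path)
    if (unit) {
      for (attempt in seq_len(100)) {
        bad <- x < 0 | x > 1
        if (!any(bad)) break
        x[bad] <- dist_sample(specs[[path]], sum(bad))
      }
      if (any(x < 0 | x > 1)) {
        stop("could not draw '", path, "' inside [0, 1] after 100 attempts",
             call. = FALSE)
      }
    }
    x
  }
  draws_in <- vapply(paths, draw_one, numeric(n))
  if (n == 1L) draws_in <- matrix(draws_in, nrow = 1,
                                  dimnames = list(NULL, paths))

  dc <- numeric(n)
  de <- numeric(n)
  for (i in seq_len(n)) {
    pi <- params
    for (j in seq_along(paths)) {
      pi <- set_parameter(pi, paths[j], draws_in[i, j])
    }
    res <- run_base_case(pi)
    dc[i] <- res$delta_cost
    de[i] <- res$delta_qaly
  }
  out <- list(draws = data.frame(delta_cost = dc, delta_qaly = de),
              parameter_draws = draws_in,
              n_iterations = as.integer(n), seed = as.integer(seed))
  class(out) <- "psa_result"
  out
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA draws with positive incremental net monetary benefit at
#' each willingness-to-pay threshold.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Thresholds, money per QALY; default 0 to 45,000 in
#'   steps of 500.
#' @return Data frame of class `ceac` with `wtp`, `prob_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 45000, by = 500)) {
  if (!length(wtp_grid)) stop("`wtp_grid` must be non-empty", call. = FALSE)
  dc <- psa$draws$delta_cost
  de <- psa$draws$delta_qaly
  prob <- vapply(wtp_grid, function(w) mean(w * de - dc > 0), numeric(1))
  out <- data.frame(wtp = wtp_grid, prob_cost_effective = prob)
  class(out) <- c("ceac", "data.frame")
  out
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations (seed %d)\n", x$n_iterations,
              x$seed))
  cat(sprintf("  mean delta cost  $%.2f\n", mean(x$draws$delta_cost)))
  cat(sprintf("  mean delta QALYs %.5f\n", mean(x$draws$delta_qaly)))
  invisible(x)
}
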