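#' @title Model parameter containers
#' @description Constructors and validation for the complete parameter set
#'   driving one model run: arm profiles, the exacerbation substate split,
#'   economic and utility inputs, the mortality table, subgroup rate ratios
#'   and the sensitivity-analysis annotations (DSA ranges and PSA
#'   distributions).  All money is held internally in US dollars; values
#'   supplied in Chinese yuan are converted at the fixed exchange rate.
#' @name parameters
NULL

CSE_SUBSTATES <- c("ocs", "hosp_ed", "hosp")

#' Model settings
#'
#' Global settings of the cohort simulation: cycle structure, discounting,
#' cohort starting age, terminal age and the willingness-to-pay band.
#'
#' @param cycle_length_weeks Cycle length in weeks (2 by default).
#' @param cycles_per_year Cycles per model year (26 by default).
#' @param annual_discount_rate Annual discount rate for costs and QALYs.
#' @param start_age Cohort age at model entry, in years.
#' @param max_age Terminal age: the remaining cohort is censored here.
#' @param wtp_lower,wtp_upper Willingness-to-pay band, money per QALY.
#' @param half_cycle_correction Apply trapezoidal half-cycle correction.
#' @return A list of class `model_settings`.
#' @export
model_settings <- function(cycle_length_weeks = 2,
                           cycles_per_year = 26L,
                           annual_discount_rate = 0.05,
                           start_age = 52.2,
                           max_age = 100,
                           wtp_lower = 15217,
                           wtp_upper = 38042,
                           half_cycle_correction = TRUE) {
  s <- list(
    cycle_length_weeks = cycle_length_weeks,
    cycles_per_year = as.integer(cycles_per_year),
    annual_discount_rate = annual_discount_rate,
    start_age = start_age,
    max_age = max_age,
    wtp_lower = wtp_lower,
    wtp_upper = wtp_upper,
    half_cycle_correction = isTRUE(half_cycle_correction)
  )
  class(s) <- "model_settings"
  validate_settings(s)
  s
}

validate_settings <- function(s) {
  if (s$annual_discount_rate < 0 || s$annual_discount_rate >= 1) {
    stop("settings.annual_discount_rate must lie in [0, 1)", call. = FALSE)
  }
  if (s$start_age >= s$max_age) {
    stop("settings.start_age must be below settings.max_age", call. = FALSE)
  }
  if (s$wtp_lower >= s$wtp_upper) {
    stop("settings.wtp_lower must be below settings.wtp_upper", call. = FALSE)
  }
  if (s$cycles_per_year < 1) {
    stop("settings.cycles_per_year must be >= 1", call. = FALSE)
  }
  invisible(s)
}

#' Treatment arm profile
#'
#' One strategy arm: its annual exacerbation rate, dosing schedule and
#' adverse-event profile.  `ae_profile` is a data frame with columns `name`,
#' `trial_incidence` (proportion over the 52-week trial window),
#' `cost_per_event` (USD) and `disutility` (utility decrement per event).
#'
#' @param name Arm label, e.g. `"mepolizumab"` or `"placebo"`.
#' @param annual_cse_rate Annual clinically-significant-exacerbation rate,
#'   events per person-year.
#' @param ae_profile Adverse-event data frame (see above); may have 0 rows.
#' @param drug_dose_mg Dose in mg per administration.
#' @param dosing_interval_cycles Cycles between administrations (2 = every
#'   4 weeks on a 2-week cycle).
#' @param treatment_duration_years Years over which drug acquisition cost
#'   accrues; `Inf` means lifelong dosing.
#' @return A list of class `arm_profile`.
#' @export
arm_profile <- function(name, annual_cse_rate, ae_profile = empty_ae_profile(),
                        drug_dose_mg = 0, dosing_interval_cycles = 2L,
                        treatment_duration_years = Inf) {
  a <- list(
    name = name,
    annual_cse_rate = annual_cse_rate,
    ae_profile = as.data.frame(ae_profile),
    drug_dose_mg = drug_dose_mg,
    dosing_interval_cycles = as.integer(dosing_interval_cycles),
    treatment_duration_years = treatment_duration_years
  )
  class(a) <- "arm_profile"
  validate_arm(a)
  a
}

#' @rdname arm_profile
#' @export
empty_ae_profile <- function() {
  data.frame(name = character(), trial_incidence = numeric(),
             cost_per_event = numeric(), disutility = numeric(),
             stringsAsFactors = FALSE)
}

validate_arm <- function(a) {
  path <- paste0("arms.", a$name)
  if (!is.numeric(a$annual_cse_rate) || a$annual_cse_rate < 0) {
    stop(path, ".annual_cse_rate must be non-negative", call. = FALSE)
  }
  if (a$dosing_interval_cycles < 1) {
    stop(path, ".dosing_interval_cycles must be >= 1", call. = FALSE)
  }
  ae <- a$ae_profile
  need <- c("name", "trial_incidence", "cost_per_event", "disutility")
  if (!all(need %in% names(ae))) {
    stop(path, ".ae_profile must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(ae)) {
    if (any(ae$trial_incidence < 0 | ae$trial_incidence > 1)) {
      stop(path, ".ae_profile.trial_incidence must lie in [0, 1]",
           call. = FALSE)
    }
    if (any(ae$cost_per_event < 0)) {
      stop(path, ".ae_profile.cost_per_event must be non-negative",
           call. = FALSE)
    }
    if (any(ae$disutility < 0 | ae$disutility > 1)) {
      stop(path, ".ae_profile.disutility must lie in [0, 1]", call. = FALSE)
    }
  }
  invisible(a)
}

#' Exacerbation substate split
#'
#' Proportions of exacerbation events managed with oral corticosteroids
#' only, requiring an emergency-department visit (without the full
#' hospitalization cost tier), or requiring hospitalization.  The three
#' proportions form a mutually exclusive, exhaustive partition; inputs that
#' missum are renormalised to 1 with a warning.
#'
#' @param p_ocs,p_hosp_ed,p_hosp Proportions in \[0, 1\].
#' @return A list of class `cse_split` whose elements sum to 1.
#' @export
cse_split <- function(p_ocs, p_hosp_ed, p_hosp) {
  p <- c(ocs = p_ocs, hosp_ed = p_hosp_ed, hosp = p_hosp)
  if (any(p < 0 | p > 1)) {
    stop("split proportions must lie in [0, 1]", call. = FALSE)
  }
  tot <- sum(p)
  if (tot <= 0) stop("split proportions must not all be zero", call. = FALSE)
  if (abs(tot - 1) > 1e-9) {
    warning(sprintf(
      "substate split sums to %.6f; renormalised to 1", tot), call. = FALSE)
    p <- p / tot
  }
  s <- as.list(p)
  names(s) <- paste0("p_", CSE_SUBSTATES)
  class(s) <- "cse_split"
  s
}

#' Economic inputs
#'
#' Unit costs and human-capital inputs.  Money fields accept either a plain
#' number (USD) or a list `list(cny = x)` converted at
#' `exchange_rate_cny_per_usd`.
#'
#' @param drug_unit_price Price per dose, USD.
#' @param monitoring_cost_per_cycle Routine monitoring cost per cycle, USD.
#' @param cse_cost_by_substate Named list (`ocs`, `hosp_ed`, `hosp`) of
#'   exacerbation management cost per event, USD.
#' @param daily_wage Average daily wage, USD.
#' @param employment_rate_by_age Data frame `age_low`, `age_high`, `rate`
#'   (half-open bands; 0 employment beyond the last band).
#' @param missed_days_outpatient,missed_days_hospitalized Missed paid
#'   workdays per exacerbation for the outpatient / hospitalized tiers.
#' @param presenteeism_days Additional reduced-productivity day-equivalents
#'   per exacerbation.
#' @param exchange_rate_cny_per_usd CNY per USD.
#' @return A list of class `economic_inputs`.
#' @export
economic_inputs <- function(drug_unit_price,
                            monitoring_cost_per_cycle,
                            cse_cost_by_substate,
                            daily_wage,
                            employment_rate_by_age,
                            missed_days_outpatient = 1,
                            missed_days_hospitalized = 6.4,
                            presenteeism_days = 0,
                            exchange_rate_cny_per_usd = 7.0467) {
  fx <- exchange_rate_cny_per_usd
  e <- list(
    drug_unit_price = as_usd(drug_unit_price, fx),
    monitoring_cost_per_cycle = as_usd(monitoring_cost_per_cycle, fx),
    cse_cost_by_substate = lapply(cse_cost_by_substate, as_usd, fx = fx),
    daily_wage = as_usd(daily_wage, fx),
    employment_rate_by_age = as.data.frame(employment_rate_by_age),
    missed_days_outpatient = missed_days_outpatient,
    missed_days_hospitalized = missed_days_hospitalized,
    presenteeism_days = presenteeism_days,
    exchange_rate_cny_per_usd = fx
  )
  class(e) <- "economic_inputs"
  validate_econ(e)
  e
}

as_usd <- function(x, fx) {
  if (is.list(x) && !is.null(x$cny)) return(x$cny / fx)
  x
}

validate_econ <- function(e) {
  if (e$exchange_rate_cny_per_usd <= 0) {
    stop("econ.exchange_rate_cny_per_usd must be positive", call. = FALSE)
  }
  money <- c(e$drug_unit_price, e$monitoring_cost_per_cycle,
             unlist(e$cse_cost_by_substate), e$daily_wage)
  if (any(money < 0)) {
    stop("econ money fields must be non-negative", call. = FALSE)
  }
  if (!all(CSE_SUBSTATES %in% names(e$cse_cost_by_substate))) {
    stop("econ.cse_cost_by_substate must name ocs, hosp_ed and hosp",
         call. = FALSE)
  }
  days <- c(e$missed_days_outpatient, e$missed_days_hospitalized,
            e$presenteeism_days)
  if (any(days < 0)) {
    stop("econ missed/presenteeism days must be non-negative", call. = FALSE)
  }
  emp <- e$employment_rate_by_age
  if (!all(c("age_low", "age_high", "rate") %in% names(emp))) {
    stop("econ.employment_rate_by_age needs age_low, age_high, rate",
         call. = FALSE)
  }
  if (any(emp$rate < 0 | emp$rate > 1)) {
    stop("econ.employment_rate_by_age.rate must lie in [0, 1]", call. = FALSE)
  }
  invisible(e)
}

#' Utility inputs
#'
#' Baseline utility of the exacerbation-free state and the per-substate
#' utility decrements applied during an exacerbation cycle.  Adverse-event
#' disutilities live on the arm profiles and are frequency-weighted at
#' reward-building time; the total per-cycle utility is floored at 0.
#'
#' @param u_no_cse Utility of the exacerbation-free state, in \[0, 1\].
#' @param disutility_by_substate Named list (`ocs`, `hosp_ed`, `hosp`) of
#'   non-negative utility decrements.
#' @return A list of class `utility_inputs`.
#' @export
utility_inputs <- function(u_no_cse, disutility_by_substate) {
  u <- list(
    u_no_cse = u_no_cse,
    disutility_by_substate = disutility_by_substate
  )
  class(u) <- "utility_inputs"
  validate_util(u)
  u
}

validate_util <- function(u) {
  if (is.null(u$u_no_cse)) {
    stop("missing required field util.u_no_cse", call. = FALSE)
  }
  if (u$u_no_cse < 0 || u$u_no_cse > 1) {
    stop("util.u_no_cse must lie in [0, 1]", call. = FALSE)
  }
  if (!all(CSE_SUBSTATES %in% names(u$disutility_by_substate))) {
    stop("util.disutility_by_substate must name ocs, hosp_ed and hosp",
         call. = FALSE)
  }
  if (any(unlist(u$disutility_by_substate) < 0)) {
    stop("util.disutility_by_substate values must be non-negative",
         call. = FALSE)
  }
  invisible(u)
}

#' Subgroup specifications
#'
#' @param name Subgroup labels.
#' @param rr Exacerbation rate ratios (mepolizumab vs placebo).
#' @param rr_low,rr_high 95% confidence bounds of the rate ratios.
#' @return A data frame of class `subgroup_spec`.
#' @export
subgroup_spec <- function(name, rr, rr_low, rr_high) {
  s <- data.frame(name = name, rr = rr, rr_low = rr_low, rr_high = rr_high,
                  stringsAsFactors = FALSE)
  if (any(s$rr <= 0 | s$rr_low <= 0 | s$rr_high <= 0)) {
    stop("subgroup rate ratios must be positive", call. = FALSE)
  }
  if (any(s$rr_low > s$rr | s$rr > s$rr_high)) {
    stop("subgroup rr must lie within [rr_low, rr_high]", call. = FALSE)
  }
  class(s) <- c("subgroup_spec", "data.frame")
  s
}

#' Assemble and validate a complete model parameter set
#'
#' @param settings A [model_settings()] object.
#' @param arms Named list with elements `mepolizumab` and `placebo`, each an
#'   [arm_profile()].  The first element is the intervention, the second the
#'   comparator.
#' @param split A [cse_split()].
#' @param econ An [economic_inputs()].
#' @param util A [utility_inputs()].
#' @param mortality A [mortality_table()].
#' @param subgroups A [subgroup_spec()] data frame (may be empty).
#' @param dsa_ranges Named list mapping parameter paths to `c(low, high)`.
#' @param psa_specs Named list mapping parameter paths to [dist_spec()]s.
#' @return A validated list of class `cea_parameters`.
#' @export
model_parameters <- function(settings, arms, split, econ, util, mortality,
                             subgroups = NULL, dsa_ranges = list(),
                             psa_specs = list()) {
  if (is.null(subgroups)) {
    subgroups <- subgroup_spec(character(), numeric(), numeric(), numeric())
  }
  p <- list(
    settings = settings, arms = arms, split = split, econ = econ,
    util = util, mortality = mortality, subgroups = subgroups,
    dsa_ranges = dsa_ranges, psa_specs = psa_specs
  )
  class(p) <- "cea_parameters"
  validate_parameters(p)
  p
}

#' Validate a parameter set
#'
#' Re-runs every structural invariant: component validity, substate-split
#' normalisation, mortality-table coverage of the simulated age span, and
#' resolvability of every DSA and PSA parameter path.
#'
#' @param params A `cea_parameters` object.
#' @return The parameters, invisibly; errors carry path-qualified messages.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "cea_parameters"))
  validate_settings(params$settings)
  if (length(params$arms) != 2) {
    stop("arms must contain exactly two profiles", call. = FALSE)
  }
  for (a in params$arms) validate_arm(a)
  tot <- sum(unlist(params$split))
  if (abs(tot - 1) > 1e-9) {
    stop("split proportions must sum to 1 after normalisation", call. = FALSE)
  }
  validate_econ(params$econ)
  validate_util(params$util)
  validate_mortality_table(params$mortality)
  if (min(params$mortality$bands$age_low) > params$settings$start_age) {
    stop(sprintf(
      "mortality table starts at age %s but settings.start_age is %s",
      min(params$mortality$bands$age_low), params$settings$start_age),
      call. = FALSE)
  }
  for (path in names(params$dsa_ranges)) {
    get_parameter(params, path)  # errors if unresolvable
    rng <- params$dsa_ranges[[path]]
    if (length(rng) != 2 || rng[1] > rng[2]) {
      stop("dsa_ranges['", path, "'] must be c(low, high)", call. = FALSE)
    }
  }
  for (path in names(params$psa_specs)) {
    point <- get_parameter(params, path)
    spec <- params$psa_specs[[path]]
    validate_dist_spec(spec, path)
    m <- dist_mean(spec)
    if (spec$family != "fixed" && point != 0 &&
        abs(m - point) > 0.05 * abs(point)) {
      stop(sprintf(
        "psa_specs['%s']: sampling mean %.6g departs from point estimate %.6g by more than 5%%",
        path, m, point), call. = FALSE)
    }
  }
  invisible(params)
}

# ---- parameter path addressing ----------------------------------------

#' Read or replace a scalar parameter by dotted path
#'
#' Paths address nested fields with `.` separators, e.g.
#' `"econ.drug_unit_price"`, `"arms.mepolizumab.annual_cse_rate"`,
#' `"split.p_hosp"` or `"util.disutility_by_substate.ocs"`.  Inside a data
#' frame the path continues with the column name and the 1-based row index,
#' e.g. `"arms.placebo.ae_profile.cost_per_event.3"`.
#'
#' @param params A `cea_parameters` object.
#' @param path Dotted parameter path.
#' @param value Replacement scalar (for `set_parameter`).
#' @return `get_parameter` returns the scalar; `set_parameter` returns the
#'   modified parameter set (not re-validated, so sensitivity analyses can
#'   explore values outside the fixture's own ranges).
#' @export
get_parameter <- function(params, path) {
  segs <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- params
  i <- 1L
  while (i <= length(segs)) {
    if (is.data.frame(node)) {
      col <- segs[i]
      if (!col %in% names(node)) {
        stop("unresolvable parameter path '", path, "' (no column '", col,
             "')", call. = FALSE)
      }
      if (i == length(segs)) {
        stop("parameter path '", path, "' must end in a row index",
             call. = FALSE)
      }
      row <- suppressWarnings(as.integer(segs[i + 1L]))
      if (is.na(row) || row < 1 || row > nrow(node)) {
        stop("unresolvable parameter path '", path, "' (bad row index)",
             call. = FALSE)
      }
      node <- node[[col]][row]
      i <- i + 2L
    } else if (is.atomic(node) && length(node) > 1) {
      row <- suppressWarnings(as.integer(segs[i]))
      if (is.na(row) || row < 1 || row > length(node)) {
        stop("unresolvable parameter path '", path, "' (bad index)",
             call. = FALSE)
      }
      node <- node[row]
      i <- i + 1L
    } else {
      if (is.null(node[[segs[i]]])) {
        stop("unresolvable parameter path '", path, "'", call. = FALSE)
      }
      node <- node[[segs[i]]]
      i <- i + 1L
    }
  }
  if (!is.numeric(node) || length(node) != 1) {
    stop("parameter path '", path, "' does not resolve to a scalar",
         call. = FALSE)
  }
  node
}

#' @rdname get_parameter
#' @export
set_parameter <- function(params, path, value) {
  segs <- strsplit(path, ".", fixed = TRUE)[[1]]
  params <- set_rec(params, segs, value, path)
  if (startsWith(path, "mortality.")) {
    mt <- params$mortality
    mt$no_cse_cycle <- prob_annual_to_cycle(mt$no_cse_annual,
                                            mt$cycles_per_year)
    mt$cse_cycle <- prob_annual_to_cycle(mt$cse_annual, mt$cycles_per_year)
    params$mortality <- mt
  }
  params
}

set_rec <- function(node, segs, value, path) {
  if (is.data.frame(node)) {
    col <- segs[1]
    row <- as.integer(segs[2])
    node[[col]][row] <- value
    return(node)
  }
  if (is.atomic(node) && length(node) > 1) {
    node[as.integer(segs[1])] <- value
    return(node)
  }
  if (length(segs) == 1L) {
    if (is.null(node[[segs]])) {
      stop("unresolvable parameter path '", path, "'", call. = FALSE)
    }
    node[[segs]] <- value
    return(node)
  }
  if (is.null(node[[segs[1]]])) {
    stop("unresolvable parameter path '", path, "'", call. = FALSE)
  }
  node[[segs[1]]] <- set_rec(node[[segs[1]]], segs[-1], value, path)
  node
}

# ---- configuration file I/O -------------------------------------------

#' Load a model parameter file
#'
#' Reads a YAML configuration, resolves any CSV-referenced tabular blocks
#' (adverse-event tables, employment rates, mortality tables, subgroups),
#' converts CNY money fields to USD and returns a fully validated parameter
#' set.  Every file read is logged with its resolved absolute path and row
#' count.
#'
#' @param path Path to a YAML parameter file.
#' @return A validated `cea_parameters` object.
#' @export
load_parameters <- function(path) {
  cfg <- yaml::read_yaml(path)
  message("read parameter file ", normalizePath(path))
  dir <- dirname(normalizePath(path))
  tab <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (is.list(x) && !is.null(x$csv)) {
      f <- file.path(dir, x$csv)
      df <- utils::read.csv(f, stringsAsFactors = FALSE)
      message("read ", what, " from ", normalizePath(f), " (", nrow(df),
              " rows)")
      return(df)
    }
    do.call(rbind, lapply(x, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  }
  need <- function(val, name) {
    if (is.null(val)) {
      stop("missing required field ", name, call. = FALSE)
    }
    val
  }

  st <- need(cfg$settings, "settings")
  settings <- do.call(model_settings, st)

  arms <- lapply(names(need(cfg$arms, "arms")), function(nm) {
    a <- cfg$arms[[nm]]
    arm_profile(
      name = nm,
      annual_cse_rate = need(a$annual_cse_rate,
                             paste0("arms.", nm, ".annual_cse_rate")),
      ae_profile = if (is.null(a$ae_profile)) empty_ae_profile() else
        tab(a$ae_profile, paste0("arms.", nm, ".ae_profile")),
      drug_dose_mg = a$drug_dose_mg %||% 0,
      dosing_interval_cycles = a$dosing_interval_cycles %||% 2L,
      treatment_duration_years = a$treatment_duration_years %||% Inf
    )
  })
  names(arms) <- names(cfg$arms)

  sp <- need(cfg$split, "split")
  split <- cse_split(need(sp$p_ocs, "split.p_ocs"),
                     need(sp$p_hosp_ed, "split.p_hosp_ed"),
                     need(sp$p_hosp, "split.p_hosp"))

  ec <- need(cfg$econ, "econ")
  econ <- economic_inputs(
    drug_unit_price = need(ec$drug_unit_price, "econ.drug_unit_price"),
    monitoring_cost_per_cycle = need(ec$monitoring_cost_per_cycle,
                                     "econ.monitoring_cost_per_cycle"),
    cse_cost_by_substate = need(ec$cse_cost_by_substate,
                                "econ.cse_cost_by_substate"),
    daily_wage = need(ec$daily_wage, "econ.daily_wage"),
    employment_rate_by_age = tab(need(ec$employment_rate_by_age,
                                      "econ.employment_rate_by_age"),
                                 "econ.employment_rate_by_age"),
    missed_days_outpatient = ec$missed_days_outpatient %||% 1,
    missed_days_hospitalized = ec$missed_days_hospitalized %||% 6.4,
    presenteeism_days = ec$presenteeism_days %||% 0,
    exchange_rate_cny_per_usd = ec$exchange_rate_cny_per_usd %||% 7.0467
  )

  ut <- need(cfg$util, "util")
  util <- utility_inputs(need(ut$u_no_cse, "util.u_no_cse"),
                         need(ut$disutility_by_substate,
                              "util.disutility_by_substate"))

  mt <- need(cfg$mortality, "mortality")
  mdf <- tab(mt, "mortality")
  mortality <- mortality_table(
    bands = mdf[c("age_low", "age_high")],
    no_cse_annual = mdf$no_cse_annual,
    cse_annual = mdf$cse_annual,
    cycles_per_year = settings$cycles_per_year
  )

  subgroups <- if (is.null(cfg$subgroups)) NULL else {
    sg <- tab(cfg$subgroups, "subgroups")
    subgroup_spec(sg$name, sg$rr, sg$rr_low, sg$rr_high)
  }

  dsa_ranges <- lapply(cfg$dsa_ranges %||% list(), function(r) c(r[[1]], r[[2]]))
  psa_specs <- lapply(cfg$psa_specs %||% list(), function(s) {
    dist_spec(s$family, unlist(s$params))
  })

  model_parameters(settings, arms, split, econ, util, mortality,
                   subgroups, dsa_ranges, psa_specs)
}

#' Write a parameter set to a YAML file
#'
#' Inverse of [load_parameters()]: a written file re-loads to a parameter
#' set equal field by field.
#'
#' @param params A `cea_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  df_rows <- function(df) lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  arms <- lapply(params$arms, function(a) {
    list(annual_cse_rate = a$annual_cse_rate,
         drug_dose_mg = a$drug_dose_mg,
         dosing_interval_cycles = a$dosing_interval_cycles,
         treatment_duration_years = a$treatment_duration_years,
         ae_profile = df_rows(a$ae_profile))
  })
  mt <- params$mortality
  mort <- df_rows(data.frame(age_low = mt$bands$age_low,
                             age_high = mt$bands$age_high,
                             no_cse_annual = mt$no_cse_annual,
                             cse_annual = mt$cse_annual))
  cfg <- list(
    settings = unclass(params$settings),
    arms = arms,
    split = unclass(params$split),
    econ = c(unclass(params$econ)[setdiff(names(params$econ),
                                          "employment_rate_by_age")],
             list(employment_rate_by_age = df_rows(params$econ$employment_rate_by_age))),
    util = unclass(params$util),
    mortality = mort,
    subgroups = df_rows(params$subgroups),
    dsa_ranges = lapply(params$dsa_ranges, function(r) as.list(unname(r))),
    psa_specs = lapply(params$psa_specs, function(s)
      list(family = s$family, params = as.list(s$params)))
  )
  writeLines(yaml::as.yaml(cfg, precision = 15), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cea_parameters <- function(x, ...) {
  cat("<cea_parameters>\n")
  cat(sprintf("  arms: %s (annual CSE rates %s)\n",
              paste(names(x$arms), collapse = " vs "),
              paste(vapply(x$arms, function(a) format(a$annual_cse_rate),
                           character(1)), collapse = " / ")))
  cat(sprintf("  cycle: %g weeks (%d/yr), discount %g%%/yr, ages %.1f-%.0f\n",
              x$settings$cycle_length_weeks, x$settings$cycles_per_year,
              100 * x$settings$annual_discount_rate, x$settings$start_age,
              x$settings$max_age))
  cat(sprintf("  WTP band: $%s-$%s per QALY\n",
              format(x$settings$wtp_lower, big.mark = ","),
              format(x$settings$wtp_upper, big.mark = ",")))
  cat(sprintf("  subgroups: %d, DSA paths: %d, PSA paths: %d\n",
              nrow(x$subgroups), length(x$dsa_ranges), length(x$psa_specs)))
  invisible(x)
}
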