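#' @title Per-cycle rewards and comparison statistics
#' @description Costs are assembled per state and cycle from five ledgers —
#'   drug acquisition, routine monitoring, exacerbation management,
#'   adverse-event management and human-capital indirect (productivity)
#'   costs — and utilities from the exacerbation-free baseline less
#'   substate and frequency-weighted adverse-event decrements.
#'   Adverse-event burdens attach to every alive state because they follow
#'   the treatment arm, not the exacerbation state; indirect costs accrue
#'   only on exacerbation cycles.
#' @name economics
NULL

#' Drug acquisition cost per cycle
#'
#' The per-dose price amortized evenly over the dosing interval: a dose
#' every 4 weeks on a 2-week cycle accrues half the dose price each cycle.
#'
#' @param arm An [arm_profile()].
#' @param econ An [economic_inputs()].
#' @return Money per cycle (0 for arms with zero dose).
#' @export
drug_cost_per_cycle <- function(arm, econ) {
  if (arm$drug_dose_mg <= 0) return(0)
  econ$drug_unit_price / arm$dosing_interval_cycles
}

#' Adverse-event management cost per cycle
#'
#' Frequency-weighted sum over the arm's adverse-event profile, with the
#' 52-week trial incidences spread evenly over the cycles of a year:
#' per-cycle frequency = trial incidence / cycles_per_year.
#'
#' @param arm An [arm_profile()].
#' @param cycles_per_year Cycles per model year.
#' @return Money per cycle.
#' @export
ae_cost_per_cycle <- function(arm, cycles_per_year = 26L) {
  ae <- arm$ae_profile
  if (!nrow(ae)) return(0)
  sum(ae$trial_incidence * ae$cost_per_event) / cycles_per_year
}

#' Adverse-event disutility per cycle
#'
#' Frequency-weighted summation of per-event disutilities, spread over the
#' cycles of a year like [ae_cost_per_cycle()].
#'
#' @inheritParams ae_cost_per_cycle
#' @return Non-negative utility decrement per cycle.
#' @export
ae_disutility_per_cycle <- function(arm, cycles_per_year = 26L) {
  ae <- arm$ae_profile
  if (!nrow(ae)) return(0)
  sum(ae$trial_incidence * ae$disutility) / cycles_per_year
}

# employment rate at an age (vectorised); 0 beyond the last band
employment_rate_at <- function(econ, age) {
  emp <- econ$employment_rate_by_age
  emp <- emp[order(emp$age_low), , drop = FALSE]
  idx <- findInterval(age, emp$age_low)
  rate <- ifelse(idx == 0, 0, emp$rate[pmax(idx, 1L)])
  over <- idx == nrow(emp) & age >= emp$age_high[nrow(emp)]
  rate[over] <- 0
  under <- idx >= 1 & idx < nrow(emp) & age >= emp$age_high[pmax(idx, 1L)]
  rate[under] <- 0  # gap between bands
  rate
}

#' Human-capital indirect cost of one exacerbation
#'
#' Missed paid workdays (1 for the outpatient tier, 6.4 for the
#' hospitalized tiers) plus presenteeism day-equivalents, valued at the
#' average daily wage and adjusted by the age-specific employment rate.
#'
#' @param substate One of `"CSE_OCS"`, `"CSE_HOSP_ED"`, `"CSE_HOSP"`.
#' @param age Age in years (vectorised).
#' @param econ An [economic_inputs()].
#' @return Money per exacerbation event.
#' @export
indirect_cost_per_cse <- function(substate, age, econ) {
  if (!substate %in% CSE_STATES) {
    stop("indirect costs are defined only for exacerbation substates",
         call. = FALSE)
  }
  missed <- if (substate == "CSE_OCS") econ$missed_days_outpatient else
    econ$missed_days_hospitalized
  emp <- employment_rate_at(econ, age)
  (missed + econ$presenteeism_days) * econ$daily_wage * emp
}

#' Assemble the per-cycle reward set for one arm at one age
#'
#' Exacerbation-free cost = drug + monitoring + adverse-event cost; each
#' exacerbation substate adds its management cost and the age-adjusted
#' indirect cost.  Exacerbation-free utility is the baseline less the
#' adverse-event decrement; substates subtract their own decrement too.
#' Utilities are floored at 0; the death state earns nothing.
#'
#' @param arm An [arm_profile()].
#' @param age Age in years.
#' @param params A `cea_parameters` object.
#' @return A list of class `cycle_rewards` with `cost_by_state` and
#'   `utility_by_state` (utility per year while in the state; multiply by
#'   the cycle fraction of a year for the QALY accrual).
#' @export
build_cycle_rewards <- function(arm, age, params) {
  sched <- cycle_reward_schedule(arm, age, params)
  r <- list(
    cost_by_state = stats::setNames(as.numeric(sched$cost[1, ]),
                                    health_states()),
    utility_by_state = stats::setNames(as.numeric(sched$utility[1, ]),
                                       health_states())
  )
  class(r) <- "cycle_rewards"
  r
}

# Vectorised over a whole age schedule: returns n x 5 matrices for total
# cost and utility plus one matrix per cost component.
cycle_reward_schedule <- function(arm, ages, params) {
  st <- params$settings
  econ <- params$econ
  n <- length(ages)
  on_drug <- (ages - st$start_age) <
    arm$treatment_duration_years - 1e-12

  zero <- matrix(0, n, STATE_N, dimnames = list(NULL, health_states()))
  alive <- c("NO_CSE", CSE_STATES)

  drug <- zero
  drug[, alive] <- drug_cost_per_cycle(arm, econ) * on_drug
  monitoring <- zero
  monitoring[, alive] <- econ$monitoring_cost_per_cycle
  ae <- zero
  ae[, alive] <- ae_cost_per_cycle(arm, st$cycles_per_year)
  mgmt <- zero
  mgmt[, "CSE_OCS"] <- econ$cse_cost_by_substate$ocs
  mgmt[, "CSE_HOSP_ED"] <- econ$cse_cost_by_substate$hosp_ed
  mgmt[, "CSE_HOSP"] <- econ$cse_cost_by_substate$hosp
  indirect <- zero
  for (s in CSE_STATES) {
    indirect[, s] <- indirect_cost_per_cse(s, ages, econ)
  }

  ae_du <- ae_disutility_per_cycle(arm, st$cycles_per_year)
  util <- zero
  util[, "NO_CSE"] <- pmax(params$util$u_no_cse - ae_du, 0)
  du <- params$util$disutility_by_substate
  util[, "CSE_OCS"] <- pmax(params$util$u_no_cse - du$ocs - ae_du, 0)
  util[, "CSE_HOSP_ED"] <- pmax(params$util$u_no_cse - du$hosp_ed - ae_du, 0)
  util[, "CSE_HOSP"] <- pmax(params$util$u_no_cse - du$hosp - ae_du, 0)

  list(cost = drug + monitoring + ae + mgmt + indirect,
       utility = util,
       components = list(drug = drug, monitoring = monitoring,
                         cse_management = mgmt, ae = ae,
                         indirect = indirect))
}

#' Compare two arm traces
#'
#' Computes incremental cost and QALYs of arm A over arm B, the ICER when
#' defined, and the dominance classification: `"dominant"` when A saves
#' money and gains QALYs, `"dominated"` when A costs more and loses QALYs,
#' `"icer"` otherwise.  A zero QALY difference leaves the ICER undefined
#' (`NA`) with classification by the cost sign.
#'
#' @param trace_a,trace_b `markov_trace` objects for the intervention and
#'   comparator, run under the same settings.
#' @return A list of class `ce_result`.
#' @export
ce_compare <- function(trace_a, trace_b) {
  res <- ce_result(trace_a$cumulative_cost, trace_b$cumulative_cost,
                   trace_a$cumulative_qaly, trace_b$cumulative_qaly)
  res$arm_a <- trace_a$arm
  res$arm_b <- trace_b$arm
  res$components_a <- trace_a$components
  res$components_b <- trace_b$components
  res$delta_components <- trace_a$components - trace_b$components
  res
}

#' Cost-effectiveness result from arm totals
#'
#' @param cost_a,cost_b Total discounted costs.
#' @param qaly_a,qaly_b Total discounted QALYs.
#' @return A list of class `ce_result` with `delta_cost`, `delta_qaly`,
#'   `icer` (NA when undefined or dominated/dominant) and `classification`.
#' @export
ce_result <- function(cost_a, cost_b, qaly_a, qaly_b) {
  dc <- cost_a - cost_b
  de <- qaly_a - qaly_b
  if (de == 0) {
    classification <- if (dc > 0) "dominated" else if (dc < 0) "dominant"
      else "equivalent"
    icer <- NA_real_
  } else if (dc <= 0 && de > 0) {
    classification <- if (dc == 0) "icer" else "dominant"
    icer <- if (dc == 0) 0 else NA_real_
  } else if (dc >= 0 && de < 0) {
    classification <- "dominated"
    icer <- NA_real_
  } else {
    classification <- "icer"
    icer <- dc / de
  }
  r <- list(cost_a = cost_a, cost_b = cost_b, qaly_a = qaly_a,
            qaly_b = qaly_b, delta_cost = dc, delta_qaly = de,
            icer = icer, classification = classification)
  class(r) <- "ce_result"
  r
}

#' Incremental net monetary benefit at a willingness-to-pay threshold
#'
#' `wtp * delta_QALY - delta_cost`; positive exactly when the intervention
#' is cost-effective at that threshold.
#'
#' @param result A `ce_result`.
#' @param wtp Willingness to pay, money per QALY (vectorised).
#' @return Incremental net monetary benefit.
#' @export
net_monetary_benefit <- function(result, wtp) {
  if (any(wtp < 0)) stop("`wtp` must be non-negative", call. = FALSE)
  wtp * result$delta_qaly - result$delta_cost
}

#' Export the cost-composition breakdown of a comparison
#'
#' One row per (arm, component) with the discounted total, mirroring a
#' cost-composition table.
#'
#' @param result A `ce_result` produced by [ce_compare()].
#' @param path Optional CSV path; omitted returns the data frame only.
#' @return Data frame `arm`, `component`, `discounted_total`.
#' @export
cost_composition <- function(result, path = NULL) {
  if (is.null(result$components_a)) {
    stop("cost composition requires a result from ce_compare()",
         call. = FALSE)
  }
  df <- rbind(
    data.frame(arm = result$arm_a, component = names(result$components_a),
               discounted_total = as.numeric(result$components_a)),
    data.frame(arm = result$arm_b, component = names(result$components_b),
               discounted_total = as.numeric(result$components_b))
  )
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

#' @export
print.ce_result <- function(x, ...) {
  fx <- 7.0467
  cat("<ce_result>")
  if (!is.null(x$arm_a)) cat(" ", x$arm_a, " vs ", x$arm_b, sep = "")
  cat("\n")
  cat(sprintf("  cost:  $%.2f vs $%.2f (delta $%.2f)\n",
              x$cost_a, x$cost_b, x$delta_cost))
  cat(sprintf("  QALYs: %.5f vs %.5f (delta %.5f)\n",
              x$qaly_a, x$qaly_b, x$delta_qaly))
  if (x$classification == "icer") {
    cat(sprintf("  ICER: $%.2f per QALY\n", x$icer))
  } else {
    cat("  classification:", x$classification, "\n")
  }
  invisible(x)
}
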