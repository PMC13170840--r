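#' Health states of the cohort model
#'
#' The model tracks an exacerbation-free state, three one-cycle
#' exacerbation tunnel substates (managed with oral corticosteroids only,
#' requiring an emergency-department visit, requiring hospitalization), and
#' an absorbing death state.  Exacerbation states are entered only from the
#' exacerbation-free state and exited within one cycle.
#'
#' @return Character vector of state names in matrix order.
#' @export
health_states <- function() {
  c("NO_CSE", "CSE_OCS", "CSE_HOSP_ED", "CSE_HOSP", "DEATH")
}

STATE_N <- 5L
CSE_STATES <- c("CSE_OCS", "CSE_HOSP_ED", "CSE_HOSP")

#' Build the per-cycle transition matrix for one arm at one age
#'
#' From the exacerbation-free state the cohort faces the age-specific
#' per-cycle death probability; survivors enter an exacerbation substate
#' with the per-cycle exacerbation probability apportioned by the substate
#' split, or stay put.  Exacerbation substates are tunnels: occupants face
#' the exacerbation-cycle death probability and otherwise return to the
#' exacerbation-free state.  Death is absorbing.
#'
#' @param arm An [arm_profile()].
#' @param age Age in years at which the matrix applies.
#' @param params A `cea_parameters` object.
#' @return A 5x5 row-stochastic matrix with `age_years` attribute.
#' @export
build_transition_matrix <- function(arm, age, params) {
  cpy <- params$settings$cycles_per_year
  p_cse <- rate_annual_to_cycle(arm$annual_cse_rate, cpy)
  p_d0 <- lookup_cycle_mortality(params$mortality, "NO_CSE", age)
  p_d1 <- lookup_cycle_mortality(params$mortality, "CSE_OCS", age)
  split <- unlist(params$split, use.names = FALSE)

  m <- matrix(0, STATE_N, STATE_N, dimnames = list(health_states(),
                                                   health_states()))
  m["NO_CSE", "DEATH"] <- p_d0
  m["NO_CSE", CSE_STATES] <- (1 - p_d0) * p_cse * split
  m["NO_CSE", "NO_CSE"] <- 1 - p_d0 - sum(m["NO_CSE", CSE_STATES])
  for (s in CSE_STATES) {
    m[s, "DEATH"] <- p_d1
    m[s, "NO_CSE"] <- 1 - p_d1
  }
  m["DEATH", "DEATH"] <- 1
  stopifnot(all(abs(rowSums(m) - 1) < 1e-9))
  attr(m, "age_years") <- age
  m
}

# Precompute everything a cohort (or microsimulation) run needs: one
# transition matrix per mortality age band actually visited, plus per-cycle
# reward matrices (cost by component, utility) and discount factors.
compile_model <- function(arm, params) {
  st <- params$settings
  cpy <- st$cycles_per_year
  n <- ceiling((st$max_age - st$start_age) * cpy)
  ages <- st$start_age + (seq_len(n) - 1) / cpy
  bands <- band_index(params$mortality, ages)
  ub <- sort(unique(bands))
  mats <- lapply(ub, function(b) {
    age_rep <- params$mortality$bands$age_low[b]
    build_transition_matrix(arm, max(age_rep, st$start_age), params)
  })
  mat_of <- match(bands, ub)

  rw <- cycle_reward_schedule(arm, ages, params)
  disc <- discount_factor(seq_len(n) - 1, st$annual_discount_rate, cpy)

  list(arm = arm, n_cycles = n, ages = ages, mats = mats, mat_of = mat_of,
       cost = rw$cost, components = rw$components, utility = rw$utility,
       qaly = rw$utility / cpy, disc = disc, settings = st)
}

#' Run the discounted, half-cycle-corrected cohort simulation for one arm
#'
#' The cohort starts fully in the exacerbation-free state at the starting
#' age and is advanced one 2-week cycle at a time through the age-specific
#' transition matrices until the terminal age, or until living occupancy
#' falls below 1e-9.  Costs and QALYs accrue per cycle on the trapezoidal
#' average of entry and exit occupancy (half-cycle correction, on by
#' default) and are discounted at the annual rate.
#'
#' @param arm An [arm_profile()].
#' @param params A `cea_parameters` object.
#' @return A `markov_trace` with per-cycle occupancy, discounted cost and
#'   QALY streams, cumulative totals, and a cost-component breakdown
#'   (`drug`, `monitoring`, `cse_management`, `ae`, `indirect`).
#' @export
run_cohort <- function(arm, params) {
  cm <- compile_model(arm, params)
  n <- cm$n_cycles
  occ <- matrix(0, n + 1L, STATE_N, dimnames = list(NULL, health_states()))
  occ[1L, "NO_CSE"] <- 1
  used <- n
  for (k in seq_len(n)) {
    occ[k + 1L, ] <- occ[k, ] %*% cm$mats[[cm$mat_of[k]]]
    if (1 - occ[k + 1L, STATE_N] < 1e-9) {
      used <- k
      break
    }
  }
  occ <- occ[seq_len(used + 1L), , drop = FALSE]

  if (any(abs(rowSums(occ) - 1) > 1e-9)) {
    stop("occupancy conservation violated", call. = FALSE)
  }
  if (any(diff(occ[, "DEATH"]) < -1e-12)) {
    stop("death occupancy must be non-decreasing", call. = FALSE)
  }

  member <- if (cm$settings$half_cycle_correction) {
    (occ[seq_len(used), , drop = FALSE] +
       occ[seq_len(used) + 1L, , drop = FALSE]) / 2
  } else {
    occ[seq_len(used), , drop = FALSE]
  }
  disc <- cm$disc[seq_len(used)]
  cost_cycle <- disc * rowSums(member * cm$cost[seq_len(used), , drop = FALSE])
  qaly_cycle <- disc * rowSums(member * cm$qaly[seq_len(used), , drop = FALSE])
  comp <- vapply(cm$components, function(cc)
    sum(disc * rowSums(member * cc[seq_len(used), , drop = FALSE])),
    numeric(1))

  tr <- list(
    arm = arm$name,
    n_cycles = used,
    ages = cm$ages[seq_len(used)],
    occupancy = occ,
    cost_per_cycle = cost_cycle,
    qaly_per_cycle = qaly_cycle,
    cumulative_cost = sum(cost_cycle),
    cumulative_qaly = sum(qaly_cycle),
    components = comp,
    life_years = sum(disc * (1 - member[, STATE_N])) /
      cm$settings$cycles_per_year,
    settings = cm$settings
  )
  class(tr) <- "markov_trace"
  tr
}

#' Export a cohort trace to CSV
#'
#' One row per cycle: cycle index, age, occupancy per state, discounted
#' cost and discounted QALYs accrued in the cycle.
#'
#' @param trace A `markov_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  n <- trace$n_cycles
  df <- data.frame(cycle = seq_len(n) - 1L, age = trace$ages,
                   trace$occupancy[seq_len(n), , drop = FALSE],
                   discounted_cost = trace$cost_per_cycle,
                   discounted_qaly = trace$qaly_per_cycle)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.markov_trace <- function(x, ...) {
  cat(sprintf(
    "<markov_trace> arm '%s': %d cycles (ages %.1f-%.1f)\n", x$arm,
    x$n_cycles, x$ages[1], x$ages[x$n_cycles]))
  cat(sprintf("  discounted cost  $%.2f\n", x$cumulative_cost))
  cat(sprintf("  discounted QALYs %.5f (life-years %.3f)\n",
              x$cumulative_qaly, x$life_years))
  comp <- paste(sprintf("%s $%.2f", names(x$components), x$components),
                collapse = ", ")
  cat("  components: ", comp, "\n", sep = "")
  invisible(x)
}
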