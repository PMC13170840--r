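#' @title Age-specific asthma mortality
#' @description The model distinguishes mortality risk in the
#'   exacerbation-free state from the (higher) risk during an exacerbation
#'   cycle.  Exacerbation-free annual probabilities are derived by a
#'   three-table stepwise calculation — asthma deaths divided by the asthma
#'   case count implied by survey rates and census population, computed per
#'   gender and then population-weighted into a single age-specific table.
#'   Annual probabilities are converted to per-cycle probabilities with the
#'   compound formula so that one year of cycles recovers the annual value.
#' @name mortality
NULL

#' Mortality derivation inputs
#'
#' Three age- and gender-stratified tables with identical age bands:
#' asthma-related death counts, asthma case rates per person (survey rates),
#' and census population counts.  Each is a data frame with columns
#' `age_low`, `age_high`, `gender`, `value`.
#'
#' @param deaths,incidence,population The three tables.
#' @return A list of class `mortality_inputs`.
#' @export
mortality_inputs <- function(deaths, incidence, population) {
  chk <- function(df, nm, unit = FALSE) {
    need <- c("age_low", "age_high", "gender", "value")
    if (!all(need %in% names(df))) {
      stop(nm, " table needs columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (any(df$value < 0)) {
      stop(nm, " table values must be non-negative", call. = FALSE)
    }
    if (unit && any(df$value > 1)) {
      stop(nm, " table values must lie in [0, 1]", call. = FALSE)
    }
    df[order(df$age_low, df$gender), , drop = FALSE]
  }
  m <- list(deaths = chk(deaths, "deaths"),
            incidence = chk(incidence, "incidence", unit = TRUE),
            population = chk(population, "population"))
  key <- function(df) paste(df$age_low, df$age_high, df$gender)
  if (!identical(key(m$deaths), key(m$incidence)) ||
      !identical(key(m$deaths), key(m$population))) {
    stop("deaths, incidence and population tables must share identical ",
         "(age band, gender) strata", call. = FALSE)
  }
  class(m) <- "mortality_inputs"
  m
}

#' Derive age-specific annual asthma mortality probabilities
#'
#' Per (age band, gender): `rate = deaths / (incidence * population)`, the
#' deaths among the asthma cases implied by the survey rate.  Per age band,
#' gender-specific rates are averaged with weights proportional to the
#' gender-specific population.  Results are clamped to \[0, 1\] with a
#' warning if a stratum's deaths exceed its implied case count.
#'
#' @param inputs A [mortality_inputs()] object.
#' @return Data frame with columns `age_low`, `age_high`, `rate`.
#' @export
derive_mortality_table <- function(inputs) {
  stopifnot(inherits(inputs, "mortality_inputs"))
  d <- inputs$deaths; i <- inputs$incidence; p <- inputs$population
  cases <- i$value * p$value
  bad <- cases == 0 & d$value > 0
  if (any(bad)) {
    stop("zero asthma-case denominator with nonzero deaths in band [",
         d$age_low[which(bad)[1]], ", ", d$age_high[which(bad)[1]], ")",
         call. = FALSE)
  }
  rate_g <- ifelse(cases > 0, d$value / cases, 0)
  band <- paste(d$age_low, d$age_high)
  w <- p$value
  num <- tapply(rate_g * w, band, sum)
  den <- tapply(w, band, sum)
  lo <- tapply(d$age_low, band, unique)
  hi <- tapply(d$age_high, band, unique)
  rate <- ifelse(den > 0, num / den, 0)
  if (any(rate > 1)) {
    warning("derived annual mortality exceeds 1 in some bands; clamped",
            call. = FALSE)
    rate <- pmin(rate, 1)
  }
  out <- data.frame(age_low = as.numeric(lo), age_high = as.numeric(hi),
                    rate = as.numeric(rate))
  out[order(out$age_low), , drop = FALSE]
}

#' Age-indexed mortality table for both health-state channels
#'
#' Holds annual death probabilities for the exacerbation-free state and for
#' exacerbation cycles, per half-open age band `[age_low, age_high)` (the
#' last band is treated as open-ended), plus the derived per-cycle
#' probabilities.
#'
#' @param bands Data frame with columns `age_low`, `age_high`.
#' @param no_cse_annual,cse_annual Annual death probabilities per band.
#' @param cycles_per_year Cycles per year used for the per-cycle conversion.
#' @return A list of class `mortality_table`.
#' @export
mortality_table <- function(bands, no_cse_annual, cse_annual,
                            cycles_per_year = 26L) {
  ord <- order(bands$age_low)
  t <- list(
    bands = data.frame(age_low = bands$age_low[ord],
                       age_high = bands$age_high[ord]),
    no_cse_annual = no_cse_annual[ord],
    cse_annual = cse_annual[ord],
    no_cse_cycle = prob_annual_to_cycle(no_cse_annual[ord], cycles_per_year),
    cse_cycle = prob_annual_to_cycle(cse_annual[ord], cycles_per_year),
    cycles_per_year = as.integer(cycles_per_year)
  )
  class(t) <- "mortality_table"
  validate_mortality_table(t)
  t
}

validate_mortality_table <- function(t) {
  probs <- c(t$no_cse_annual, t$cse_annual)
  if (any(probs < 0 | probs > 1)) {
    stop("mortality probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(t$cse_annual < t$no_cse_annual)) {
    stop("mortality during exacerbation cycles must be at least the ",
         "exacerbation-free mortality in every age band", call. = FALSE)
  }
  if (any(diff(t$bands$age_low) <= 0)) {
    stop("mortality age bands must be strictly increasing", call. = FALSE)
  }
  if (any(t$bands$age_high <= t$bands$age_low)) {
    stop("mortality age bands must satisfy age_low < age_high", call. = FALSE)
  }
  invisible(t)
}

# index of the band containing `age` under [low, high) bands, last band
# open-ended upward
band_index <- function(table, age) {
  idx <- findInterval(age, table$bands$age_low)
  if (any(idx == 0)) {
    stop("age ", age[which(idx == 0)[1]],
         " is below mortality table coverage", call. = FALSE)
  }
  idx
}

#' Look up the per-cycle death probability for a state at an age
#'
#' All three exacerbation substates share the exacerbation-cycle channel.
#'
#' @param table A [mortality_table()].
#' @param state A health state name (see [health_states()]); must be alive.
#' @param age Age in years (vectorised).
#' @return Per-cycle death probability.
#' @export
lookup_cycle_mortality <- function(table, state, age) {
  if (state == "DEATH") {
    stop("mortality lookup is undefined for the DEATH state", call. = FALSE)
  }
  idx <- band_index(table, age)
  if (state == "NO_CSE") table$no_cse_cycle[idx] else table$cse_cycle[idx]
}

#' @export
print.mortality_table <- function(x, ...) {
  cat("<mortality_table> ", nrow(x$bands), " age bands, ages [",
      min(x$bands$age_low), ", ", max(x$bands$age_high), ")\n", sep = "")
  df <- data.frame(x$bands, no_cse_annual = x$no_cse_annual,
                   cse_annual = x$cse_annual)
  print(utils::head(df, 10), row.names = FALSE)
  if (nrow(df) > 10) cat("  ...\n")
  invisible(x)
}
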