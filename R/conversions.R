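#' Convert an annual event rate to a per-cycle rate
#'
#' Divides an annual event rate (events per person-year) evenly across the
#' model cycles of one year.  This linear conversion is the one used for
#' clinically significant exacerbation (CSE) rates: an annual rate of 1.31
#' events/person-year becomes 0.05038 events per 2-week cycle with 26 cycles
#' per year.  The result is used directly as the per-cycle probability of
#' entering the exacerbation state and is therefore clamped at 1 (with a
#' warning) if an extreme input pushes it above.
#'
#' @param rate_annual Non-negative annual event rate (events/person-year).
#' @param cycles_per_year Positive integer number of model cycles per year.
#' @return Per-cycle event rate (used as a per-cycle probability, clamped to
#'   at most 1).
#' @seealso [prob_annual_to_cycle()] for the compound conversion used for
#'   mortality probabilities.
#' @export
#' @examples
#' rate_annual_to_cycle(1.31, 26) # 0.05038...
#' rate_annual_to_cycle(0.45, 26) # 0.01731...
rate_annual_to_cycle <- function(rate_annual, cycles_per_year = 26L) {
  stopifnot(is.numeric(rate_annual), is.numeric(cycles_per_year))
  if (any(rate_annual < 0)) {
    stop("`rate_annual` must be non-negative", call. = FALSE)
  }
  if (any(cycles_per_year < 1)) {
    stop("`cycles_per_year` must be >= 1", call. = FALSE)
  }
  out <- rate_annual / cycles_per_year
  if (any(out > 1)) {
    warning("per-cycle rate exceeds 1; clamped to 1", call. = FALSE)
    out <- pmin(out, 1)
  }
  out
}

#' Convert an annual probability to a per-cycle probability
#'
#' Compound conversion `1 - (1 - p)^(1/cycles_per_year)`: compounding the
#' per-cycle probability over one year of cycles recovers the annual
#' probability.  This is the conversion used for the age-specific asthma
#' mortality probabilities.
#'
#' @param p_annual Annual probability in \[0, 1\] (vectorised).
#' @param cycles_per_year Positive integer number of model cycles per year.
#' @return Per-cycle probability.
#' @export
#' @examples
#' p <- prob_annual_to_cycle(0.05, 26)
#' 1 - (1 - p)^26 # 0.05
prob_annual_to_cycle <- function(p_annual, cycles_per_year = 26L) {
  stopifnot(is.numeric(p_annual))
  if (any(p_annual < 0 | p_annual > 1)) {
    stop("`p_annual` must lie in [0, 1]", call. = FALSE)
  }
  if (any(cycles_per_year < 1)) {
    stop("`cycles_per_year` must be >= 1", call. = FALSE)
  }
  1 - (1 - p_annual)^(1 / cycles_per_year)
}

#' Compound a per-cycle probability back to an annual probability
#'
#' Inverse of [prob_annual_to_cycle()].
#'
#' @param p_cycle Per-cycle probability in \[0, 1\].
#' @param cycles_per_year Positive integer number of model cycles per year.
#' @return Annual probability.
#' @export
prob_cycle_to_annual <- function(p_cycle, cycles_per_year = 26L) {
  stopifnot(is.numeric(p_cycle))
  if (any(p_cycle < 0 | p_cycle > 1)) {
    stop("`p_cycle` must lie in [0, 1]", call. = FALSE)
  }
  1 - (1 - p_cycle)^cycles_per_year
}

#' Per-cycle discount factor
#'
#' Discount factor applied to costs and QALYs accrued in a given cycle, for
#' an annual discount rate compounded continuously over cycle fractions of a
#' year: `(1 + r)^(-cycle_index / cycles_per_year)`.  Cycle 0 has factor 1;
#' one full year of cycles at a 5% annual rate gives 1/1.05.
#'
#' @param cycle_index Non-negative integer cycle index (0-based, vectorised).
#' @param annual_discount_rate Annual discount rate in \[0, 1).
#' @param cycles_per_year Positive integer number of model cycles per year.
#' @return Discount factor in (0, 1].
#' @export
discount_factor <- function(cycle_index, annual_discount_rate = 0.05,
                            cycles_per_year = 26L) {
  stopifnot(is.numeric(cycle_index))
  if (any(cycle_index < 0)) {
    stop("`cycle_index` must be non-negative", call. = FALSE)
  }
  if (annual_discount_rate < 0 || annual_discount_rate >= 1) {
    stop("`annual_discount_rate` must lie in [0, 1)", call. = FALSE)
  }
  (1 + annual_discount_rate)^(-cycle_index / cycles_per_year)
}
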