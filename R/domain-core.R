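#' Estimation configuration
#'
#' Working-time constants used throughout the supply accounting.  Defaults
#' encode the study convention of 200 working days per year and six working
#' hours per day, i.e. 1200 contracted hours per full-time worker per year.
#'
#' @param working_days_per_year Number of working days per year (default 200).
#' @param hours_per_day Contracted working hours per day (default 6).
#' @param annual_fte_hours Annual hours defining one full-time equivalent
#'   (default `working_days_per_year * hours_per_day`).
#' @param utilization Fraction of contracted time spent on package delivery.
#'   The default 1 encodes the conservative assumption that all working time
#'   is devoted to prevention and health promotion; values < 1 shrink the
#'   available supply accordingly.
#' @return An object of class `estimation_config`.
#' @examples
#' cfg <- estimation_config()
#' available_supply_hours(10, cfg) # 12000 annual hours
#' @export
estimation_config <- function(working_days_per_year = 200,
                              hours_per_day = 6,
                              annual_fte_hours = working_days_per_year * hours_per_day,
                              utilization = 1) {
  stopifnot(
    is.numeric(working_days_per_year), length(working_days_per_year) == 1L,
    is.numeric(hours_per_day), length(hours_per_day) == 1L,
    is.numeric(annual_fte_hours), length(annual_fte_hours) == 1L,
    is.numeric(utilization), length(utilization) == 1L
  )
  if (working_days_per_year <= 0 || hours_per_day <= 0 || annual_fte_hours <= 0)
    stop("estimation_config: all working-time constants must be positive")
  if (utilization <= 0 || utilization > 1)
    stop("estimation_config: 'utilization' must be in (0, 1]")
  structure(
    list(
      working_days_per_year = working_days_per_year,
      hours_per_day = hours_per_day,
      annual_fte_hours = annual_fte_hours,
      utilization = utilization
    ),
    class = "estimation_config"
  )
}

#' @export
print.estimation_config <- function(x, ...) {
  cat("Estimation configuration\n")
  cat("  working days/year :", x$working_days_per_year, "\n")
  cat("  hours/day         :", x$hours_per_day, "\n")
  cat("  annual FTE hours  :", x$annual_fte_hours, "\n")
  cat("  utilization       :", x$utilization, "\n")
  invisible(x)
}

#' Available supply in annual hours
#'
#' Converts a staff headcount into contracted annual hours:
#' `headcount * working_days_per_year * hours_per_day * utilization`.
#'
#' @param headcount Non-negative worker count(s); vectorised.
#' @param config An [estimation_config()].
#' @return Annual hours available, same length as `headcount`.
#' @export
available_supply_hours <- function(headcount, config = estimation_config()) {
  stopifnot(inherits(config, "estimation_config"))
  if (!is.numeric(headcount) || any(!is.finite(headcount)))
    stop("available_supply_hours: 'headcount' must be finite and numeric")
  if (any(headcount < 0))
    stop("available_supply_hours: 'headcount' must be non-negative")
  headcount * config$working_days_per_year * config$hours_per_day *
    config$utilization
}

#' Ideal supply in annual hours
#'
#' Annual hours needed to deliver the package to an attended population:
#' per-person annual minutes for each age group are multiplied by the group's
#' attended population, summed, and converted to hours.
#'
#' @param minutes Named numeric vector of per-person annual minutes by age
#'   group (one channel: time used or time required).
#' @param population Named numeric vector of attended individuals by age
#'   group.  Every group named in `minutes` must be present.
#' @return Annual hours, a single number: `sum(minutes * population) / 60`.
#' @examples
#' ideal_supply_hours(c(adults = 60), c(adults = 1200)) # 1200 hours
#' @export
ideal_supply_hours <- function(minutes, population) {
  if (!is.numeric(minutes) || any(!is.finite(minutes)) || any(minutes < 0))
    stop("ideal_supply_hours: 'minutes' must be finite and non-negative")
  if (!is.numeric(population) || any(!is.finite(population)) || any(population < 0))
    stop("ideal_supply_hours: 'population' must be finite and non-negative")
  if (!is.null(names(minutes))) {
    missing <- setdiff(names(minutes), names(population))
    if (length(missing))
      stop("ideal_supply_hours: no population entry for age group(s): ",
           paste(missing, collapse = ", "))
    population <- population[names(minutes)]
  } else if (length(minutes) != length(population)) {
    stop("ideal_supply_hours: 'minutes' and 'population' lengths differ")
  }
  sum(minutes * population) / 60
}

#' Convert annual hours to full-time equivalents
#'
#' @param hours Non-negative annual hours; vectorised.
#' @inheritParams available_supply_hours
#' @return `hours / annual_fte_hours` (fractional worker counts).
#' @export
hours_to_fte <- function(hours, config = estimation_config()) {
  stopifnot(inherits(config, "estimation_config"))
  if (!is.numeric(hours) || any(!is.finite(hours)))
    stop("hours_to_fte: 'hours' must be finite and numeric")
  if (any(hours < 0))
    stop("hours_to_fte: 'hours' must be non-negative")
  hours / config$annual_fte_hours
}

#' Supply gap
#'
#' Signed difference `available - ideal`; negative values indicate a
#' shortage.  Both arguments must be on the same scale (hours or FTE).
#'
#' @param available,ideal Numeric vectors of equal length.
#' @return `available - ideal`.
#' @export
supply_gap <- function(available, ideal) {
  stopifnot(is.numeric(available), is.numeric(ideal))
  if (length(available) != length(ideal) &&
      length(available) != 1L && length(ideal) != 1L)
    stop("supply_gap: incompatible lengths")
  available - ideal
}

#' Median of a numeric sample
#'
#' Sorted middle value; for even n, the mean of the two central values.
#' Implemented explicitly because the whole reporting surface is median
#' based (the time variables are right skewed).
#'
#' @param values Non-empty numeric vector; `NA` removed when `na.rm = TRUE`.
#' @param na.rm Drop missing values first.
#' @return The sample median.
#' @export
aggregate_median <- function(values, na.rm = FALSE) {
  if (na.rm) values <- values[!is.na(values)]
  if (length(values) == 0L)
    stop("aggregate_median: empty input")
  if (anyNA(values))
    stop("aggregate_median: missing values present (use na.rm = TRUE)")
  s <- sort(values)
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) %/% 2L] else (s[n %/% 2L] + s[n %/% 2L + 1L]) / 2
}

#' Difference between median time used and median time required
#'
#' @param summary_used,summary_required Median per-person annual minutes for
#'   the same stratum/cadre.
#' @return `summary_used - summary_required` (negative when more time is
#'   required than used).
#' @export
median_time_difference <- function(summary_used, summary_required) {
  stopifnot(is.numeric(summary_used), is.numeric(summary_required))
  summary_used - summary_required
}

#' Round half up
#'
#' Commercial rounding (0.5 always away from zero towards +Inf for positive
#' numbers), used for human-readable tables so that e.g. 13.75 FTE prints
#' as 13.8.  Base R's `round()` rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Reduce per-activity minutes to per-group, per-cadre totals
#'
#' The elicitation instrument records minutes per activity; the supply
#' arithmetic consumes per-age-group annual minutes per cadre.  This reducer
#' sums activity minutes within each age group x cadre cell.
#'
#' @param activities Data frame with columns `activity_id`, `age_group`,
#'   `cadre`, `minutes_used`, `minutes_required`.
#' @return Data frame with columns `age_group`, `cadre`, `minutes_used`,
#'   `minutes_required` (summed).
#' @export
activities_to_group_minutes <- function(activities) {
  req <- c("activity_id", "age_group", "cadre", "minutes_used", "minutes_required")
  miss <- setdiff(req, names(activities))
  if (length(miss))
    stop("activities_to_group_minutes: missing column(s): ",
         paste(miss, collapse = ", "))
  dup <- duplicated(activities[c("age_group", "activity_id")])
  if (any(dup))
    stop("activities_to_group_minutes: duplicate activity_id within age group")
  if (any(activities$minutes_used < 0) || any(activities$minutes_required < 0))
    stop("activities_to_group_minutes: negative minutes")
  agg <- aggregate(
    activities[c("minutes_used", "minutes_required")],
    by = activities[c("age_group", "cadre")],
    FUN = sum
  )
  agg[order(agg$age_group, agg$cadre), , drop = FALSE]
}
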