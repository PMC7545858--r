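#' Yearly mission profile of a HEMS station
#'
#' Counts and average billable durations of the four mission types that a
#' helicopter emergency medical service (HEMS) station flies in one year.
#' Primary missions respond to an incident site; secondary missions are
#' interhospital transfers and typically take longer.
#'
#' @param x Primary missions at daytime (count/year). The cost driver; most
#'   functions sweep over it.
#' @param y Primary missions at nighttime (count/year).
#' @param z Secondary missions at daytime (count/year).
#' @param w Secondary missions at nighttime (count/year).
#' @param b_x,b_y Average billable duration of primary missions, minutes.
#' @param b_z,b_w Average billable duration of secondary missions, minutes.
#'
#' @return An object of class `hems_profile` (a named list).
#' @examples
#' mission_profile(x = 1200, z = 92)
#' @export
mission_profile <- function(x = 0, y = 0, z = 0, w = 0,
                            b_x = 20, b_y = 20, b_z = 45, b_w = 45) {
  counts <- c(x = x, y = y, z = z, w = w)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("mission counts x, y, z, w must be nonnegative integers")
  }
  durations <- c(b_x = b_x, b_y = b_y, b_z = b_z, b_w = b_w)
  if (any(durations <= 0)) {
    abort("billable durations b_x, b_y, b_z, b_w must be positive")
  }
  structure(list(x = x, y = y, z = z, w = w,
                 b_x = b_x, b_y = b_y, b_z = b_z, b_w = b_w),
            class = "hems_profile")
}

#' Jump-fixed maintenance schedule
#'
#' Maintenance of the aircraft is jump-fixed: within an interval the cost is
#' constant, and every time the cumulative activity (starts, engine minutes,
#' winch usages) crosses a multiple of an interval threshold, the interval
#' price falls due. A schedule holds up to four start-dependent and four
#' flight-time-dependent intervals, and up to two winch intervals.
#'
#' Flight-time thresholds are expressed in engine **minutes**.
#'
#' @param start_thresholds,start_costs Start-dependent intervals: starts per
#'   cycle and cost in EUR per triggered cycle.
#' @param flight_thresholds,flight_costs Flight-time-dependent intervals:
#'   engine minutes per cycle and cost in EUR per triggered cycle.
#' @param winch_thresholds,winch_costs Winch intervals: usages per cycle and
#'   cost in EUR; may be empty for aircraft without a hoist.
#'
#' @return An object of class `hems_schedule`: a list of three tibbles
#'   (`starts`, `flighttime`, `winch`) with columns `threshold` and `cost`.
#' @examples
#' maintenance_schedule(
#'   start_thresholds  = c(200, 400, 1200, 2400),
#'   start_costs       = c(4200, 8000, 50000, 100000),
#'   flight_thresholds = c(3000, 6000, 18000, 36000),
#'   flight_costs      = c(1000, 3000, 14000, 40000)
#' )
#' @export
maintenance_schedule <- function(start_thresholds, start_costs,
                                 flight_thresholds, flight_costs,
                                 winch_thresholds = numeric(),
                                 winch_costs = numeric()) {
  one <- function(th, co, max_n, what) {
    if (length(th) != length(co)) {
      abort(sprintf("%s thresholds and costs must have equal length", what))
    }
    if (length(th) > max_n) {
      abort(sprintf("at most %d %s intervals are supported", max_n, what))
    }
    if (length(th) && (any(th <= 0) || any(diff(th) <= 0))) {
      abort(sprintf("%s thresholds must be strictly positive and strictly increasing", what))
    }
    if (any(co < 0)) abort(sprintf("%s interval costs must be nonnegative", what))
    tibble(threshold = as.numeric(th), cost = as.numeric(co))
  }
  structure(list(
    starts     = one(start_thresholds, start_costs, 4L, "start"),
    flighttime = one(flight_thresholds, flight_costs, 4L, "flight-time"),
    winch      = one(winch_thresholds, winch_costs, 2L, "winch")
  ), class = "hems_schedule")
}

#' Special-equipment profile (rescue winch or static rope)
#'
#' Carrying hoists or static ropes changes the flight profile of a share of
#' the primary missions (more starts, longer billable durations), adds
#' dedicated training flights, and adds yearly fixed and personnel cost.
#' With `alpha = 0` the profile is normalised to contribute nothing to any
#' cost term (all remaining fields are zeroed and the correction factors set
#' to 1), so a standard aircraft is simply `special_equipment()`.
#'
#' @param alpha Share of total primary missions flown with special equipment
#'   (0 to 1).
#' @param m Correction factor for starts per special-equipment mission.
#' @param n Correction factor for billable duration of special-equipment
#'   missions.
#' @param r Training starts per year with special equipment (count).
#' @param s Training duration per start, minutes.
#' @param o Additional yearly personnel cost for special equipment, EUR.
#' @param v Additional yearly fixed cost for special equipment, EUR.
#'
#' @return An object of class `hems_special` (a named list).
#' @examples
#' special_equipment(alpha = 0.1, m = 0.5, n = 2, r = 100, s = 60,
#'                   o = 45000, v = 94980)
#' @export
special_equipment <- function(alpha = 0, m = 1, n = 1, r = 0, s = 0,
                              o = 0, v = 0) {
  if (alpha < 0 || alpha > 1) abort("alpha must lie in [0, 1]")
  if (any(c(r, s, o, v) < 0)) abort("r, s, o, v must be nonnegative")
  if (alpha == 0) {
    m <- 1; n <- 1; r <- 0; s <- 0; o <- 0; v <- 0
  } else if (m <= 0 || n <= 0) {
    abort("correction factors m and n must be positive when alpha > 0")
  }
  structure(list(alpha = alpha, m = m, n = n, r = r, s = s, o = o, v = v),
            class = "hems_special")
}

#' Cost parameters of a HEMS station
#'
#' Bundles every parameter of the total-cost and average-cost functions:
#' yearly fixed and personnel cost, variable-cost valuations, the
#' maintenance schedule, the special-equipment profile, the area-based
#' allocation key and the reimbursement tariff.
#'
#' @param a Yearly fixed cost for standard operations, EUR.
#' @param p Yearly personnel cost, EUR.
#' @param q Share of personnel cost attributable to daytime operations
#'   (0 < q <= 1).
#' @param i Valued average medical-material consumption per primary mission,
#'   EUR.
#' @param j Valued average medical-material consumption per secondary
#'   mission, EUR.
#' @param l Valued average fuel consumption per engine minute, EUR/min.
#' @param t Starts per mission (count, >= 1).
#' @param beta Area of operations for primary missions, km^2. Together with
#'   `gamma` it forms the allocation key beta/(beta+gamma) that distributes
#'   fixed and personnel cost onto the primary-mission remit.
#' @param gamma Area of operations for secondary missions, km^2.
#' @param schedule A [maintenance_schedule()].
#' @param special A [special_equipment()] profile.
#' @param price_per_minute Revenue per billable flight minute, EUR (used by
#'   the break-even analysis).
#'
#' @return An object of class `hems_parameters` (a named list).
#' @seealso [total_cost()], [average_primary_cost()], [hems_scenarios()]
#' @export
hems_parameters <- function(a, p, q = 1, i = 120, j = 170, l = 5.83, t = 2,
                            beta = 11550, gamma = 23000,
                            schedule, special = special_equipment(),
                            price_per_minute = 70) {
  if (any(c(a, p, i, j, l) < 0)) abort("a, p, i, j, l must be nonnegative")
  if (t < 1) abort("starts per mission t must be at least 1")
  if (beta <= 0 || gamma <= 0) abort("operation areas beta and gamma must be positive")
  if (q <= 0 || q > 1) abort("daytime personnel share q must lie in (0, 1]")
  if (price_per_minute < 0) abort("price_per_minute must be nonnegative")
  if (!inherits(schedule, "hems_schedule")) abort("schedule must be a maintenance_schedule()")
  if (!inherits(special, "hems_special")) abort("special must be a special_equipment() profile")
  structure(list(a = a, p = p, q = q, i = i, j = j, l = l, t = t,
                 beta = beta, gamma = gamma, schedule = schedule,
                 special = special, price_per_minute = price_per_minute),
            class = "hems_parameters")
}

#' @export
print.hems_parameters <- function(x, ...) {
  cat("<hems_parameters>\n")
  cat(sprintf("  fixed a = %s, personnel p = %s (daytime share q = %.4g)\n",
              format_eur(x$a), format_eur(x$p), x$q))
  cat(sprintf("  material i/j = %s/%s, fuel l = %s per min, t = %g starts/mission\n",
              format_eur(x$i), format_eur(x$j), format_eur(x$l), x$t))
  cat(sprintf("  allocation key beta/(beta+gamma) = %.4f, tariff P = %s per min\n",
              x$beta / (x$beta + x$gamma), format_eur(x$price_per_minute)))
  if (x$special$alpha > 0) {
    cat(sprintf("  special equipment: alpha = %.2f, m = %g, n = %g, r = %g, s = %g, o+v = %s\n",
                x$special$alpha, x$special$m, x$special$n, x$special$r,
                x$special$s, format_eur(x$special$o + x$special$v)))
  }
  invisible(x)
}

#' @export
print.hems_profile <- function(x, ...) {
  cat(sprintf("<hems_profile> x=%g y=%g z=%g w=%g (b: %g/%g/%g/%g min)\n",
              x$x, x$y, x$z, x$w, x$b_x, x$b_y, x$b_z, x$b_w))
  invisible(x)
}

# replace the free variable x of a base profile
set_missions <- function(profile, x) {
  mission_profile(x = x, y = profile$y, z = profile$z, w = profile$w,
                  b_x = profile$b_x, b_y = profile$b_y,
                  b_z = profile$b_z, b_w = profile$b_w)
}
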