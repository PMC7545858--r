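#' Total yearly starts of the aircraft
#'
#' Starts drive the start-dependent maintenance intervals. Special-equipment
#' missions change the starts per mission by the correction factor `m`
#' (e.g. static-rope rescues need three starts instead of two), and
#' special-equipment training flights add `r` starts.
#'
#' @param params A [hems_parameters()] object.
#' @param profile A [mission_profile()].
#' @param x Optional vector of primary daytime mission counts overriding
#'   `profile$x` (vectorised evaluation for sweeps).
#'
#' @return Starts per year, `(1-alpha)*t*x + alpha*x*t*m + t*(y+z+w) + r`
#'   with `r` the special-equipment training starts.
#' @export
total_starts <- function(params, profile, x = profile$x) {
  sp <- params$special
  sp$r + (1 - sp$alpha) * params$t * x + sp$alpha * x * params$t * sp$m +
    params$t * (profile$y + profile$z + profile$w)
}

#' Yearly engine minutes, split by origin
#'
#' Engine runtime drives fuel consumption and the flight-time maintenance
#' intervals. Special-equipment missions fly `n` times the standard primary
#' duration; training flights add `r*s` minutes.
#'
#' @inheritParams total_starts
#' @return A tibble with one row per element of `x` and columns `training`
#'   (`r*s`), `primary` (`(1-alpha)*x*b_x + alpha*b_x*x*n`), `other`
#'   (`y*b_y + z*b_z + w*b_w`) and `total`, all in minutes/year.
#' @examples
#' sc <- hems_scenarios("1.I")
#' engine_minutes(sc$params[[1]], sc$base_profile[[1]], x = 1200)
#' @export
engine_minutes <- function(params, profile, x = profile$x) {
  sp <- params$special
  training <- rep(sp$r * sp$s, length(x))
  primary <- (1 - sp$alpha) * x * profile$b_x + sp$alpha * profile$b_x * x * sp$n
  other <- rep(profile$y * profile$b_y + profile$z * profile$b_z +
                 profile$w * profile$b_w, length(x))
  tibble(training = training, primary = primary, other = other,
         total = training + primary + other)
}

#' Total yearly cost of HEMS operations
#'
#' Evaluates the full-cost function: fixed cost `a`, personnel cost `p`,
#' special-equipment add-ons `o` and `v`, jump-fixed maintenance triggered
#' by starts, engine minutes and winch usages (see [step_cost()]), medical
#' material valued per mission, and fuel valued per engine minute. Fuel is
#' charged on all engine minutes including special-equipment training
#' flights.
#'
#' @inheritParams total_starts
#' @param secondary_material `"formula"` values secondary-mission medical
#'   material at `j` (the default); `"table"` values it at `i`, the
#'   convention under which the published scenario-table totals were
#'   computed (they sit exactly `(j - i) * (z + w)` below the
#'   formula-faithful value).
#'
#' @return A tibble with one row per element of `x` and the cost components
#'   `fixed`, `personnel`, `special_personnel`, `special_fixed`,
#'   `maintenance_starts`, `maintenance_flighttime`, `maintenance_winch`,
#'   `material`, `fuel` and their sum `total`, all in EUR/year.
#' @examples
#' sc <- hems_scenarios("1.I")
#' total_cost(sc$params[[1]], sc$base_profile[[1]], x = 1200)$total
#' # 1697546.2
#' @export
total_cost <- function(params, profile, x = profile$x,
                       secondary_material = c("formula", "table")) {
  secondary_material <- match.arg(secondary_material)
  sp <- params$special
  mins <- engine_minutes(params, profile, x)
  j_eff <- if (secondary_material == "table") params$i else params$j
  out <- tibble(
    fixed = rep(params$a, length(x)),
    personnel = rep(params$p, length(x)),
    special_personnel = rep(sp$o, length(x)),
    special_fixed = rep(sp$v, length(x)),
    maintenance_starts = step_cost(total_starts(params, profile, x),
                                   params$schedule$starts),
    maintenance_flighttime = step_cost(mins$total, params$schedule$flighttime),
    maintenance_winch = step_cost(sp$alpha * x + sp$r, params$schedule$winch),
    material = params$i * (x + profile$y) + j_eff * (profile$z + profile$w),
    fuel = params$l * mins$total
  )
  out$total <- rowSums(out)
  out
}

# area-based allocation key: share of fixed and personnel cost attributed
# to the primary-mission remit
primary_area_share <- function(params) {
  params$beta / (params$beta + params$gamma)
}

#' Average cost per primary daytime mission
#'
#' Allocates the yearly cost onto one primary daytime mission: fixed and
#' personnel cost enter through the area key `beta/(beta+gamma)` spread
#' over primary billable minutes; start- and flight-time maintenance enters
#' in proportion to the primary (plus training) share of engine minutes;
#' winch maintenance and the special-equipment add-ons `o + v` are spread
#' over the special-equipment missions `CEIL(alpha*x)` and weighted by
#' `alpha`; variable cost is the per-mission fuel and material.
#'
#' @inheritParams total_cost
#' @param fixed_denominator Minutes over which the allocated fixed cost is
#'   spread: `"primary"` (the default) uses all primary billable minutes
#'   `x*b_x + y*b_y`; `"daytime"` uses the daytime billable minutes
#'   `x*b_x + z*b_z`, the convention that reproduces the published
#'   dual-use (variation III) table cells.
#' @param daytime_personnel_cost Optional override, EUR: replaces the
#'   daytime personnel cost `p*q` in the personnel component. The published
#'   24-hour-scenario personnel cells match the corresponding 12-hour
#'   personnel sums rather than `p*q`; passing those sums here replicates
#'   the tables.
#'
#' @return A tibble with one row per element of `x` and columns
#'   `avg_fixed`, `avg_personnel`, `avg_maintenance`, `avg_variable` and
#'   their sum `avg_total`, all in EUR per primary mission. Components are
#'   kept at full floating precision; round only for presentation.
#' @examples
#' sc <- hems_scenarios("1.I")
#' round(average_primary_cost(sc$params[[1]], sc$base_profile[[1]], x = 1200), 2)
#' # avg_fixed 88.16, avg_personnel 201.69, avg_maintenance 236.96,
#' # avg_variable 236.60, avg_total 763.41
#' @export
average_primary_cost <- function(params, profile, x = profile$x,
                                 fixed_denominator = c("primary", "daytime"),
                                 daytime_personnel_cost = NULL) {
  fixed_denominator <- match.arg(fixed_denominator)
  if (any(x < 1)) abort("average cost per primary mission requires x >= 1")
  sp <- params$special
  share <- primary_area_share(params)
  mins <- engine_minutes(params, profile, x)

  denom_fixed <- switch(fixed_denominator,
    primary = x * profile$b_x + profile$y * profile$b_y,
    daytime = x * profile$b_x + profile$z * profile$b_z
  )
  special_per_mission <- if (sp$alpha > 0) {
    (sp$o + sp$v) / ceiling(sp$alpha * x) * sp$alpha
  } else {
    rep(0, length(x))
  }
  avg_fixed <- params$a * share / denom_fixed * profile$b_x + special_per_mission

  p_day <- daytime_personnel_cost %||% (params$p * params$q)
  avg_personnel <- p_day * share / (x * profile$b_x) * profile$b_x

  maint <- step_cost(total_starts(params, profile, x), params$schedule$starts) +
    step_cost(mins$total, params$schedule$flighttime)
  winch <- step_cost(sp$alpha * x + sp$r, params$schedule$winch)
  winch_per_mission <- if (sp$alpha > 0) {
    winch / ceiling(sp$alpha * x) * sp$alpha
  } else {
    rep(0, length(x))
  }
  avg_maintenance <- maint / mins$total * (mins$training + mins$primary) / x +
    winch_per_mission

  avg_variable <- params$l * ((1 - sp$alpha) * profile$b_x +
                                sp$alpha * profile$b_x * sp$n) + params$i

  tibble(avg_fixed = avg_fixed, avg_personnel = avg_personnel,
         avg_maintenance = avg_maintenance,
         avg_variable = rep(avg_variable, length(x)),
         avg_total = avg_fixed + avg_personnel + avg_maintenance + avg_variable)
}

#' Yearly cost allocated to the primary-mission remit
#'
#' The share of total cost carried by primary daytime missions: the
#' area-key-allocated fixed and personnel cost, the primary-minute share of
#' start and flight-time maintenance, winch maintenance and the
#' special-equipment add-ons, plus the primary variable cost. Equals
#' `x` times the (unrounded) average cost per primary mission.
#'
#' @inheritParams average_primary_cost
#' @return EUR/year, one value per element of `x`.
#' @export
primary_mission_total_cost <- function(params, profile, x = profile$x,
                                       fixed_denominator = c("primary", "daytime"),
                                       daytime_personnel_cost = NULL) {
  avg <- average_primary_cost(params, profile, x,
                              fixed_denominator = fixed_denominator,
                              daytime_personnel_cost = daytime_personnel_cost)
  x * avg$avg_total
}
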