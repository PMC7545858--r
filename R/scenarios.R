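#' Built-in scenario variations
#'
#' The fifteen scenario variations of the cost study: three operating-hour
#' scenarios (1 = 12 h, 2 = 16 h, 3 = 24 h) crossed with five variations
#' (I initial, II high cost assumption, III dual-use services, IV static
#' rope, V rescue winch). Parameter sets are shipped as a YAML data file
#' and loaded with [read_scenarios_yaml()].
#'
#' All variations share the constants i = 120, j = 170 EUR of medical
#' material, l = 5.83 EUR per engine minute of fuel, t = 2 starts per
#' mission, the allocation areas beta = 11550 and gamma = 23000 km^2, and
#' billable durations of 20 min (primary) and 45 min (secondary). The
#' 24-hour scenario adds y = 120 nighttime primary and w = 140 nighttime
#' secondary missions; the dual-use variation raises daytime secondary
#' missions z from 92 to 400.
#'
#' @param ids Optional character vector of variation ids (e.g. `"1.I"`) to
#'   select; unknown ids raise an error. `NULL` returns all fifteen.
#'
#' @return A tibble with one row per variation: `id`, `scenario`,
#'   `variation`, `hours`, `label`, plus list-columns `params`
#'   ([hems_parameters()]) and `base_profile` ([mission_profile()] with the
#'   fixed y, z, w and x = 0, the free variable).
#' @examples
#' hems_scenarios(c("1.I", "1.II"))
#' @export
hems_scenarios <- function(ids = NULL) {
  all <- read_scenarios_yaml(system.file("extdata", "scenarios.yaml",
                                         package = "hemscost", mustWork = TRUE))
  if (is.null(ids)) return(all)
  missing <- setdiff(ids, all$id)
  if (length(missing)) {
    abort(sprintf("unknown scenario id(s): %s", paste(missing, collapse = ", ")))
  }
  all[match(ids, all$id), ]
}

#' Scenario cost table
#'
#' Evaluates average cost per primary mission, primary-allocated yearly
#' cost and total yearly cost for each scenario variation at each primary
#' daytime mission count, mirroring the column layout of the published
#' scenario tables.
#'
#' @param scenarios A scenarios tibble as returned by [hems_scenarios()]
#'   (or any subset of its rows).
#' @param x Primary daytime mission counts to evaluate, each >= 1.
#' @inheritParams total_cost
#' @inheritParams average_primary_cost
#'
#' @return A tibble with columns `scenario` (the variation id), `x`, `y`,
#'   `z`, `w`, `avg_fixed`, `avg_personnel`, `avg_maintenance`,
#'   `avg_variable`, `avg_total`, `primary_total`, `total` (EUR,
#'   unrounded).
#' @examples
#' cost_table(hems_scenarios("1.I"), x = c(900, 1200, 1500))
#' @export
cost_table <- function(scenarios, x = c(900, 1200, 1500),
                       secondary_material = c("formula", "table"),
                       fixed_denominator = c("primary", "daytime"),
                       daytime_personnel_cost = NULL) {
  if (!length(x) || any(x < 1)) abort("x values must be a nonempty set of counts >= 1")
  secondary_material <- match.arg(secondary_material)
  fixed_denominator <- match.arg(fixed_denominator)
  pmap(scenarios[c("id", "params", "base_profile")], function(id, params, base_profile) {
    avg <- average_primary_cost(params, base_profile, x = x,
                                fixed_denominator = fixed_denominator,
                                daytime_personnel_cost = daytime_personnel_cost)
    tibble(scenario = id, x = x,
           y = base_profile$y, z = base_profile$z, w = base_profile$w,
           !!!avg,
           primary_total = x * avg$avg_total,
           total = total_cost(params, base_profile, x = x,
                              secondary_material = secondary_material)$total)
  }) |> list_rbind()
}

#' Average-cost curve over mission counts
#'
#' Dense per-integer evaluation of the average cost per primary mission,
#' the fixed-cost digression curve. Missions are indivisible, so the curve
#' is defined on integers only. Upward jumps — mission counts whose added
#' starts or engine minutes trigger a new maintenance interval — are
#' flagged; between flagged jumps the curve is strictly decreasing.
#'
#' @inheritParams cost_table
#' @param x_min,x_max Integer range of primary daytime mission counts,
#'   `1 <= x_min <= x_max`.
#'
#' @return A tibble of class `hems_curve` with columns `scenario`, `x`,
#'   `avg_total` and `jump` (`TRUE` where the average cost increased
#'   relative to `x - 1`).
#' @examples
#' crv <- average_cost_curve(hems_scenarios("1.I"), 1100, 1200)
#' crv[crv$jump, ]
#' @export
average_cost_curve <- function(scenarios, x_min = 1, x_max = 2000,
                               fixed_denominator = c("primary", "daytime"),
                               daytime_personnel_cost = NULL) {
  if (x_min < 1 || x_max < x_min) abort("need 1 <= x_min <= x_max")
  fixed_denominator <- match.arg(fixed_denominator)
  xs <- seq.int(ceiling(x_min), floor(x_max))
  out <- pmap(scenarios[c("id", "params", "base_profile")],
              function(id, params, base_profile) {
    avg <- average_primary_cost(params, base_profile, x = xs,
                                fixed_denominator = fixed_denominator,
                                daytime_personnel_cost = daytime_personnel_cost)
    tibble(scenario = id, x = xs, avg_total = avg$avg_total,
           jump = c(FALSE, diff(avg$avg_total) > 0))
  }) |> list_rbind()
  class(out) <- c("hems_curve", class(out))
  out
}

#' Random valid scenario for property testing
#'
#' Draws a random but invariant-respecting parameter set and mission
#' profile: random fixed, personnel and variable cost levels, random
#' strictly increasing maintenance schedules (up to 4/4/2 intervals), and
#' with probability 1/2 a special-equipment profile. Uses the current RNG
#' state; seed with [set.seed()] for reproducibility.
#'
#' @return A list with elements `params` ([hems_parameters()]) and
#'   `profile` ([mission_profile()]).
#' @examples
#' set.seed(1)
#' sc <- random_scenario()
#' total_cost(sc$params, sc$profile)$total
#' @export
random_scenario <- function() {
  rand_intervals <- function(n_max, th_lo, th_hi, cost_hi) {
    n <- sample.int(n_max, 1)
    th <- sort(sample(seq(th_lo, th_hi), n))
    list(th = th, co = round(runif(n, 0, cost_hi) * cumsum(rep(1, n))))
  }
  st <- rand_intervals(4, 50, 3000, 20000)
  fl <- rand_intervals(4, 500, 40000, 20000)
  has_winch <- runif(1) < 0.5
  wi <- if (has_winch) rand_intervals(2, 1, 500, 5000) else list(th = numeric(), co = numeric())
  special <- if (runif(1) < 0.5) {
    special_equipment(alpha = runif(1, 0.01, 0.3), m = runif(1, 0.5, 3),
                      n = runif(1, 0.5, 3), r = sample(0:400, 1),
                      s = sample(5:90, 1), o = runif(1, 0, 5e4),
                      v = runif(1, 0, 1e5))
  } else {
    special_equipment()
  }
  params <- hems_parameters(
    a = runif(1, 1e5, 1e6), p = runif(1, 3e5, 2e6), q = runif(1, 0.3, 1),
    i = runif(1, 50, 300), j = runif(1, 50, 300), l = runif(1, 1, 12),
    t = sample(1:3, 1), beta = runif(1, 5e3, 5e4), gamma = runif(1, 5e3, 5e4),
    schedule = maintenance_schedule(st$th, st$co, fl$th, fl$co, wi$th, wi$co),
    special = special,
    price_per_minute = runif(1, 30, 90)
  )
  profile <- mission_profile(
    x = sample(1:2000, 1), y = sample(0:300, 1),
    z = sample(0:500, 1), w = sample(0:300, 1),
    b_x = runif(1, 10, 40), b_y = runif(1, 10, 40),
    b_z = runif(1, 20, 90), b_w = runif(1, 20, 90)
  )
  list(params = params, profile = profile)
}
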