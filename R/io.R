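#' Currency formatting and parsing
#'
#' `format_eur()` renders EUR amounts with two decimals, half-up rounding,
#' a `.` decimal separator and no thousands grouping. `parse_eur()` reads
#' both that plain format and German-style grouping (`"1.697.546,20"`),
#' which is normalised on input and never emitted.
#'
#' @param x Numeric amounts (format) or character amounts (parse).
#' @return A character vector (`format_eur`) or numeric vector
#'   (`parse_eur`).
#' @examples
#' format_eur(1697546.195)        # "1697546.20"
#' parse_eur("1.697.546,20")      # 1697546.2
#' parse_eur("1697546.20")        # 1697546.2
#' @export
format_eur <- function(x) {
  sprintf("%.2f", floor(abs(x) * 100 + 0.5) / 100 * sign(x))
}

#' @rdname format_eur
#' @export
parse_eur <- function(x) {
  x <- trimws(gsub("€", "", x))
  german <- grepl(",", x)
  x[german] <- gsub(",", ".", gsub("\\.", "", x[german]))
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out)) abort(sprintf("cannot parse currency value(s): %s",
                                paste(x[is.na(out)], collapse = ", ")))
  out
}

# accept "4/7"-style fractions for exact shares in config files
parse_share <- function(x) {
  if (is.character(x) && grepl("/", x)) {
    parts <- as.numeric(strsplit(x, "/", fixed = TRUE)[[1]])
    return(parts[1] / parts[2])
  }
  as.numeric(x)
}

# short symbol -> long alias accepted in config files
.param_aliases <- c(
  a = "fixed_costs_eur", p = "personnel_costs_eur",
  q = "daytime_personnel_share", i = "material_primary_eur",
  j = "material_secondary_eur", l = "fuel_eur_per_minute",
  t = "starts_per_mission", beta = "primary_area_km2",
  gamma = "secondary_area_km2", price_per_minute = "price_per_minute_eur",
  alpha = "special_share", m = "start_correction_factor",
  n = "duration_correction_factor", r = "training_starts",
  s = "training_minutes_per_start", o = "special_personnel_eur",
  v = "special_fixed_eur"
)

# resolve a key that may be given under its symbol or its long alias
pick_key <- function(lst, key, default = NULL) {
  alias <- .param_aliases[[key]] %||% ""
  lst[[key]] %||% lst[[alias]] %||% default
}

#' Serialize cost parameters to and from plain lists
#'
#' The list representation is the YAML/JSON config dialect: keys are the
#' model's symbol names (`a`, `p`, `q`, ...) and long aliases
#' (`fixed_costs_eur`, ...) are accepted on input. Shares such as `q` may
#' be written as exact fractions (`"4/7"`).
#'
#' @param params A [hems_parameters()] object.
#' @param lst A named list in the config dialect.
#' @return `parameters_to_list()` returns a named list;
#'   `parameters_from_list()` returns a [hems_parameters()] object.
#' @export
parameters_to_list <- function(params) {
  sp <- params$special
  sch <- params$schedule
  list(
    a = params$a, p = params$p, q = params$q, i = params$i, j = params$j,
    l = params$l, t = params$t, beta = params$beta, gamma = params$gamma,
    price_per_minute = params$price_per_minute,
    special = list(alpha = sp$alpha, m = sp$m, n = sp$n, r = sp$r, s = sp$s,
                   o = sp$o, v = sp$v),
    maintenance = list(
      start_thresholds = sch$starts$threshold, start_costs = sch$starts$cost,
      flight_thresholds = sch$flighttime$threshold,
      flight_costs = sch$flighttime$cost,
      winch_thresholds = sch$winch$threshold, winch_costs = sch$winch$cost
    )
  )
}

#' @rdname parameters_to_list
#' @export
parameters_from_list <- function(lst) {
  sp <- lst$special %||% list()
  mt <- lst$maintenance %||% abort("config is missing the 'maintenance' schedule block")
  num <- function(x) if (is.null(x)) numeric() else as.numeric(x)
  hems_parameters(
    a = pick_key(lst, "a") %||% abort("config is missing 'a' (fixed_costs_eur)"),
    p = pick_key(lst, "p") %||% abort("config is missing 'p' (personnel_costs_eur)"),
    q = parse_share(pick_key(lst, "q", 1)),
    i = pick_key(lst, "i", 120), j = pick_key(lst, "j", 170),
    l = pick_key(lst, "l", 5.83), t = pick_key(lst, "t", 2),
    beta = pick_key(lst, "beta", 11550), gamma = pick_key(lst, "gamma", 23000),
    price_per_minute = pick_key(lst, "price_per_minute", 70),
    schedule = maintenance_schedule(
      num(mt$start_thresholds), num(mt$start_costs),
      num(mt$flight_thresholds), num(mt$flight_costs),
      num(mt$winch_thresholds), num(mt$winch_costs)
    ),
    special = special_equipment(
      alpha = parse_share(pick_key(sp, "alpha", 0)),
      m = pick_key(sp, "m", 1), n = pick_key(sp, "n", 1),
      r = pick_key(sp, "r", 0), s = pick_key(sp, "s", 0),
      o = pick_key(sp, "o", 0), v = pick_key(sp, "v", 0)
    )
  )
}

#' Read and write scenario fixture files
#'
#' Scenario variations are stored in a YAML file with one entry per
#' variation (`id`, `scenario`, `variation`, `hours`, `label`, `params`,
#' `profile`); the `params` block uses the config dialect of
#' [parameters_to_list()]. Writing and re-reading a scenarios tibble is
#' lossless.
#'
#' @param path Path of the YAML file.
#' @param scenarios A scenarios tibble ([hems_scenarios()] layout).
#' @return `read_scenarios_yaml()` returns a scenarios tibble;
#'   `write_scenarios_yaml()` returns `path` invisibly.
#' @export
read_scenarios_yaml <- function(path) {
  entries <- yaml::read_yaml(path)
  map(entries, function(e) {
    pr <- e$profile %||% list()
    tibble(
      id = e$id, scenario = as.integer(e$scenario), variation = e$variation,
      hours = as.numeric(e$hours), label = e$label,
      params = list(parameters_from_list(e$params)),
      base_profile = list(mission_profile(
        x = pr$x %||% 0, y = pr$y %||% 0, z = pr$z %||% 0, w = pr$w %||% 0,
        b_x = pr$b_x %||% 20, b_y = pr$b_y %||% 20,
        b_z = pr$b_z %||% 45, b_w = pr$b_w %||% 45
      ))
    )
  }) |> list_rbind()
}

#' @rdname read_scenarios_yaml
#' @export
write_scenarios_yaml <- function(scenarios, path) {
  entries <- pmap(scenarios, function(id, scenario, variation, hours, label,
                                      params, base_profile) {
    list(id = id, scenario = scenario, variation = variation, hours = hours,
         label = label, params = parameters_to_list(params),
         profile = base_profile[c("x", "y", "z", "w", "b_x", "b_y", "b_z", "b_w")])
  })
  yaml::write_yaml(entries, path, precision = 16L)
  invisible(path)
}

#' Load a run configuration
#'
#' Reads a YAML run configuration and applies defaults: all scenarios, the
#' table grid `x = c(900, 1200, 1500)`, curve sweep 900 to 1500, tariff
#' P = 70 EUR/min, formula-faithful secondary material valuation and the
#' primary-minutes fixed-cost denominator. Unknown scenario ids and
#' invalid mode values are rejected with the offending key named.
#'
#' @param path Path of the YAML config file.
#' @return A list of class `hems_config` with elements `scenarios`
#'   (resolved tibble), `x`, `x_range`, `price_per_minute`,
#'   `secondary_material`, `fixed_denominator`, `daytime_personnel_cost`,
#'   `output_dir`, `verbose`.
#' @export
read_hems_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path) %||% list()
  ids <- cfg$scenarios %||% "all"
  sc <- if (identical(ids, "all")) hems_scenarios() else hems_scenarios(as.character(ids))
  x <- as.numeric(cfg$x %||% c(900, 1200, 1500))
  if (!length(x) || any(x < 1)) abort("config key 'x': values must be >= 1")
  x_range <- as.numeric(cfg$x_range %||% c(900, 1500))
  if (length(x_range) != 2 || x_range[1] > x_range[2] || x_range[1] < 1) {
    abort("config key 'x_range': expected c(min, max) with 1 <= min <= max")
  }
  price <- pick_key(cfg, "price_per_minute", 70)
  if (is.character(price)) price <- parse_eur(price)
  sm <- cfg$secondary_material %||% "formula"
  if (!sm %in% c("formula", "table")) {
    abort("config key 'secondary_material': must be 'formula' or 'table'")
  }
  fd <- cfg$fixed_denominator %||% "primary"
  if (!fd %in% c("primary", "daytime")) {
    abort("config key 'fixed_denominator': must be 'primary' or 'daytime'")
  }
  structure(list(
    scenarios = sc, x = x, x_range = x_range, price_per_minute = price,
    secondary_material = sm, fixed_denominator = fd,
    daytime_personnel_cost = cfg$daytime_personnel_cost,
    output_dir = cfg$output_dir %||% ".",
    verbose = isTRUE(cfg$verbose)
  ), class = "hems_config")
}

#' Write a cost table as CSV
#'
#' Currency columns are written with two decimals, `.` decimal separator
#' and no grouping; identical inputs produce byte-identical files.
#'
#' @param tbl A tibble from [cost_table()], [average_cost_curve()] or
#'   [tidy()] of a break-even object.
#' @param path Output file; `""` writes to standard output.
#' @return `path`, invisibly.
#' @export
write_cost_table <- function(tbl, path) {
  eur_cols <- intersect(names(tbl),
                        c("avg_fixed", "avg_personnel", "avg_maintenance",
                          "avg_variable", "avg_total", "primary_total",
                          "total", "revenue", "total_cost", "profit",
                          "printed", "computed", "diff"))
  out <- mutate(as_tibble(tbl), across(all_of(eur_cols), format_eur))
  if (identical(path, "")) {
    utils::write.csv(out, stdout(), row.names = FALSE, quote = FALSE)
  } else {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
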