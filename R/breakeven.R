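#' Yearly revenue from billable flight minutes
#'
#' Revenue is the tariff per billable engine minute times all billable
#' mission minutes. Special-equipment training flights are not billable
#' and earn nothing.
#'
#' @inheritParams total_starts
#' @param price Tariff per billable flight minute, EUR; defaults to the
#'   parameter set's `price_per_minute`.
#' @return EUR/year, one value per element of `x`:
#'   `P * ((1-alpha)*x*b_x + alpha*b_x*x*n + y*b_y + z*b_z + w*b_w)`.
#' @examples
#' sc <- hems_scenarios("1.I")
#' revenue(sc$params[[1]], sc$base_profile[[1]], x = 1200)  # 1969800
#' @export
revenue <- function(params, profile, x = profile$x,
                    price = params$price_per_minute) {
  if (price < 0) abort("price must be nonnegative")
  sp <- params$special
  billable <- (1 - sp$alpha) * x * profile$b_x +
    sp$alpha * profile$b_x * x * sp$n +
    profile$y * profile$b_y + profile$z * profile$b_z + profile$w * profile$b_w
  price * billable
}

#' Break-even analysis of HEMS operations
#'
#' Scans profit = revenue - total cost over integer primary daytime mission
#' counts. Because maintenance cost is jump-fixed, profit can turn positive
#' and then fall back below zero when the next maintenance interval is
#' triggered; such transient crossings are reported separately from the
#' sustainable break-even point, the smallest `x` at which profit is
#' nonnegative and stays nonnegative for every larger `x` in the scanned
#' range. Equality counts as breaking even.
#'
#' @inheritParams cost_table
#' @param price Tariff per billable flight minute, EUR. `NULL` (default)
#'   uses each variation's `price_per_minute`.
#' @param x_range Ascending integer mission counts to scan.
#'
#' @return An object of class `hems_breakeven` with components
#'   `curve` (tibble `scenario`, `x`, `revenue`, `total_cost`, `profit`)
#'   and `summary` (tibble `scenario`, `price`, `x_star`, `transient`
#'   (list-column of transient crossing counts), `status`). [tidy()]
#'   returns the curve, [glance()] the summary, and [autoplot()] draws
#'   cost and revenue against mission count.
#' @examples
#' be <- break_even(hems_scenarios("1.I"), price = 70,
#'                  secondary_material = "table")
#' glance(be)$x_star  # 800
#' @export
break_even <- function(scenarios, price = NULL, x_range = 1:2000,
                       secondary_material = c("formula", "table")) {
  if (!length(x_range) || any(x_range < 1) || is.unsorted(x_range, strictly = TRUE)) {
    abort("x_range must be a nonempty ascending sequence of counts >= 1")
  }
  secondary_material <- match.arg(secondary_material)
  pieces <- pmap(scenarios[c("id", "params", "base_profile")],
                 function(id, params, base_profile) {
    P <- price %||% params$price_per_minute
    rev <- revenue(params, base_profile, x = x_range, price = P)
    cost <- total_cost(params, base_profile, x = x_range,
                       secondary_material = secondary_material)$total
    profit <- rev - cost
    ok <- profit >= 0
    crossings <- x_range[ok & !c(FALSE, ok[-length(ok)])]
    x_star <- if (length(ok) && ok[length(ok)]) {
      runs <- rle(ok)
      x_range[length(ok) - runs$lengths[length(runs$lengths)] + 1L]
    } else {
      NA_real_
    }
    transient <- crossings[is.na(x_star) | crossings < x_star]
    list(
      curve = tibble(scenario = id, x = x_range, revenue = rev,
                     total_cost = cost, profit = profit),
      summary = tibble(scenario = id, price = P, x_star = x_star,
                       transient = list(transient),
                       status = if (is.na(x_star)) "no break-even in range" else "break-even")
    )
  })
  structure(list(curve = list_rbind(map(pieces, "curve")),
                 summary = list_rbind(map(pieces, "summary")),
                 secondary_material = secondary_material),
            class = "hems_breakeven")
}

#' @export
print.hems_breakeven <- function(x, ...) {
  cat("<hems_breakeven> profit scan over x =",
      min(x$curve$x), "...", max(x$curve$x),
      sprintf("(secondary material: %s)\n", x$secondary_material))
  for (k in seq_len(nrow(x$summary))) {
    s <- x$summary[k, ]
    tr <- s$transient[[1]]
    cat(sprintf("  %s at %s EUR/min: %s%s\n", s$scenario, format_eur(s$price),
                if (is.na(s$x_star)) s$status
                else sprintf("sustainable break-even at x* = %d", as.integer(s$x_star)),
                if (length(tr)) sprintf(" (transient crossings: %s)",
                                        paste(tr, collapse = ", ")) else ""))
  }
  invisible(x)
}

#' @describeIn break_even profit curve as a tibble.
#' @param x,object A `hems_breakeven` object.
#' @param ... Unused.
#' @export
tidy.hems_breakeven <- function(x, ...) x$curve

#' @describeIn break_even one-row-per-scenario summary with `x_star`,
#'   transient crossings (comma-separated string) and status.
#' @export
glance.hems_breakeven <- function(x, ...) {
  mutate(x$summary,
         transient = map_chr(.data$transient, \(tr) paste(tr, collapse = ",")))
}

#' @describeIn break_even cost and revenue curves with the sustainable
#'   break-even point marked.
#' @export
autoplot.hems_breakeven <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curve, c("revenue", "total_cost"),
                              names_to = "series", values_to = "eur")
  marks <- filter(object$summary, !is.na(.data$x_star)) |>
    left_join(object$curve, by = "scenario") |>
    filter(.data$x == .data$x_star)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$eur,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$x_star),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = "primary daytime missions x", y = "EUR / year",
                  colour = NULL,
                  title = "Break-even analysis",
                  subtitle = "dashed line: sustainable break-even point")
}

#' @importFrom purrr map_chr
NULL
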