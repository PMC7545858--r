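#' Re-check the published scenario-table cells
#'
#' Recomputes every cell of the three published cost-overview tables (15
#' variations at x = 900, 1200, 1500) from the built-in parameter sets and
#' compares against the printed values, which ship with the package as a
#' plain-text transcription. The computation uses the conventions that the
#' published tables themselves follow where those are documented and
#' consistent: total cost with secondary material valued at `i`
#' (`secondary_material = "table"`) and the daytime fixed-cost denominator
#' for the dual-use variation III. All other cells are evaluated
#' formula-faithfully, so the `computed` column of a deviating cell is the
#' formula-faithful alternative to the printed number.
#'
#' Three groups of printed cells are known not to follow the printed
#' equations and are annotated as known deviations rather than failures:
#' the average maintenance cells of the special-equipment variations IV
#' and V; the 24-hour scenario's average personnel cells (which match the
#' 12-hour personnel sums instead of `p * q`); and the dual-use
#' variation's total-cost column (whose printed values count the
#' additional secondary missions only in the maintenance term, not in
#' material or fuel).
#'
#' @param tolerance Match tolerance in EUR, applied per cell.
#' @return A tibble with one row per printed cell: `scenario`, `x`,
#'   `cell`, `printed`, `computed`, `diff`, `matched` and `note`
#'   (`"known deviation: ..."` where applicable). Attribute `"summary"`
#'   holds the match counts.
#' @examples
#' v <- hems_validate()
#' attr(v, "summary")
#' @export
hems_validate <- function(tolerance = 0.01) {
  printed <- readr::read_csv(
    system.file("extdata", "printed_cost_tables.csv", package = "hemscost",
                mustWork = TRUE),
    show_col_types = FALSE)
  scenarios <- hems_scenarios()
  computed <- pmap(scenarios[c("id", "variation", "params", "base_profile")],
                   function(id, variation, params, base_profile) {
    cost_table(tibble(id = id, params = list(params),
                      base_profile = list(base_profile)),
               x = c(900, 1200, 1500),
               secondary_material = "table",
               fixed_denominator = if (variation == "III") "daytime" else "primary")
  }) |> list_rbind()

  cells <- c("avg_fixed", "avg_personnel", "avg_maintenance", "avg_variable",
             "avg_total", "primary_total", "total")
  long_p <- tidyr::pivot_longer(printed, all_of(cells),
                                names_to = "cell", values_to = "printed")
  long_c <- tidyr::pivot_longer(select(computed, -c("y", "z", "w")),
                                all_of(cells),
                                names_to = "cell", values_to = "computed")
  out <- left_join(long_p, long_c, by = c("scenario", "x", "cell")) |>
    mutate(
      diff = .data$computed - .data$printed,
      matched = abs(.data$diff) <= tolerance,
      variation = sub("^[0-9]+\\.", "", .data$scenario),
      hours24 = grepl("^3\\.", .data$scenario),
      note = dplyr::case_when(
        matched ~ "",
        variation %in% c("IV", "V") & cell == "total" ~
          "known deviation: printed special-equipment totals exclude fuel on training flights (and use an undocumented winch schedule for V)",
        variation %in% c("IV", "V") & cell %in%
          c("avg_maintenance", "avg_total", "primary_total") ~
          "known deviation: special-equipment maintenance cells do not follow the printed equations",
        hours24 & cell %in% c("avg_personnel", "avg_total", "primary_total") ~
          "known deviation: 24h personnel cells match the 12h personnel sums rather than p*q",
        variation == "III" & cell == "total" ~
          "known deviation: dual-use totals count the added secondary missions only in maintenance",
        TRUE ~ "unexplained deviation"
      )
    ) |>
    select(all_of(c("scenario", "x", "cell", "printed", "computed", "diff",
                    "matched", "note")))
  attr(out, "summary") <- list(
    n_cells = nrow(out),
    n_matched = sum(out$matched),
    n_known_deviation = sum(!out$matched & startsWith(out$note, "known deviation")),
    n_unexplained = sum(out$note == "unexplained deviation"),
    tolerance = tolerance
  )
  out
}
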