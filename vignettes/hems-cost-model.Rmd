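---
title: "A full-cost model for helicopter emergency medical services"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A full-cost model for helicopter emergency medical services}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemscost)
```

## The cost structure of a HEMS station

A helicopter emergency medical service (HEMS) station does not fit the
classic linear cost function of fixed plus proportional variable cost.
Three layers interact:

* **Fixed cost** `a` (station infrastructure, aircraft depreciation,
  insurances) and **personnel cost** `p` (pilots, emergency physicians,
  HEMS technical crew) accrue per year regardless of output. A share `q`
  of the personnel cost is attributable to daytime operations.
* **Variable cost** accrues per mission: medical material valued at `i`
  EUR per primary and `j` EUR per secondary mission, and fuel at `l` EUR
  per engine minute of billable flight time.
* **Jump-fixed maintenance cost**: airworthiness checks fall due whenever
  the cumulative number of starts, engine minutes, or winch usages crosses
  a multiple of an interval threshold. Within an interval the cost behaves
  like a fixed cost; at the threshold it jumps. Each family carries up to
  four intervals (two for the winch), evaluated by `step_cost()` as
  `sum(floor(amount / threshold) * cost)`.

The yearly mission profile counts primary missions at day (`x`, the cost
driver) and night (`y`) and secondary interhospital transfers at day
(`z`) and night (`w`), with average billable durations `b_x`, `b_y`
(20 min) and `b_z`, `b_w` (45 min). Each mission needs `t` starts
(2 by default).

Carrying special rescue equipment (a hoist or a static rope) modifies a
share `alpha` of the primary missions: starts scale by `m` (a static-rope
rescue needs three starts, `m = 1.5`; a winch rescue hovers and needs
only one, `m = 0.5`), billable duration scales by `n` (2 for both), and
`r` yearly training starts of `s` minutes plus extra personnel (`o`) and
fixed (`v`) cost are added. With `alpha = 0` the special profile is
normalised away entirely.

`total_cost()` evaluates the resulting cost function and returns the full
component breakdown; its `total` is

```
K = a + p + o + v
  + sum_d floor((r + (1-alpha) t x + alpha x t m + t (y+z+w)) / u_d) c_d
  + sum_d floor((r s + (1-alpha) x b_x + alpha b_x x n + y b_y + z b_z + w b_w) / e_d) f_d
  + sum_d floor((alpha x + r) / g_d) h_d
  + i (x + y) + j (z + w) + l * (all engine minutes)
```

```{r}
sc <- hems_scenarios("1.I")
total_cost(sc$params[[1]], sc$base_profile[[1]], x = 1200)
```

## Average cost per primary mission

Because one aircraft serves both the primary and the secondary remit,
output-independent cost must be divided between the two before a unit
cost can be stated. The model uses an **area-based allocation key**:
primary missions serve an operations area of `beta` = 11,550 km²,
secondary missions one of `gamma` = 23,000 km², so the primary remit
carries `beta / (beta + gamma)` (about one third) of fixed and personnel
cost. The key conserves cost exactly: the two shares sum to one.

`average_primary_cost()` returns the four components of the published
table columns. Fixed and personnel cost are spread over primary billable
minutes and re-scaled to one mission of `b_x` minutes; start- and
flight-time maintenance is allocated by the primary (plus training) share
of engine minutes; winch maintenance and the special add-on `o + v` are
spread over the `CEIL(alpha x)` special-equipment missions and weighted
by `alpha`; variable cost is the per-mission fuel and material. All
arithmetic is kept at full floating precision; currency is rounded
half-up to cents only at presentation time (`format_eur()`).

```{r}
round(average_primary_cost(sc$params[[1]], sc$base_profile[[1]],
                           x = c(900, 1200, 1500)), 2)
```

Average cost falls with rising output (fixed-cost digression) except at
mission counts whose added starts or minutes trigger a maintenance
interval, where it jumps upward. `average_cost_curve()` evaluates the
curve on integer mission counts (missions are indivisible; no
interpolation) and flags the jumps by comparing consecutive counts:

```{r, fig.width = 6, fig.height = 3.5}
crv <- average_cost_curve(hems_scenarios(c("1.I", "2.I", "3.I")), 600, 1600)
autoplot(crv)
```

## Break-even analysis

Revenue is a tariff `P` (default 70 EUR) per billable flight minute;
training flights are not billable. `break_even()` scans profit =
revenue − total cost over integer mission counts. Profit is affine in
`x` between maintenance thresholds but drops by the triggered interval
price at each crossing, so it can turn positive and fall back again. The
scan therefore distinguishes *transient crossings* from the *sustainable
break-even point* `x*`, the smallest count from which profit stays
nonnegative (equality counts as breaking even; `x*` is reported relative
to the scanned range).

```{r}
be <- break_even(hems_scenarios(c("1.I", "2.I", "3.I")), price = 70,
                 secondary_material = "table")
glance(be)
```

## The built-in scenario variations

`hems_scenarios()` ships fifteen parameter sets: three operating-hour
scenarios (12 h, 16 h with night-vision equipment, 24 h with a second
pilot shift and nighttime missions `y` = 120, `w` = 140) crossed with
five variations (I initial, II high cost assumptions with more expensive
maintenance intervals, III dual-use with `z` = 400 secondary missions,
IV static rope, V rescue winch). They are stored as a YAML file in the
package's config dialect (`inst/extdata/scenarios.yaml`) and round-trip
losslessly through `write_scenarios_yaml()` / `read_scenarios_yaml()`.

These fixtures are also what the package's tests exercise, together with
`random_scenario()`, a generator of invariant-respecting random parameter
sets used for property checks (step-cost oracle equivalence, digression
between jumps, reconciliation of allocated totals with averages,
break-even scan versus exhaustive evaluation). The generator draws
realistic magnitudes (fixed cost 0.1–1 M EUR, up to 2000 missions,
schedules of up to 4/4/2 intervals) but it emulates only the *structure*
of the cost system; passing property tests shows internal consistency of
the model, not fidelity to any particular station's accounts.

## Numerical and design choices

Several points are deliberately fixed where the source material is open
to interpretation; they are chosen once and documented here.

* **Flight-time thresholds are engine minutes.** The input table labels
  the flight-time intervals 3,000 / 6,000 / 18,000 / 36,000 "hours", but
  only the minutes reading reproduces the published maintenance averages
  (28,140 yearly minutes trigger 9·1,000 + 4·3,000 + 1·14,000 = 35,000
  EUR, giving the 236.96 EUR average at `x` = 1200).
* **`trunc` is `floor`** (all activity amounts are nonnegative), and
  **`CEIL` of an exact integer is that integer** — validated by the
  special-equipment fixed component `(o+v)/CEIL(0.1*1200) * 0.1` =
  116.65 EUR reproducing the printed 204.81 EUR cell.
* **Fuel on training flights.** The total-cost formula as printed omits
  `r*s` from the fuel term, but the input table's footnotes state that
  winch and static-rope training flights consume fuel like any flight.
  The package charges fuel on all engine minutes. For every
  standard-equipment variation (`alpha` = 0) the two readings coincide.
* **Secondary material valuation.** The published table totals value
  secondary-mission material at `i` instead of `j` (they sit exactly
  `(j - i)(z + w)` below the formula value, while the headline total
  matches the formula). `secondary_material = c("formula", "table")`
  switches between the two conventions; `"formula"` is the default.
* **Fixed-cost denominator.** As printed, allocated fixed cost is spread
  over primary minutes `x b_x + y b_y`. The published dual-use cells
  instead match a spread over daytime minutes `x b_x + z b_z`;
  `fixed_denominator = "daytime"` reproduces them.
* **Daytime personnel override.** The published 24-hour personnel cells
  match the corresponding 12-hour personnel sums rather than `p*q`;
  `daytime_personnel_cost` reproduces them while `p*q` stays the
  formula-faithful default.
* **Winch schedule.** The winch interval table is typographically
  ambiguous; the package reads it as a 100 EUR check per usage and a
  3,000 EUR overhaul every 20 usages. No reading reproduces the published
  winch-variation maintenance cells, which `hems_validate()` therefore
  reports as known deviations.
* **Degenerate inputs.** `x = 0` has no average cost (rejected);
  `alpha > 0` with an empty winch schedule is legal (the static-rope
  variation); an empty year costs exactly `a + p + o + v`.
* **No randomness anywhere in the model** — identical inputs give
  byte-identical outputs, which the command-line interface relies on.

`hems_validate()` recomputes all 315 published table cells from the
shipped fixtures and classifies each as matched (±0.01 EUR) or as one of
three documented deviation groups (winch/static-rope maintenance-derived
cells, 24-hour personnel cells, dual-use totals). The published
break-even counts are similarly reproduced only in part: the scan matches
the reported 800 (12 h) and 959 (16 h) missions under the table
convention, finds 1019 against the reported 1020 for 24 h, and cannot
reproduce the headline 728 under any convention; `break_even()` always
reports its own scan result rather than forcing agreement.

## Problem sizes

All computations are desk scale: the cost function is closed form, a
2000-point curve for all fifteen variations evaluates in well under a
second, and the full test suite (including the brute-force oracles)
runs in seconds.

## Limitations

The model is deterministic and annual: it does not model stochastic
demand, dispatch, queueing or coverage of HEMS networks, cost-benefit or
severity-score mission profiling, currency conversion, or discounting of
capital cost. Parameter values describe one German rural primary-rescue
station and its documented variations; transferring them to another
system means replacing the fixtures, not the code.
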