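# hemscost

Deterministic full-cost simulation of a helicopter emergency medical
service (HEMS) station, for health economists and emergency-service
planners who want to understand what one primary rescue mission actually
costs, and at which utilisation a station covers its cost.

Helicopter operations break the classic linear cost function: besides
yearly fixed cost *a* and personnel cost *p*, and variable cost per
mission (medical material *i*, *j*; fuel *l* per engine minute),
airworthiness maintenance is **jump-fixed** — a check falls due every
time cumulative starts, engine minutes or winch usages cross a multiple
of an interval threshold *u<sub>d</sub>*, *e<sub>d</sub>*,
*g<sub>d</sub>*. Total annual cost is

> K = a + p + o + v
> &nbsp;&nbsp;+ Σ<sub>d</sub> ⌊(r + (1−α)·t·x + α·x·t·m + t·(y+z+w)) / u<sub>d</sub>⌋·c<sub>d</sub>
> &nbsp;&nbsp;+ Σ<sub>d</sub> ⌊(r·s + (1−α)·x·b<sub>x</sub> + α·b<sub>x</sub>·x·n + y·b<sub>y</sub> + z·b<sub>z</sub> + w·b<sub>w</sub>) / e<sub>d</sub>⌋·f<sub>d</sub>
> &nbsp;&nbsp;+ Σ<sub>d</sub> ⌊(α·x + r) / g<sub>d</sub>⌋·h<sub>d</sub>
> &nbsp;&nbsp;+ i·(x+y) + j·(z+w) + l·(engine minutes)

where *x*, *y*, *z*, *w* count primary/secondary missions at day/night,
*b* are billable durations, *t* starts per mission, and α, m, n, r, s,
o, v describe special rescue equipment (hoist or static rope). An
area-based allocation key β/(β+γ) divides fixed and personnel cost
between the primary and secondary remits to yield the **average cost k
per primary mission**, and a tariff *P* per billable flight minute
defines revenue for the **break-even analysis** — which, because of the
jump-fixed costs, distinguishes transient profitability from a
sustainable break-even point.

The package ships the study's fifteen scenario variations (12/16/24
operating hours × initial / high-cost / dual-use / static-rope / winch
assumptions) as editable YAML fixtures, everything in tidyverse style:
tibbles in and out, `tidy()`/`glance()` for break-even objects,
`autoplot()` for curves.

## Worked example

```r
library(hemscost)

sc <- hems_scenarios("1.I")              # 12 h operations, initial costs
cost_table(sc, x = c(900, 1200, 1500))
#>   scenario    x y  z w avg_fixed avg_personnel avg_maintenance avg_variable
#> 1      1.I  900 0 92 0    117.54        268.92          135.32        236.6
#> 2      1.I 1200 0 92 0     88.16        201.69          236.96        236.6
#> 3      1.I 1500 0 92 0     70.53        161.35          210.31        236.6
#>   avg_total primary_total   total
#> 1    758.39      682549.1 1442966
#> 2    763.41      916090.2 1697546
#> 3    678.79     1018186.2 1794126
```

At 1200 primary and 92 secondary missions the station costs
1,697,546.20 € per year; one primary mission averages 763.41 €, of which
88.16 € are allocated fixed cost, 201.69 € personnel, 236.96 €
maintenance and 236.60 € fuel and material. Average cost *falls* with
utilisation (fixed-cost digression: 678.79 € at 1500 missions) except
where an added mission triggers a maintenance interval — note the jump
between 900 and 1200.

```r
be <- break_even(hems_scenarios(c("1.I", "2.I", "3.I")), price = 70,
                 secondary_material = "table")
be
#> <hems_breakeven> profit scan over x = 1 ... 2000 (secondary material: table)
#>   1.I at 70.00 EUR/min: sustainable break-even at x* = 800
#>   2.I at 70.00 EUR/min: sustainable break-even at x* = 959
#>   3.I at 70.00 EUR/min: sustainable break-even at x* = 1019
```

At a 70 €/min tariff, the 12-hour station covers its cost from 800
primary missions per year; extended operating hours need higher
utilisation (959 and 1019 missions).

`hems_validate()` recomputes every cell of the published scenario tables
from the fixtures and classifies each as matched (±0.01 €) or as one of
three documented deviation groups; see the methods vignette
(`vignettes/hems-cost-model.Rmd`) for the conventions and known
irreproducibilities.

A small CLI wraps the same functions:

```sh
Rscript inst/scripts/hems-cost tables --scenario 1.I --x 900,1200,1500
Rscript inst/scripts/hems-cost breakeven --scenario 1.I --price 70 --mode table
Rscript inst/scripts/hems-cost validate
```

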