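# Brute-force oracle for jump-fixed cost: accumulate the activity one unit
# at a time and charge each interval price whenever its own counter reaches
# the threshold. Mechanically independent of the floor()-based formula.
step_cost_brute <- function(amount, intervals) {
  counters <- rep(0, nrow(intervals))
  total <- 0
  u <- 0
  while (u < amount) {
    u <- u + 1
    counters <- counters + 1
    due <- counters == intervals$threshold
    total <- total + sum(intervals$cost[due])
    counters[due] <- 0
  }
  total
}

# Exhaustive break-even oracle: evaluate the sign of profit at every integer
# in range and apply the definitions directly.
break_even_brute <- function(params, profile, price, x_range,
                             secondary_material = "formula") {
  ok <- vapply(x_range, function(x) {
    revenue(params, profile, x = x, price = price) >=
      total_cost(params, profile, x = x,
                 secondary_material = secondary_material)$total
  }, logical(1))
  x_star <- NA_real_
  for (k in seq_along(x_range)) {
    if (all(ok[k:length(ok)])) { x_star <- x_range[k]; break }
  }
  crossings <- x_range[ok & !c(FALSE, ok[-length(ok)])]
  list(x_star = x_star,
       transient = crossings[is.na(x_star) | crossings < x_star])
}

scenario_fixture <- function(id) {
  sc <- hems_scenarios(id)
  list(params = sc$params[[1]], profile = sc$base_profile[[1]])
}
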