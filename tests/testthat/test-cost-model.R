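test_that("yearly starts follow the mission profile and special-equipment corrections", {
  f <- scenario_fixture("1.I")
  expect_equal(total_starts(f$params, f$profile, x = 1200), 2584)

  empty <- mission_profile()
  expect_equal(total_starts(f$params, empty), 0)

  # winch variation without secondary missions: 100 training starts,
  # 0.9*2*1200 standard and 0.1*1200*2*0.5 winch-mission starts
  v <- scenario_fixture("1.V")
  no_secondary <- mission_profile(x = 1200)
  expect_equal(total_starts(v$params, no_secondary), 100 + 2160 + 120)
})

test_that("engine minutes split into training, primary and other components", {
  f <- scenario_fixture("1.I")
  m <- engine_minutes(f$params, f$profile, x = 1200)
  expect_equal(m$total, 28140)
  expect_equal(m$primary, 24000)
  expect_equal(m$other, 4140)
  expect_equal(m$training, 0)

  expect_equal(engine_minutes(f$params, mission_profile())$total, 0)

  v <- scenario_fixture("1.V")
  mv <- engine_minutes(v$params, v$profile, x = 1200)
  expect_equal(unlist(mv[c("training", "primary", "other")], use.names = FALSE),
               c(6000, 26400, 4140))
  expect_equal(mv$total, 36540)
})

test_that("total cost reproduces the baseline scenario and balances its components", {
  f <- scenario_fixture("1.I")
  k <- total_cost(f$params, f$profile, x = 1200)
  expect_equal(k$total, 1697546.20, tolerance = 1e-9)
  expect_equal(k$maintenance_starts, 298400)
  expect_equal(k$maintenance_flighttime, 35000)
  expect_equal(k$total,
               k$fixed + k$personnel + k$special_personnel + k$special_fixed +
                 k$maintenance_starts + k$maintenance_flighttime +
                 k$maintenance_winch + k$material + k$fuel,
               tolerance = 1e-2)

  expect_equal(total_cost(f$params, f$profile, x = 900)$total, 1442966.20)
})

test_that("table-convention totals sit exactly (j - i) * (z + w) below the formula", {
  for (id in c("1.I", "1.III", "3.I")) {
    f <- scenario_fixture(id)
    delta <- (f$params$j - f$params$i) * (f$profile$z + f$profile$w)
    expect_equal(
      total_cost(f$params, f$profile, x = 1200)$total -
        total_cost(f$params, f$profile, x = 1200, secondary_material = "table")$total,
      delta)
  }
})

test_that("with no missions only output-independent cost remains", {
  sched <- maintenance_schedule(200, 4200, 3000, 1000)
  sp <- special_equipment(alpha = 0.1, m = 1, n = 1, r = 0, s = 0,
                          o = 11000, v = 22000)
  params <- hems_parameters(a = 100000, p = 500000, schedule = sched, special = sp)
  k <- total_cost(params, mission_profile())
  expect_equal(k$total, 100000 + 500000 + 11000 + 22000)
})

test_that("a zero special-equipment share removes every special cost term", {
  base <- scenario_fixture("1.I")
  four <- scenario_fixture("1.IV")
  # variation IV with alpha = 0 and variation I cost levels collapses onto I
  neutral <- hems_parameters(
    a = base$params$a, p = base$params$p, q = four$params$q,
    schedule = four$params$schedule, special = special_equipment(alpha = 0))
  for (x in c(900, 1200, 1500)) {
    expect_equal(total_cost(neutral, four$profile, x = x)$total,
                 total_cost(base$params, base$profile, x = x)$total)
    expect_equal(average_primary_cost(neutral, four$profile, x = x)$avg_total,
                 average_primary_cost(base$params, base$profile, x = x)$avg_total)
  }
  # the constructor itself zeroes the inactive profile
  zeroed <- special_equipment(alpha = 0, r = 300, s = 20, o = 10000, v = 39980)
  expect_equal(unlist(unclass(zeroed)),
               c(alpha = 0, m = 1, n = 1, r = 0, s = 0, o = 0, v = 0))
})

test_that("maintenance families contribute additively", {
  v <- scenario_fixture("1.V")
  k <- total_cost(v$params, v$profile, x = 1200)
  sp <- v$params$special
  expect_equal(k$maintenance_starts,
               step_cost(total_starts(v$params, v$profile, x = 1200),
                         v$params$schedule$starts))
  expect_equal(k$maintenance_winch,
               step_cost(sp$alpha * 1200 + sp$r, v$params$schedule$winch))
  # dropping the winch schedule removes exactly the winch term
  no_winch <- v$params
  no_winch$schedule$winch <- no_winch$schedule$winch[0, ]
  expect_equal(total_cost(no_winch, v$profile, x = 1200)$total,
               k$total - k$maintenance_winch)
})

test_that("parameter invariants are enforced", {
  sched <- maintenance_schedule(200, 4200, 3000, 1000)
  expect_error(mission_profile(x = -1), "nonnegative")
  expect_error(mission_profile(x = 1.5), "nonnegative integer")
  expect_error(mission_profile(b_x = 0), "positive")
  expect_error(hems_parameters(a = -1, p = 0, schedule = sched), "nonnegative")
  expect_error(hems_parameters(a = 0, p = 0, q = 0, schedule = sched), "q")
  expect_error(hems_parameters(a = 0, p = 0, t = 0.5, schedule = sched), "t")
  expect_error(special_equipment(alpha = 2), "alpha")
  expect_error(special_equipment(alpha = 0.5, m = 0), "correction")
})
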