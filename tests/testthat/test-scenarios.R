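test_that("the fifteen built-in variations carry the published input data", {
  sc <- hems_scenarios()
  expect_equal(nrow(sc), 15)
  expect_false(anyDuplicated(sc$id) > 0)

  p1 <- hems_scenarios("1.I")$params[[1]]
  expect_equal(c(p1$a, p1$p, p1$q), c(316450, 724000, 1))
  p2 <- hems_scenarios("1.II")$params[[1]]
  expect_equal(c(p2$a, p2$p), c(657000, 842000))
  expect_equal(p2$schedule$starts$cost, c(4200, 9000, 55000, 110000))
  expect_equal(p2$schedule$flighttime$cost, c(1000, 3000, 15000, 45000))

  s3 <- hems_scenarios("3.I")
  expect_equal(unlist(s3$base_profile[[1]][c("y", "z", "w")]),
               c(y = 120, z = 92, w = 140))
  expect_equal(s3$params[[1]]$q, 4 / 7)
  expect_equal(hems_scenarios("3.IV")$params[[1]]$q, 5 / 9)
  expect_equal(hems_scenarios("1.III")$base_profile[[1]]$z, 400)

  sp4 <- hems_scenarios("1.IV")$params[[1]]$special
  expect_equal(unlist(unclass(sp4)),
               c(alpha = 0.05, m = 1.5, n = 2, r = 300, s = 20, o = 10000, v = 39980))
  sp5 <- hems_scenarios("1.V")$params[[1]]$special
  expect_equal(unlist(unclass(sp5)),
               c(alpha = 0.1, m = 0.5, n = 2, r = 100, s = 60, o = 45000, v = 94980))

  # constants shared by every variation
  for (k in seq_len(nrow(sc))) {
    p <- sc$params[[k]]
    expect_equal(c(p$i, p$j, p$l, p$t, p$beta, p$gamma),
                 c(120, 170, 5.83, 2, 11550, 23000))
    b <- sc$base_profile[[k]]
    expect_equal(c(b$b_x, b$b_y, b$b_z, b$b_w), c(20, 20, 45, 45))
  }
  expect_error(hems_scenarios("9.I"), "unknown scenario id")
})

test_that("scenario fixtures survive a YAML round trip losslessly", {
  sc <- hems_scenarios()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenarios_yaml(sc, path)
  back <- read_scenarios_yaml(path)
  expect_equal(back$id, sc$id)
  for (k in seq_len(nrow(sc))) {
    expect_identical(unclass(back$params[[k]])[names(unclass(sc$params[[k]])) != "schedule"],
                     unclass(sc$params[[k]])[names(unclass(sc$params[[k]])) != "schedule"],
                     label = sprintf("params of %s", sc$id[k]))
    expect_equal(back$params[[k]]$schedule, sc$params[[k]]$schedule)
    expect_identical(unclass(back$base_profile[[k]]), unclass(sc$base_profile[[k]]))
  }
})

test_that("the cost table mirrors the published rows", {
  tbl <- cost_table(hems_scenarios(c("1.I", "2.I")), x = c(900, 1200, 1500))
  expect_equal(nrow(tbl), 6)
  expect_equal(names(tbl),
               c("scenario", "x", "y", "z", "w", "avg_fixed", "avg_personnel",
                 "avg_maintenance", "avg_variable", "avg_total",
                 "primary_total", "total"))
  one <- tbl[tbl$scenario == "1.I", ]
  expect_equal(as.numeric(format_eur(one$avg_total)), c(758.39, 763.41, 678.79))
  expect_equal(as.numeric(format_eur(
    tbl$avg_total[tbl$scenario == "2.I" & tbl$x == 1200])), 809.93)
})

test_that("variation totals rank as reported: high-cost II above initial I", {
  tbl <- cost_table(hems_scenarios(), x = 1200)
  for (s in 1:3) {
    grp <- tbl[startsWith(tbl$scenario, paste0(s, ".")), ]
    expect_equal(grp$scenario[which.max(grp$total)], sprintf("%d.II", s))
    expect_lt(grp$total[grp$scenario == sprintf("%d.I", s)],
              grp$total[grp$scenario == sprintf("%d.II", s)])
  }
})

test_that("the average-cost curve passes through the table and flags maintenance jumps", {
  crv <- average_cost_curve(hems_scenarios("1.I"), 900, 1500)
  tbl <- cost_table(hems_scenarios("1.I"), x = c(900, 1200, 1500))
  expect_equal(crv$avg_total[match(c(900, 1200, 1500), crv$x)], tbl$avg_total)

  # the first upward jump above x = 1101 falls before x = 1200
  jumps <- crv$x[crv$jump]
  expect_true(any(jumps > 1101 & jumps <= 1200))
  expect_equal(min(jumps[jumps > 1101]), 1108)

  # strictly decreasing between flagged jump points
  seg <- cumsum(crv$jump)
  drops <- tapply(crv$avg_total, seg, function(v) all(diff(v) < 0))
  expect_true(all(drops))

  expect_error(average_cost_curve(hems_scenarios("1.I"), 0, 10), "x_min")
})

test_that("the random scenario generator emits invariant-respecting inputs", {
  set.seed(123)
  for (rep in 1:10) {
    s <- random_scenario()
    expect_s3_class(s$params, "hems_parameters")
    expect_s3_class(s$profile, "hems_profile")
    k <- total_cost(s$params, s$profile)
    expect_true(is.finite(k$total) && k$total >= 0)
    expect_equal(k$total, sum(k[1, names(k) != "total"]))
  }
  set.seed(99)
  a <- random_scenario()
  set.seed(99)
  b <- random_scenario()
  expect_identical(a, b)
})
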