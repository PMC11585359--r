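test_that("the eight scenario definitions encode the scheme/flag ledger", {
  tab <- scenario_table()
  expect_equal(tab$label, c("B1", "B2", "T1", "T2", "T3", "M1", "M2", "M3"))
  expect_equal(tab$scheme, rep(c("bigleaf", "twoleaf", "multilayer"),
                               c(2, 3, 3)))
  expect_equal(tab$capacity_gradient,
               c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(tab$acclimation,
               c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE))
  sp <- scenario_spec("T3")
  expect_s3_class(sp, "scenario_spec")
  expect_true(sp$capacity_gradient && sp$acclimation)
  expect_error(scenario_spec("X9"), "unknown scenario")
})

test_that("growth temperature is the preceding-window rolling mean", {
  d <- seq(as.Date("2014-01-01"), by = "day", length.out = 60)
  expect_equal(growth_temperature(d, rep(20, 60)), rep(20, 60))
  # step change: day 31 onwards at 25; by day 61 the window is all-new
  x <- c(rep(15, 30), rep(25, 30))
  d61 <- seq(as.Date("2014-01-01"), by = "day", length.out = 61)
  tg <- growth_temperature(d61, c(x, 25))
  expect_equal(tg[61], 25)
  expect_equal(tg[31], 15)        # the day of the step still sees history
  # linear ramp lags by about half the window
  ramp <- 15 + 0.1 * (0:59)
  tgr <- growth_temperature(d, ramp)
  expect_equal(ramp[60] - tgr[60], 0.1 * (30 / 2 + 0.5), tolerance = 0.01)
  expect_error(growth_temperature(as.Date(character()), numeric()), "empty")
})

test_that("acclimation shifts capacities by the fitted slopes", {
  p <- photo_params()
  acc <- acclimation_model()
  base <- acclimate_capacities(acc$T_ref, p, acc)
  expect_equal(base$Vcmax25, 103.6)
  expect_equal(base$Jmax25, 178.2)
  warm <- acclimate_capacities(acc$T_ref + 1, p, acc)
  expect_equal(warm$Vcmax25, 103.6 - 1.9)
  expect_equal(warm$Jmax25, 178.2 - 3.7)
  # monotone decreasing, floored
  tg <- seq(0, 80, by = 5)
  v <- acclimate_capacities(tg, p, acc)$Vcmax25
  expect_true(all(diff(v) <= 0))
  expect_gte(min(v), 0.1 * 103.6)
})

test_that("the crown capacity profile interpolates exponentially", {
  prof <- layer_capacity_profile(103.6, 0.21)
  expect_equal(prof[1], 103.6)
  expect_equal(prof[6], 103.6 * 0.79, tolerance = 1e-9)
  expect_true(all(diff(prof) < 0))
  # log-linear in depth
  expect_equal(diff(log(prof)), rep(diff(log(prof))[1], 5), tolerance = 1e-12)
  expect_equal(layer_capacity_profile(100, 0), rep(100, 6))
  jprof <- layer_capacity_profile(178.2, 0.26)
  expect_equal(jprof[6], 178.2 * 0.74, tolerance = 1e-9)
})

test_that("all eight scenarios run and produce aligned series", {
  met <- short_met(seed = 3, start = "2013-12-20", end = "2013-12-22")
  trees <- short_trees(seed = 3, start = "2013-12-20", end = "2013-12-22")
  out <- lapply(scenario_table()$label, run_scenario, met = met, trees = trees)
  for (o in out) {
    expect_equal(nrow(o), nrow(met))
    expect_equal(o$timestamp, met$timestamp)
    expect_true(all(is.finite(o$anet_umol_m2leaf_s)))
    expect_true(all(o$flag == ""))
  }
  # daytime fluxes differ between schemes, night respiration is shared
  day <- met$par_umol_m2_s > 800
  a <- sapply(out, function(o) mean(o$anet_umol_m2leaf_s[day]))
  expect_gt(max(a) - min(a), 0.5)
})

test_that("acclimation lowers summer capacity and flux (M3 < M1)", {
  # a hot spell: growth temperature well above the acclimation reference
  met <- synth_met(synth_met_config(start = "2014-01-05", end = "2014-01-12",
                                    cadence_min = 60, t_day_mean = 27,
                                    seed = 5))
  trees <- short_trees(seed = 5, start = "2014-01-05", end = "2014-01-12")
  m1 <- run_scenario("M1", met, trees)
  m3 <- run_scenario("M3", met, trees)
  day <- met$par_umol_m2_s > 400
  # summer growth temperature exceeds T_ref, so M3 capacities are reduced
  expect_lt(mean(m3$anet_umol_m2leaf_s[day]), mean(m1$anet_umol_m2leaf_s[day]))
})
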