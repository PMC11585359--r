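make_series <- function(anet, par, start = "2014-01-01 00:00",
                        cadence_min = 15, chamber = "C01") {
  n <- length(anet)
  ts <- as.POSIXct(start, tz = "Etc/GMT-10") + (seq_len(n) - 1) * cadence_min * 60
  data.frame(timestamp = ts, chamber_id = chamber,
             anet_umol_m2leaf_s = anet, par_umol_m2_s = par,
             tair_c = 20, vpd_kpa = 1, stringsAsFactors = FALSE)
}

test_that("hourly averaging is the arithmetic mean per clock hour", {
  s <- make_series(c(1, 2, 3, 4, 5, 5, 5, 5), par = rep(1000, 8))
  h <- hourly_average(s)
  expect_equal(nrow(h), 2)
  expect_equal(h$anet_umol_m2leaf_s, c(2.5, 5))
  expect_false(any(h$partial))
  # a missing sub-interval: mean of the remaining three, flagged
  s2 <- make_series(c(1, NA, 3, 5), par = rep(1000, 4))
  h2 <- hourly_average(s2)
  expect_equal(h2$anet_umol_m2leaf_s, 3)
  expect_true(h2$partial)
  expect_equal(h2$n_subintervals, 3)
  # below the minimum: hour dropped
  s3 <- make_series(c(1, NA, NA, NA), par = rep(1000, 4))
  expect_equal(nrow(hourly_average(s3)), 0)
  expect_error(hourly_average(make_series(1, 1000)[0, ]), "empty")
})

test_that("high-light subsetting uses a strict threshold", {
  s <- make_series(1:5, par = c(0, 1199, 1200, 1201, 1500))
  hs <- highlight_subset(s)
  expect_equal(hs$par_umol_m2_s, c(1201, 1500))  # 1200 itself excluded
  expect_equal(nrow(highlight_subset(make_series(1:4, par = rep(0, 4)))), 0)
  # equivalent to a brute-force filter
  set.seed(51)
  par <- runif(200, 0, 2300)
  s2 <- make_series(seq_len(200), par = par)
  expect_equal(nrow(highlight_subset(s2)), sum(par > 1200))
})

test_that("hourly averaging and high-light subsetting commute with chamber splits", {
  set.seed(61)
  a <- make_series(rnorm(96, 5), par = runif(96, 800, 2000), chamber = "C01")
  b <- make_series(rnorm(96, 6), par = runif(96, 800, 2000), chamber = "C02")
  both <- rbind(a, b)
  pooled <- highlight_subset(hourly_average(both))
  split <- rbind(highlight_subset(hourly_average(a)),
                 highlight_subset(hourly_average(b)))
  split <- split[order(split$chamber_id, split$timestamp), ]
  rownames(split) <- NULL
  expect_equal(pooled$anet_umol_m2leaf_s, split$anet_umol_m2leaf_s)
  expect_equal(pooled$timestamp, split$timestamp)
})

test_that("model-observation regression reproduces known relationships", {
  set.seed(71)
  obs <- make_series(rnorm(300, 6, 2.5), par = rep(1500, 300))
  # identical series: the identity summary
  r0 <- suppressWarnings(regress_model_obs(obs, obs))
  expect_equal(r0$slope, 1, tolerance = 1e-12)
  expect_equal(r0$intercept, 0, tolerance = 1e-12)
  expect_equal(r0$r2, 1, tolerance = 1e-12)
  expect_equal(r0$rmse, 0, tolerance = 1e-12)
  # affine shift
  shifted <- obs
  shifted$anet_umol_m2leaf_s <- obs$anet_umol_m2leaf_s + 2
  r1 <- suppressWarnings(regress_model_obs(shifted, obs))
  expect_equal(r1$intercept, 2, tolerance = 1e-9)
  expect_equal(r1$slope, 1, tolerance = 1e-9)
  expect_equal(r1$rmse, 2, tolerance = 1e-9)
  expect_error(regress_model_obs(obs[1:5, ], obs[1:5, ]), "10 paired")
})

test_that("OLS slope and RMSE match closed-form expectations under noise", {
  set.seed(81)
  n <- 1000
  truth <- rnorm(n, 8, 3)
  obs <- make_series(truth, par = rep(1500, n))
  mod <- make_series(0.8 * truth + rnorm(n, 0, 1), par = rep(1500, n))
  r <- regress_model_obs(mod, obs)
  expect_equal(r$slope, 0.8, tolerance = 0.02 * 2.5)
  # E[(m - o)^2] = var(noise) + (1-0.8)^2 var(truth) + (0.2 mean)^2
  exp_rmse <- sqrt(1 + 0.04 * 9 + (0.2 * 8)^2)
  expect_equal(r$rmse, exp_rmse, tolerance = 0.1)
  expect_equal(r$n, n)
})
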