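test_that("quadratic optimum fit recovers noiseless parameters exactly", {
  T <- seq(12, 38, by = 2)
  A <- quadratic_response(T, 20, 24.7, 0.04)
  f <- fit_quadratic_topt(T, A)
  expect_equal(unname(coef(f)["Aopt"]), 20, tolerance = 1e-6)
  expect_equal(unname(coef(f)["Topt"]), 24.7, tolerance = 1e-6)
  expect_equal(unname(coef(f)["b"]), 0.04, tolerance = 1e-6)
  expect_false(f$boundary)
  expect_equal(predict(f, data.frame(T = 30)),
               quadratic_response(30, 20, 24.7, 0.04), tolerance = 1e-6)
})

test_that("monotone data yields a boundary-flagged quadratic optimum", {
  T <- seq(15, 40, by = 1)
  A <- 25 - 0.5 * T
  f <- fit_quadratic_topt(T, A)
  expect_true(f$boundary)
  expect_error(fit_quadratic_topt(1:4, 1:4), "at least 5")
})

test_that("peaked Arrhenius fit is exact on self-generated data", {
  T <- seq(25, 42, length.out = 6)
  rates <- peaked_arrhenius(T + 273.15, 103.6, 59700, 634, 2e5)
  f <- fit_peaked_arrhenius(T, rates)
  expect_equal(unname(coef(f)["k25"]), 103.6, tolerance = 1e-3)
  expect_equal(unname(coef(f)["Ea"]), 59700, tolerance = 1)
  expect_equal(unname(coef(f)["dS"]), 634, tolerance = 0.01)
  expect_false(f$no_peak)
  expect_equal(f$Topt_C, 311.962 - 273.15, tolerance = 0.01)
})

test_that("rates without a high-temperature decline are flagged no-peak", {
  T <- seq(25, 42, length.out = 6)
  rates <- arrhenius(T + 273.15, 60, 55000)  # pure exponential rise
  f <- fit_peaked_arrhenius(T, rates)
  expect_true(f$no_peak)
})

test_that("A/Ci fitting recovers the generating capacities", {
  kin <- kinetic_constants()
  p <- photo_params(Vcmax25 = 85, Jmax25 = 150)
  Ci <- c(60, 100, 150, 220, 300, 420, 600, 850, 1100)
  A <- fvcb_assimilation(Ci, 25, 1500, p, kin)$Anet
  f <- fit_aci(A, Ci, Tleaf = 25, params = p, kin = kin)
  expect_equal(f$Vcmax, 85, tolerance = 0.01)
  expect_equal(f$Jmax, 150, tolerance = 0.01)
  expect_true(f$jmax_estimable)
  # truncated curve: no RuBP-limited region reachable
  Ci_lo <- c(40, 70, 100, 140, 190, 250)
  A_lo <- fvcb_assimilation(Ci_lo, 25, 1500, p, kin)$Anet
  f_lo <- fit_aci(A_lo, Ci_lo, Tleaf = 25, params = p, kin = kin)
  expect_equal(f_lo$Vcmax, 85, tolerance = 0.05)
  expect_false(f_lo$jmax_estimable)
})

test_that("g1 fitting is exact on noiseless Medlyn data and flags issues", {
  set.seed(21)
  A <- runif(60, 2, 25)
  D <- runif(60, 0.4, 3)
  gs <- 1.6 * (1 + 2.4 / sqrt(D)) * A / 400
  f <- suppressWarnings(fit_g1(gs, A, 400, D))
  expect_equal(f$g1, 2.4, tolerance = 1e-9)
  expect_false(f$nonpositive)
  expect_false(f$low_information)
  f1 <- fit_g1(gs[1:20], A[1:20], 400, rep(1.2, 20))
  expect_true(f1$low_information)
})

test_that("smooth and quadratic optima agree on quadratic data", {
  set.seed(31)
  T <- runif(120, 12, 38)
  A <- quadratic_response(T, 20, 24.7, 0.04)
  sm <- fit_smooth_response(T, A)
  expect_lt(abs(sm$Topt - 24.7), 0.2)
  expect_false(sm$boundary)
  # with moderate noise the two methods still agree
  An <- A + rnorm(120, 0, 0.8)
  qf <- fit_quadratic_topt(T, An)
  smn <- fit_smooth_response(T, An)
  expect_lt(abs(smn$Topt - unname(coef(qf)["Topt"])), 1.5)
  # monotone data: boundary optimum at the cool edge
  md <- fit_smooth_response(T, 30 - 0.5 * T + rnorm(120, 0, 0.3))
  expect_true(md$boundary)
  expect_equal(md$Topt, min(T), tolerance = 0.2)
})

test_that("identical smooth responses are not deemed different", {
  set.seed(41)
  T <- runif(80, 12, 38)
  A <- quadratic_response(T, 18, 24, 0.035) + rnorm(80, 0, 0.5)
  a <- fit_smooth_response(T, A)
  expect_false(smooth_responses_differ(a, a)$different)
  # a strongly shifted response separates
  b <- fit_smooth_response(T, A + 8)
  expect_true(smooth_responses_differ(a, b)$different)
})
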