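test_that("electron transport saturates between 0 and Jmax", {
  expect_equal(electron_transport(0, 178.2), 0)
  expect_equal(electron_transport(1e7, 178.2), 178.2, tolerance = 1e-3)
  # quadratic-root oracle at the standard light level
  expect_equal(electron_transport(1500, 178.2, 0.26, 0.57), 142.7566,
               tolerance = 1e-4)
  apar <- seq(0, 3000, by = 50)
  J <- electron_transport(apar, 178.2)
  expect_true(all(diff(J) >= 0))
  expect_true(all(J <= pmin(0.26 * apar, 178.2) + 1e-9))
  expect_error(electron_transport(100, 178.2, theta_J = 1.2), "theta_J")
})

test_that("FvCB assimilation equals the minimum branch minus respiration", {
  # independent brute-force evaluation of both branches over random draws
  set.seed(7)
  kin <- kinetic_constants()
  for (i in 1:200) {
    Ci <- runif(1, 50, 800)
    Tl <- runif(1, 5, 42)
    apar <- runif(1, 0, 2000)
    p <- photo_params(Vcmax25 = runif(1, 20, 150), Jmax25 = runif(1, 40, 250))
    out <- fvcb_assimilation(Ci, Tl, apar, p, kin)
    Tk <- Tl + 273.15
    vc <- peaked_arrhenius(Tk, p$Vcmax25, p$Ea_V, p$dS_V, p$Hd)
    jm <- peaked_arrhenius(Tk, p$Jmax25, p$Ea_J, p$dS_J, p$Hd)
    gs <- arrhenius(Tk, kin$GammaStar25, kin$Ea_GammaStar)
    km <- arrhenius(Tk, kin$Kc25, kin$Ea_Kc) *
      (1 + kin$Oi / arrhenius(Tk, kin$Ko25, kin$Ea_Ko))
    J <- electron_transport(apar, jm, p$alpha_J, p$theta_J)
    ac <- vc * max(Ci - gs, 0) / (Ci + km)
    aj <- (J / 4) * max(Ci - gs, 0) / (Ci + 2 * gs)
    rl <- day_respiration(Tl, p$Rl25, p$Q10)
    expect_equal(out$Anet, min(ac, aj) - rl, tolerance = 1e-10)
    expect_lte(min(ac, aj), ac + 1e-12)
    expect_lte(min(ac, aj), aj + 1e-12)
  }
})

test_that("assimilation at and below the compensation point is -Rl", {
  kin <- kinetic_constants()
  gs25 <- kin$GammaStar25
  out <- fvcb_assimilation(gs25, 25, 1500)
  expect_equal(out$Anet, -day_respiration(25), tolerance = 1e-9)
  out_dark <- fvcb_assimilation(280, 25, 0)
  expect_equal(out_dark$Anet, -day_respiration(25), tolerance = 1e-9)
  # monotone non-decreasing in Ci
  A <- fvcb_assimilation(seq(10, 900, by = 10), 25, 1500)$Anet
  expect_true(all(diff(A) >= -1e-9))
})

test_that("Medlyn conductance matches its closed form", {
  expect_equal(medlyn_gs(10, 400, 1, stomatal_params(g1 = 2.4)), 0.136)
  expect_equal(medlyn_gs(0, 400, 1), 0)
  expect_equal(medlyn_gs(-3, 400, 1), 0)        # negative A -> g0
  expect_equal(medlyn_gs(10, 400, 1e9), 1.6 * 10 / 400, tolerance = 1e-3)
  # proportional to Anet at fixed D
  expect_equal(medlyn_gs(20, 400, 1), 2 * medlyn_gs(10, 400, 1))
})

test_that("coupled leaf solution closes supply, demand and energy balance", {
  for (tt in c(10, 20, 30, 40)) {
    st <- solve_coupled_leaf(env_conditions(tt, 1.2, 1500))
    if (st$Anet > 0) {
      expect_lt(abs((st$gs / 1.6) * (400 - st$Ci) - st$Anet), 1e-3)
      expect_lte(st$Ci, 400)
    }
    expect_equal(st$D, max(esat(st$Tleaf) - (esat(tt) - 1.2), 0.05),
                 tolerance = 0.05)
  }
})

test_that("well-coupled limit pins leaf temperature at air temperature", {
  st <- solve_coupled_leaf(env_conditions(25, 1, 1500), gb = Inf)
  expect_equal(st$Tleaf, 25, tolerance = 0.02)
  # with finite coupling a sunlit chamber leaf runs 1-2 degC warm
  st2 <- solve_coupled_leaf(env_conditions(25, 1, 1500))
  expect_gt(st2$Tleaf - 25, 0.5)
  expect_lt(st2$Tleaf - 25, 2.5)
})

test_that("light level moves the leaf temperature optimum", {
  hi <- temperature_sweep("leaf", Tair = seq(10, 45, 0.5), PAR = 1500,
                          params = photo_params(Vcmax25 = 60, Jmax25 = 103))
  lo <- temperature_sweep("leaf", Tair = seq(10, 45, 0.5), PAR = 200,
                          params = photo_params(Vcmax25 = 60, Jmax25 = 103))
  expect_gt(sweep_argmax(hi), sweep_argmax(lo))
  # at 200 umol m-2 s-1 net photosynthesis declines monotonically, 15-40 degC
  mid <- lo$Tair >= 15 & lo$Tair <= 40
  expect_true(all(diff(lo$Anet[mid]) < 0))
  # saturating-light curve supports an interior quadratic optimum
  hi_fit <- fit_quadratic_topt(hi$Tair, hi$Anet)
  expect_false(hi_fit$boundary)
})

test_that("vectorized and scalar leaf solvers agree", {
  env <- env_conditions(28, 1.4, 1500)
  apar <- c(0, 40, 150, 420, 900, 1237)
  vec <- crownscale:::solve_leaf_vec(env, apar, rep(103.6, 6), rep(178.2, 6))
  for (i in seq_along(apar)) {
    st <- solve_coupled_leaf(env, APAR = apar[i])
    expect_equal(vec$Anet[i], st$Anet, tolerance = 0.02)
    expect_equal(vec$Tleaf[i], st$Tleaf, tolerance = 0.05)
  }
})
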