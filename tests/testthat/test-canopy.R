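test_that("fPAR follows Beer's law", {
  expect_equal(fpar(0.5, 0), 0)
  expect_equal(fpar(0.7, 0), 0)
  expect_equal(fpar(0.5, 3), 1 - exp(-1.5), tolerance = 1e-10)
  expect_equal(fpar(0.5, 1e4), 1, tolerance = 1e-12)
  expect_error(fpar(0.5, -1), "non-negative")
  lai <- seq(0, 10, by = 0.25)
  expect_true(all(diff(fpar(0.5, lai)) > 0))
})

test_that("big-leaf canopy flux behaves like a scaled sun leaf", {
  expect_equal(bigleaf_flux(env_conditions(25, 1, 1500),
                            structure = canopy_structure(LAI = 0))$Anet, 0)
  sw <- temperature_sweep("bigleaf")
  am <- sweep_argmax(sw)
  expect_gt(am, min(sw$Tair))            # interior optimum ...
  expect_lt(am, max(sw$Tair))
  lf <- temperature_sweep("leaf")
  expect_lt(abs(am - sweep_argmax(lf)), 4)  # ... near the leaf-scale one
  # light-saturated: doubling PAR changes flux far less than proportionally
  a1 <- bigleaf_flux(env_conditions(25, 1, 1500))$Anet
  a2 <- bigleaf_flux(env_conditions(25, 1, 3000))$Anet
  expect_lt((a2 - a1) / a1, 0.15)
})

test_that("sun/shade partition conserves leaf area and energy", {
  set.seed(11)
  for (i in 1:25) {
    PAR <- runif(1, 0, 2200)
    zen <- runif(1, 0, 89)
    L <- runif(1, 0.5, 6)
    p <- partition_sun_shade(PAR, zen, canopy_structure(LAI = L))
    expect_equal(p$LAI_sun + p$LAI_shade, L, tolerance = 1e-12)
    expect_true(all(c(p$LAI_sun, p$LAI_shade, p$APAR_sun, p$APAR_shade) >= 0))
    expect_lte(p$APAR_sun + p$APAR_shade, PAR + 1e-9)
  }
  # hand evaluation: overhead sun, kb' = 0.5, LAI = 3
  p <- partition_sun_shade(1500, 0, canopy_structure(LAI = 3))
  expect_equal(p$LAI_sun, (1 - exp(-1.5)) / 0.5, tolerance = 1e-9)
  # grazing sun: no sunlit leaf area, everything diffuse
  pg <- partition_sun_shade(300, 89)
  expect_equal(pg$LAI_sun, 0)
  expect_equal(pg$diffuse_frac, 1)
})

test_that("two-leaf flux is below big-leaf and peaks at lower temperature", {
  e <- env_conditions(25, 1, 1500)
  expect_lt(twoleaf_flux(e)$Anet, bigleaf_flux(e)$Anet)
  tw <- temperature_sweep("twoleaf")
  bl <- temperature_sweep("bigleaf")
  expect_lt(sweep_argmax(tw), sweep_argmax(bl))
  # dark: only respiration remains
  d <- twoleaf_flux(env_conditions(18, 0.8, 0))
  expect_lt(d$Anet, 0)
  expect_equal(d$Anet, -day_respiration(d$shade$Tleaf), tolerance = 0.05)
})

test_that("kn weighting reduces canopy capacity below the uniform integral", {
  p_u <- partition_sun_shade(1500, 30, capacity_mode = "uniform")
  p_k <- partition_sun_shade(1500, 30, capacity_mode = "kn")
  expect_lt(p_k$Vc_sun + p_k$Vc_shade, p_u$Vc_sun + p_u$Vc_shade)
  st <- canopy_structure()
  expect_equal(p_k$Vc_sun + p_k$Vc_shade,
               103.6 * (1 - exp(-st$kn * st$LAI)) / st$kn, tolerance = 1e-9)
})

test_that("scheme fluxes are consistent across the hierarchy", {
  e <- env_conditions(25, 1, 1500)
  bl <- bigleaf_flux(e)$Anet
  tl <- twoleaf_flux(e)$Anet
  grid <- gridpoint_apar(build_crown_grid(slab_crown()), 1500, 30, 180)
  ml <- multilayer_flux(e, grid)$Anet
  # big-leaf is the upper bound; in the horizontally homogeneous (slab)
  # limit the explicit multilayer agrees with the two-leaf integral to
  # within the schemes' radiation-discretization differences
  expect_gt(bl, tl)
  expect_gt(bl, ml)
  expect_lt(abs(ml - tl) / tl, 0.05)
})

test_that("multilayer reproduces the two-leaf flux in the degenerate limit", {
  # single-layer single-point slab under all-diffuse light, with the
  # two-leaf diffuse extinction set to the sky-quadrature effective value
  L <- 0.8
  zen <- c(15, 45, 75)
  wz <- cos(zen * pi / 180) * sin(zen * pi / 180)
  wz <- wz / sum(wz)
  keff <- -log(sum(wz * exp(-0.5 * L / cos(zen * pi / 180)))) / L
  gd <- gridpoint_apar(build_crown_grid(slab_crown(LAI = L, depth = 0.5), 1, 1),
                       80, 30, 180)
  e <- env_conditions(20, 1, 80)
  md <- multilayer_flux(e, gd)$Anet
  td <- twoleaf_flux(e, structure = canopy_structure(LAI = L, k = keff))$Anet
  expect_lt(abs(md - td) / abs(td), 0.05)
})
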