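test_that("crown grid has the specified sub-volume structure", {
  geom <- chamber_crown()
  g <- build_crown_grid(geom)
  expect_equal(nrow(g), 72)
  expect_equal(length(unique(g$layer)), 6)
  expect_equal(sum(g$leaf_area), geom$leaf_area, tolerance = 1e-12)
  expect_true(all(table(g$layer) == 12))
  # layer 1 is the top
  expect_gt(mean(g$z[g$layer == 1]), mean(g$z[g$layer == 6]))
  # degenerate single-volume grid
  g1 <- build_crown_grid(geom, 1, 1)
  expect_equal(nrow(g1), 1)
  expect_equal(g1$leaf_area, geom$leaf_area)
  expect_error(crown_geometry(height = 1, radius = 0.5, leaf_area = 1,
                              crown_base = 2), "degenerate")
})

test_that("ray-cylinder paths match hand-computed chords", {
  # vertical ray through the full depth of a cylinder
  p <- crownscale:::ray_cylinder_path(0, 0, 0, 0, 0, 1, 0, 0, 1, 1, 3)
  expect_equal(p, 2)
  # horizontal ray through the centre: full diameter
  p2 <- crownscale:::ray_cylinder_path(-5, 0, 2, 1, 0, 0, 0, 0, 1, 1, 3)
  expect_equal(p2, 2)
  # ray that misses
  p3 <- crownscale:::ray_cylinder_path(-5, 2, 2, 1, 0, 0, 0, 0, 1, 1, 3)
  expect_equal(p3, 0)
  # 45-degree ray from inside the cylinder wall
  s2 <- 1 / sqrt(2)
  p4 <- crownscale:::ray_cylinder_path(0, 0, 2, s2, 0, s2, 0, 0, 1, 0, 4)
  expect_equal(p4, sqrt(2), tolerance = 1e-9)
})

test_that("gridpoint APAR respects extinction geometry", {
  geom <- chamber_crown()
  g <- gridpoint_apar(build_crown_grid(geom), 1500, 30, 180)
  # beam extinction is monotone with depth at the same plan position
  for (pt in unique(g$point)) {
    sub <- g[g$point == pt, ]
    sub <- sub[order(sub$layer), ]
    expect_true(all(diff(sub$sunlit_frac) <= 1e-9))
  }
  expect_true(all(g$sunlit_frac >= 0 & g$sunlit_frac <= 1))
  expect_true(all(g$APAR_sun >= g$APAR_shade))
  # under a pure diffuse sky the shade irradiance also decays with depth
  gd <- gridpoint_apar(build_crown_grid(geom), 90, 30, 180)
  for (pt in unique(gd$point)) {
    sub <- gd[gd$point == pt, ]
    sub <- sub[order(sub$layer), ]
    expect_true(all(diff(sub$APAR_shade) <= 1e-6))
  }
})

test_that("a transparent canopy transmits everything", {
  # at zenith 60 the projected beam irradiance per unit leaf area equals
  # the horizontal flux, so total APAR is incident PAR x absorptance
  geom <- crown_geometry(height = 3, radius = 0.6, leaf_area = 1e-9)
  g <- gridpoint_apar(build_crown_grid(geom), 1500, 60, 180)
  expect_equal(g$sunlit_frac, rep(1, 72), tolerance = 1e-6)
  expect_equal(g$APAR_sun, rep(0.825 * 1500, 72), tolerance = 0.5)
})

test_that("a neighbour crown between gridpoint and sun reduces transmittance", {
  geom <- chamber_crown()
  g0 <- gridpoint_apar(build_crown_grid(geom), 1500, 45, 180)
  # sun azimuth 180 (north-up convention): beam arrives from the south;
  # a neighbour placed due south intercepts it
  blocker <- chamber_crown(LAI = 6, x = 0, y = -3)
  g1 <- gridpoint_apar(build_crown_grid(geom), 1500, 45, 180,
                       neighbours = list(blocker))
  expect_true(all(g1$sunlit_frac <= g0$sunlit_frac + 1e-12))
  expect_lt(mean(g1$sunlit_frac), mean(g0$sunlit_frac))
  # a neighbour on the opposite side leaves the beam untouched
  g2 <- gridpoint_apar(build_crown_grid(geom), 1500, 45, 180,
                       neighbours = list(chamber_crown(LAI = 6, x = 0, y = 30)))
  expect_equal(g2$sunlit_frac, g0$sunlit_frac, tolerance = 1e-12)
})

test_that("multilayer aggregation conserves leaf area and absorbed light", {
  geom <- chamber_crown()
  g <- gridpoint_apar(build_crown_grid(geom), 1500, 30, 180,
                      neighbours = neighbour_crowns(chamber_layout(), "C03",
                                                    geom))
  e <- env_conditions(25, 1, 1500)
  ml <- multilayer_flux(e, g)
  la_sun <- g$leaf_area * g$sunlit_frac
  la_shade <- g$leaf_area * (1 - g$sunlit_frac)
  expect_equal(sum(la_sun + la_shade), geom$leaf_area, tolerance = 1e-9)
  w <- sum(ml$detail$anet_sun * la_sun + ml$detail$anet_shade * la_shade) /
    geom$leaf_area
  expect_equal(ml$Anet, w, tolerance = 1e-9)
  # dark multilayer flux is leaf respiration
  gd <- gridpoint_apar(build_crown_grid(geom), 0, Inf, 0)
  md <- multilayer_flux(env_conditions(18, 0.8, 0), gd)
  expect_equal(md$Anet, -day_respiration(18), tolerance = 0.05)
})

test_that("per-layer capacity profiles propagate to the flux", {
  geom <- chamber_crown()
  g <- gridpoint_apar(build_crown_grid(geom), 1500, 30, 180)
  e <- env_conditions(25, 1, 1500)
  uniform <- multilayer_flux(e, g)$Anet
  vc <- layer_capacity_profile(103.6, 0.21)
  jm <- layer_capacity_profile(178.2, 0.26)
  graded <- multilayer_flux(e, g, Vcmax25_layers = vc, Jmax25_layers = jm)$Anet
  expect_lt(graded, uniform)
})
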