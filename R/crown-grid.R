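# Multilayer crown scheme: each cylindrical crown is divided into
# n_layers x n_points sub-volumes; beam and diffuse transmittances are
# ray-traced through the own crown and neighbouring crown cylinders, and
# the coupled leaf model is solved for the sunlit and shaded leaf area of
# every sub-volume.

#' Build the crown grid
#'
#' Divides a cylindrical crown into `n_layers` equal-thickness horizontal
#' layers (layer 1 at the top), each carrying `n_points` gridpoints on a
#' fixed areal template (for the default 12 points: 4 on an inner ring at
#' r/3, 8 on an outer ring at 2r/3). Leaf area density is uniform, so every
#' sub-volume holds `leaf_area / (n_layers * n_points)`.
#'
#' @param geom A [crown_geometry()] object.
#' @param n_layers Number of horizontal layers (default 6).
#' @param n_points Number of gridpoints per layer (default 12).
#' @return An object of class `crown_grid`: data.frame with `layer`,
#'   `point`, centroid coordinates `x`, `y`, `z` (m) and `leaf_area` (m2),
#'   plus the geometry as attribute `geom`.
#' @export
build_crown_grid <- function(geom, n_layers = 6, n_points = 12) {
  stopifnot(inherits(geom, "crown_geometry"), n_layers >= 1, n_points >= 1)
  r <- geom$radius
  if (n_points == 1) {
    tpl <- data.frame(px = 0, py = 0)
  } else if (n_points <= 4) {
    az <- 2 * pi * (seq_len(n_points) - 1) / n_points
    tpl <- data.frame(px = r / 2 * sin(az), py = r / 2 * cos(az))
  } else {
    n_in <- max(1, round(n_points / 3))
    n_out <- n_points - n_in
    az_in <- 2 * pi * (seq_len(n_in) - 0.5) / n_in
    az_out <- 2 * pi * (seq_len(n_out) - 1) / n_out
    tpl <- data.frame(px = c(r / 3 * sin(az_in), 2 * r / 3 * sin(az_out)),
                      py = c(r / 3 * cos(az_in), 2 * r / 3 * cos(az_out)))
  }
  z_top <- geom$height
  dz <- geom$depth / n_layers
  g <- do.call(rbind, lapply(seq_len(n_layers), function(l) {
    data.frame(layer = l, point = seq_len(n_points),
               x = geom$x + tpl$px, y = geom$y + tpl$py,
               z = z_top - (l - 0.5) * dz)
  }))
  g$leaf_area <- geom$leaf_area / (n_layers * n_points)
  attr(g, "geom") <- geom
  class(g) <- c("crown_grid", "data.frame")
  g
}

# Path length of rays through a vertical cylinder (vectorized over origins).
# ox, oy, oz: ray origins; (dx, dy, dz): unit direction (shared); cylinder
# centred at (cx, cy) with radius r, z in [z0, z1]. Returns the length of
# the forward (t > 0) intersection of each ray with the cylinder.
ray_cylinder_path <- function(ox, oy, oz, dx, dy, dz, cx, cy, r, z0, z1) {
  rx <- ox - cx
  ry <- oy - cy
  a <- dx^2 + dy^2
  n <- length(ox)
  if (a < 1e-12) {
    # vertical ray: inside the circle or not
    inside <- rx^2 + ry^2 <= r^2
    tlo <- (z0 - oz) / dz
    thi <- (z1 - oz) / dz
    t0 <- pmax(pmin(tlo, thi), 0)
    t1 <- pmax(pmax(tlo, thi), 0)
    return(ifelse(inside, pmax(t1 - t0, 0), 0))
  }
  b <- 2 * (rx * dx + ry * dy)
  cc <- rx^2 + ry^2 - r^2
  disc <- b^2 - 4 * a * cc
  hit <- disc > 0
  out <- numeric(n)
  if (!any(hit)) return(out)
  sq <- sqrt(pmax(disc, 0))
  t0 <- (-b - sq) / (2 * a)
  t1 <- (-b + sq) / (2 * a)
  if (abs(dz) > 1e-12) {
    tz0 <- (z0 - oz) / dz
    tz1 <- (z1 - oz) / dz
    zlo <- pmin(tz0, tz1)
    zhi <- pmax(tz0, tz1)
    t0 <- pmax(t0, zlo)
    t1 <- pmin(t1, zhi)
  } else {
    inz <- oz >= z0 & oz <= z1
    t0[!inz] <- 0
    t1[!inz] <- 0
  }
  t0 <- pmax(t0, 0)
  t1 <- pmax(t1, 0)
  out[hit] <- pmax(t1 - t0, 0)[hit]
  out
}

# Optical path (leaf area per unit ground... actually leaf area per m2 along
# the ray) accumulated through the target crown and all neighbour crowns.
path_lai <- function(grid, dx, dy, dz, neighbours) {
  geom <- attr(grid, "geom")
  crowns <- c(list(geom), neighbours)
  tot <- numeric(nrow(grid))
  for (cr in crowns) {
    len <- ray_cylinder_path(grid$x, grid$y, grid$z, dx, dy, dz,
                             cr$x, cr$y, cr$radius,
                             cr$crown_base, cr$height)
    tot <- tot + cr$lad * len
  }
  tot
}

sun_direction <- function(zenith, azimuth) {
  z <- zenith * pi / 180
  a <- azimuth * pi / 180
  c(dx = sin(z) * sin(a), dy = sin(z) * cos(a), dz = cos(z))
}

# Uniform-overcast sky quadrature: 3 zenith x 4 azimuth directions with
# cos-weighted zenith weights.
.SKY_QUAD <- local({
  zen <- c(15, 45, 75)
  w_z <- cos(zen * pi / 180) * sin(zen * pi / 180)
  w_z <- w_z / sum(w_z)
  az <- c(45, 135, 225, 315)
  q <- expand.grid(zenith = zen, azimuth = az)
  q$w <- rep(w_z, times = length(az)) / length(az)
  # leaf projection G/cos(zenith), normalized so the unattenuated per-leaf
  # diffuse irradiance equals the horizontal diffuse flux exactly
  q$proj <- 0.5 / cos(q$zenith * pi / 180)
  q$proj <- q$proj / sum(q$w * q$proj)
  q
})

#' Absorbed PAR and sunlit fractions for every crown sub-volume
#'
#' For each gridpoint the direct-beam transmittance is computed from the
#' optical path length through the own crown and any intersected neighbour
#' cylinders (extinction 0.5 per unit path leaf area, the spherical
#' leaf-angle value); the sunlit leaf fraction of the sub-volume equals the
#' beam transmittance. Diffuse PAR is attenuated along a 3-zenith x
#' 4-azimuth quadrature of a uniform overcast sky. Shaded leaves receive
#' the local diffuse stream plus a single-scattering beam term; sunlit
#' leaves additionally receive the unattenuated direct beam.
#'
#' @param grid A [build_crown_grid()] object.
#' @param PAR Incident PAR above the canopy (umol m-2 s-1).
#' @param zenith,azimuth Solar position (degrees).
#' @param structure A [canopy_structure()] object (optical properties).
#' @param neighbours List of [crown_geometry()] objects shading the target
#'   crown (may be empty).
#' @return `grid` with columns added: `sunlit_frac`, `APAR_sun`,
#'   `APAR_shade` (per unit leaf area, umol m-2 s-1).
#' @export
gridpoint_apar <- function(grid, PAR, zenith, azimuth = 0,
                           structure = canopy_structure(),
                           neighbours = list()) {
  alpha <- structure$absorptance
  sigma_s <- unname(structure$leaf_reflectance["par"] +
                      structure$leaf_transmittance["par"])
  G <- 0.5  # spherical leaf angle distribution projection

  beam_up <- is.finite(zenith) && zenith < 88 && PAR > 0
  fd <- if (beam_up) diffuse_fraction(PAR) else 1
  Pd <- fd * PAR
  Pb <- (1 - fd) * PAR

  # local diffuse irradiance per unit leaf area, as a fraction of the
  # above-canopy diffuse flux: each sky direction is attenuated along its
  # slant path and projected onto the leaves with G/cos(zenith) (for a
  # spherical distribution the unattenuated sum is ~1, i.e. per-leaf
  # diffuse irradiance equals the horizontal diffuse flux)
  tau_d <- numeric(nrow(grid))
  for (i in seq_len(nrow(.SKY_QUAD))) {
    d <- sun_direction(.SKY_QUAD$zenith[i], .SKY_QUAD$azimuth[i])
    pl <- path_lai(grid, d["dx"], d["dy"], d["dz"], neighbours)
    tau_d <- tau_d + .SKY_QUAD$w[i] * .SKY_QUAD$proj[i] * exp(-G * pl)
  }

  if (beam_up) {
    d <- sun_direction(zenith, azimuth)
    pl_b <- path_lai(grid, d["dx"], d["dy"], d["dz"], neighbours)
    tau_b <- exp(-G * pl_b)
  } else {
    tau_b <- numeric(nrow(grid))
  }

  scatter <- 0.5 * sigma_s * Pb * (1 - tau_b)  # single-scattering source
  grid$sunlit_frac <- tau_b
  grid$APAR_shade <- alpha * (Pd * tau_d + scatter)
  # sunlit leaves intercept the beam at the mean projected irradiance for a
  # spherical leaf angle distribution, G/cos(z) per unit leaf area
  beam_leaf <- if (beam_up) G / cos(min(zenith, 85) * pi / 180) * Pb else 0
  grid$APAR_sun <- grid$APAR_shade + alpha * beam_leaf
  grid
}

#' Multilayer canopy photosynthesis
#'
#' Solves the coupled leaf model separately for the sunlit and shaded leaf
#' area of every crown sub-volume (after [gridpoint_apar()]) and aggregates
#' to canopy net photosynthesis per unit leaf area. Photosynthetic
#' capacities may vary by layer (see [layer_capacity_profile()]).
#'
#' @param env An [env_conditions()] object (its `PAR` should match the PAR
#'   used in [gridpoint_apar()]).
#' @param grid A crown grid with APAR columns filled.
#' @param params Leaf-level [photo_params()]; `Vcmax25_layers` /
#'   `Jmax25_layers` override per layer when supplied.
#' @param Vcmax25_layers,Jmax25_layers Optional per-layer capacities at
#'   25 degC (length = number of layers, layer 1 = top).
#' @param kin,stomatal Kinetic and stomatal parameter objects.
#' @param ... Passed to [solve_coupled_leaf()].
#' @return An object of class `canopy_flux` with `Anet` per unit leaf area
#'   and the per-sub-volume flux table as `$detail`.
#' @export
multilayer_flux <- function(env, grid, params = photo_params(),
                            Vcmax25_layers = NULL, Jmax25_layers = NULL,
                            kin = kinetic_constants(),
                            stomatal = stomatal_params(), ...) {
  stopifnot(!is.null(grid$APAR_sun))
  n_layers <- max(grid$layer)
  vc <- if (is.null(Vcmax25_layers)) rep(params$Vcmax25, n_layers) else Vcmax25_layers
  jm <- if (is.null(Jmax25_layers)) rep(params$Jmax25, n_layers) else Jmax25_layers
  stopifnot(length(vc) == n_layers, length(jm) == n_layers)

  n <- nrow(grid)
  if (stomatal$g0 == 0) {
    # both light classes of all sub-volumes in one vectorized solve
    sol <- solve_leaf_vec(env,
                          APAR = c(grid$APAR_sun, grid$APAR_shade),
                          Vcmax25 = rep(vc[grid$layer], 2),
                          Jmax25 = rep(jm[grid$layer], 2),
                          params = params, kin = kin, stomatal = stomatal, ...)
    anet_sun <- sol$Anet[seq_len(n)]
    anet_shade <- sol$Anet[n + seq_len(n)]
  } else {
    anet_sun <- anet_shade <- numeric(n)
    solve_one <- function(apar, layer) {
      cp <- params
      cp$Vcmax25 <- vc[layer]
      cp$Jmax25 <- jm[layer]
      st <- tryCatch(
        solve_coupled_leaf(env, cp, kin, stomatal, APAR = apar, ...),
        error = function(e) stop(sprintf("sub-volume (layer %d): %s",
                                         layer, conditionMessage(e)),
                                 call. = FALSE))
      st$Anet
    }
    for (i in seq_len(n)) {
      if (grid$sunlit_frac[i] > 1e-6) {
        anet_sun[i] <- solve_one(grid$APAR_sun[i], grid$layer[i])
      }
      anet_shade[i] <- solve_one(grid$APAR_shade[i], grid$layer[i])
    }
  }
  la_sun <- grid$leaf_area * grid$sunlit_frac
  la_shade <- grid$leaf_area * (1 - grid$sunlit_frac)
  total <- sum(anet_sun * la_sun + anet_shade * la_shade)
  structure(list(Anet = total / sum(grid$leaf_area),
                 detail = data.frame(grid,
                                     anet_sun = anet_sun,
                                     anet_shade = anet_shade)),
            class = "canopy_flux")
}

#' Default whole-tree-chamber stand layout
#'
#' A 2-row x 6-column array of chamber positions used as the neighbour
#' configuration for multilayer simulations.
#'
#' @param nrow,ncol Array dimensions.
#' @param spacing Chamber spacing (m).
#' @return data.frame with `tree_id`, `x_m`, `y_m`.
#' @export
chamber_layout <- function(nrow = 2, ncol = 6, spacing = 9) {
  g <- expand.grid(col = seq_len(ncol), row = seq_len(nrow))
  data.frame(tree_id = sprintf("C%02d", seq_len(nrow(g))),
             x_m = (g$col - 1) * spacing,
             y_m = (g$row - 1) * spacing)
}

#' Neighbour crown list from a stand layout
#'
#' @param layout data.frame with `tree_id`, `x_m`, `y_m`.
#' @param target_id Which tree is the target (its row is excluded).
#' @param geom A [crown_geometry()] template; every neighbour gets this
#'   geometry at its layout position.
#' @return List of [crown_geometry()] objects.
#' @export
neighbour_crowns <- function(layout, target_id, geom) {
  idx <- layout$tree_id != target_id
  lapply(which(idx), function(i) {
    crown_geometry(height = geom$height, radius = geom$radius,
                   leaf_area = geom$leaf_area, crown_base = geom$crown_base,
                   x = layout$x_m[i], y = layout$y_m[i])
  })
}
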