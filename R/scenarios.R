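# The eight canonical parameterization scenarios: three canopy schemes
# crossed with within-crown capacity gradients and seasonal thermal
# acclimation of Vcmax25/Jmax25.

#' Scenario specification
#'
#' Maps a scenario label to its scheme and parameterization flags:
#' \tabular{llll}{
#'   B1 \tab big-leaf   \tab no gradient \tab no acclimation \cr
#'   B2 \tab big-leaf   \tab no gradient \tab acclimation \cr
#'   T1 \tab two-leaf   \tab uniform     \tab no acclimation \cr
#'   T2 \tab two-leaf   \tab kn gradient \tab no acclimation \cr
#'   T3 \tab two-leaf   \tab kn gradient \tab acclimation \cr
#'   M1 \tab multilayer \tab uniform     \tab no acclimation \cr
#'   M2 \tab multilayer \tab layer profile \tab no acclimation \cr
#'   M3 \tab multilayer \tab layer profile \tab acclimation
#' }
#'
#' @param label One of `"B1"`, `"B2"`, `"T1"`, `"T2"`, `"T3"`, `"M1"`,
#'   `"M2"`, `"M3"`.
#' @return An object of class `scenario_spec` with `label`, `scheme`
#'   (`"bigleaf"`, `"twoleaf"` or `"multilayer"`), `capacity_gradient` and
#'   `acclimation` logicals.
#' @export
scenario_spec <- function(label) {
  tab <- scenario_table()
  i <- match(label, tab$label)
  if (is.na(i)) {
    stop("unknown scenario label '", label, "'; expected one of ",
         paste(tab$label, collapse = ", "))
  }
  structure(as.list(tab[i, ]), class = "scenario_spec")
}

#' All eight scenario definitions
#'
#' @return data.frame with one row per scenario.
#' @export
scenario_table <- function() {
  data.frame(
    label = c("B1", "B2", "T1", "T2", "T3", "M1", "M2", "M3"),
    scheme = c("bigleaf", "bigleaf", "twoleaf", "twoleaf", "twoleaf",
               "multilayer", "multilayer", "multilayer"),
    capacity_gradient = c(FALSE, FALSE, FALSE, TRUE, TRUE,
                          FALSE, TRUE, TRUE),
    acclimation = c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Seasonal thermal acclimation model for photosynthetic capacity
#'
#' Linear response of Vcmax25 and Jmax25 to the preceding growth
#' temperature: capacities decrease by `slope` umol m-2 s-1 per degC that
#' growth temperature exceeds the reference. Defaults are the fitted rates
#' of decrease, 1.9 (Vcmax) and 3.7 (Jmax) umol m-2 s-1 per degC, with the
#' reference growth temperature set to the experiment-mean daytime
#' temperature of 19.4 degC.
#'
#' @param slope_V,slope_J Change in Vcmax25 / Jmax25 per degC of growth
#'   temperature (umol m-2 s-1 degC-1; negative = decrease with warming).
#' @param T_ref Growth temperature (degC) at which the baseline capacities
#'   apply.
#' @param window Averaging window for growth temperature (days).
#' @param floor Minimum capacity as a fraction of the baseline.
#' @return An object of class `acclimation_model`.
#' @export
acclimation_model <- function(slope_V = -1.9, slope_J = -3.7,
                              T_ref = 19.4, window = 30, floor = 0.1) {
  stopifnot(window > 0, floor >= 0, floor < 1)
  structure(list(slope_V = slope_V, slope_J = slope_J, T_ref = T_ref,
                 window = window, floor = floor),
            class = "acclimation_model")
}

#' Growth temperature series
#'
#' For each day, the mean air temperature over the preceding `window` days
#' (the day itself excluded); shorter leading segments use whatever history
#' is available, and the first day falls back to its own mean.
#'
#' @param dates Vector of class `Date` (one per day, increasing).
#' @param tair_daily Daily mean air temperature (degC), same length.
#' @param window Window length in days (default 30).
#' @return Numeric vector of growth temperatures, one per day.
#' @export
growth_temperature <- function(dates, tair_daily, window = 30) {
  n <- length(tair_daily)
  if (n == 0) stop("empty temperature series")
  stopifnot(length(dates) == n)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - window)
    if (i == 1) tair_daily[1] else mean(tair_daily[lo:(i - 1)])
  }, numeric(1))
}

#' Acclimated photosynthetic capacities
#'
#' \eqn{V_{cmax25}(T_g) = V_{cmax25,ref} + s_V (T_g - T_{ref})} and likewise
#' for Jmax25, floored at `floor` x the reference value.
#'
#' @param Tgrowth Growth temperature (degC). Vectorized.
#' @param params Baseline [photo_params()].
#' @param acc An [acclimation_model()].
#' @return List with vectors `Vcmax25` and `Jmax25`.
#' @export
acclimate_capacities <- function(Tgrowth, params = photo_params(),
                                 acc = acclimation_model()) {
  v <- params$Vcmax25 + acc$slope_V * (Tgrowth - acc$T_ref)
  j <- params$Jmax25 + acc$slope_J * (Tgrowth - acc$T_ref)
  list(Vcmax25 = pmax(v, acc$floor * params$Vcmax25),
       Jmax25 = pmax(j, acc$floor * params$Jmax25))
}

#' Within-crown capacity profile
#'
#' Exponential decline of capacity with crown depth,
#' \eqn{v(d) = v_{sun} e^{-c (d-1)}} for layer depth d = 1 (top, sun
#' leaves) to `n_layers` (bottom, shade leaves), with the decay rate chosen
#' so the bottom layer is reduced by `shade_reduction` relative to the top
#' (defaults: 21% for Vcmax25, 26% for Jmax25).
#'
#' @param sun_value Capacity of the top (sun) layer (umol m-2 s-1).
#' @param shade_reduction Fractional reduction at the bottom layer, in
#'   [0, 1).
#' @param n_layers Number of crown layers.
#' @return Numeric vector of per-layer capacities, layer 1 first.
#' @export
layer_capacity_profile <- function(sun_value, shade_reduction, n_layers = 6) {
  stopifnot(shade_reduction >= 0, shade_reduction < 1, n_layers >= 1)
  if (n_layers == 1) return(sun_value)
  cc <- -log(1 - shade_reduction) / (n_layers - 1)
  sun_value * exp(-cc * (seq_len(n_layers) - 1))
}

#' Run a parameterization scenario over a forcing period
#'
#' Drives the scenario's canopy scheme with a meteorological series and a
#' daily tree-structure series, resolving photosynthetic capacities per
#' calendar month (or per day) when the scenario acclimates to growth
#' temperature, and applying the within-crown capacity gradient where the
#' scenario requires it.
#'
#' @param label Scenario label (see [scenario_spec()]).
#' @param met data.frame with columns `timestamp` (POSIXct), `tair_c`,
#'   `vpd_kpa`, `par_umol_m2_s` and optionally `ca_umol_mol` (default 400).
#' @param trees data.frame with columns `date`, `height_m`, `crown_base_m`,
#'   `crown_radius_m`, `leaf_area_m2` (one row per day).
#' @param layout Stand layout data.frame (`tree_id`, `x_m`, `y_m`) for
#'   multilayer neighbour shading.
#' @param target_id Tree id of the simulated (target) chamber.
#' @param params,kin,stomatal Parameter objects.
#' @param acc An [acclimation_model()].
#' @param structure A [canopy_structure()] template; its `LAI` is replaced
#'   per day from the tree series.
#' @param shade_reduction_V,shade_reduction_J Bottom-layer capacity
#'   reductions for the multilayer profile.
#' @param acclim_step `"monthly"` (capacities re-assigned per calendar
#'   month from that month's mean growth temperature) or `"daily"`.
#' @param site Named vector `c(lat = , lon = )` for solar geometry.
#' @param n_layers,n_points Crown grid resolution.
#' @return data.frame of class `flux_series`: `timestamp`, `chamber_id`,
#'   `anet_umol_m2leaf_s`, `par_umol_m2_s`, `tair_c`, `vpd_kpa`,
#'   `scenario`, `source`, `flag`.
#' @export
run_scenario <- function(label, met, trees,
                         layout = chamber_layout(), target_id = NULL,
                         params = photo_params(),
                         kin = kinetic_constants(),
                         stomatal = stomatal_params(),
                         acc = acclimation_model(),
                         structure = canopy_structure(),
                         shade_reduction_V = 0.21, shade_reduction_J = 0.26,
                         acclim_step = c("monthly", "daily"),
                         site = c(lat = -33.62, lon = 150.74),
                         n_layers = 6, n_points = 12) {
  spec <- scenario_spec(label)
  acclim_step <- match.arg(acclim_step)
  stopifnot(all(c("timestamp", "tair_c", "vpd_kpa", "par_umol_m2_s") %in%
                  names(met)))
  if (is.null(met$ca_umol_mol)) met$ca_umol_mol <- 400
  if (is.null(target_id)) {
    ctr <- c(mean(layout$x_m), mean(layout$y_m))
    target_id <- layout$tree_id[
      which.min((layout$x_m - ctr[1])^2 + (layout$y_m - ctr[2])^2)]
  }

  day <- as.Date(met$timestamp, tz = attr(met$timestamp, "tzone") %||% "UTC")
  trees$date <- as.Date(trees$date)
  tri <- match(day, trees$date)
  if (anyNA(tri)) stop("tree series does not cover the met period")

  # daily growth temperature and capacity assignment
  ud <- sort(unique(day))
  tair_daily <- vapply(split(met$tair_c, day), mean, numeric(1))
  tg <- growth_temperature(ud, tair_daily[as.character(ud)], acc$window)
  if (spec$acclimation) {
    if (acclim_step == "monthly") {
      mon <- format(ud, "%Y-%m")
      tg_mon <- vapply(split(tg, mon), mean, numeric(1))
      tg_eff <- tg_mon[mon]
    } else {
      tg_eff <- tg
    }
  } else {
    tg_eff <- rep(acc$T_ref, length(ud))  # identity: baseline capacities
  }
  caps <- acclimate_capacities(tg_eff, params, acc)
  names(caps$Vcmax25) <- names(caps$Jmax25) <- as.character(ud)

  sp <- solar_position(met$timestamp, site["lat"], site["lon"])

  anet <- numeric(nrow(met))
  flag <- character(nrow(met))
  # pre-build per-day geometry for the multilayer scheme
  for (d in as.character(ud)) {
    rows <- which(as.character(day) == d)
    tr <- trees[tri[rows[1]], ]
    geom <- crown_geometry(height = tr$height_m,
                           radius = tr$crown_radius_m,
                           leaf_area = tr$leaf_area_m2,
                           crown_base = tr$crown_base_m,
                           x = layout$x_m[layout$tree_id == target_id],
                           y = layout$y_m[layout$tree_id == target_id])
    LAI <- geom$leaf_area / geom$plan_area
    st <- structure
    st$LAI <- LAI
    dp <- params
    dp$Vcmax25 <- unname(caps$Vcmax25[d])
    dp$Jmax25 <- unname(caps$Jmax25[d])

    if (spec$scheme == "multilayer") {
      grid <- build_crown_grid(geom, n_layers, n_points)
      nbs <- neighbour_crowns(layout, target_id, geom)
      vc_layers <- if (spec$capacity_gradient) {
        layer_capacity_profile(dp$Vcmax25, shade_reduction_V, n_layers)
      } else rep(dp$Vcmax25, n_layers)
      jm_layers <- if (spec$capacity_gradient) {
        layer_capacity_profile(dp$Jmax25, shade_reduction_J, n_layers)
      } else rep(dp$Jmax25, n_layers)
    }

    for (i in rows) {
      env <- env_conditions(met$tair_c[i], met$vpd_kpa[i],
                            met$par_umol_m2_s[i], met$ca_umol_mol[i])
      res <- tryCatch({
        if (spec$scheme == "bigleaf") {
          bigleaf_flux(env, dp, st, kin, stomatal)$Anet
        } else if (spec$scheme == "twoleaf") {
          zen <- if (sp$above_horizon[i]) sp$zenith[i] else Inf
          twoleaf_flux(env, dp, st, kin, stomatal,
                       capacity_mode = if (spec$capacity_gradient) "kn" else "uniform",
                       zenith = zen)$Anet
        } else {
          zen <- if (sp$above_horizon[i]) sp$zenith[i] else Inf
          g <- gridpoint_apar(grid, env$PAR, zen, sp$azimuth[i], st, nbs)
          multilayer_flux(env, g, dp, vc_layers, jm_layers, kin, stomatal)$Anet
        }
      }, error = function(e) e)
      if (inherits(res, "error")) {
        anet[i] <- NA_real_
        flag[i] <- conditionMessage(res)
      } else {
        anet[i] <- res
      }
    }
  }

  out <- data.frame(timestamp = met$timestamp,
                    chamber_id = target_id,
                    anet_umol_m2leaf_s = anet,
                    par_umol_m2_s = met$par_umol_m2_s,
                    tair_c = met$tair_c,
                    vpd_kpa = met$vpd_kpa,
                    scenario = label,
                    source = "modelled",
                    flag = flag,
                    stringsAsFactors = FALSE)
  class(out) <- c("flux_series", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Idealized temperature sweep for a scheme
#'
#' Sweeps air temperature at fixed PAR, VPD and CO2 for one of the four
#' model levels (single leaf, big-leaf, two-leaf, multilayer chamber
#' crown), the standard protocol for locating temperature optima.
#'
#' @param scheme `"leaf"`, `"bigleaf"`, `"twoleaf"` or `"multilayer"`.
#' @param Tair Air temperatures to sweep (degC).
#' @param PAR Incident PAR (umol m-2 s-1).
#' @param VPD Air vapour pressure deficit (kPa).
#' @param Ca CO2 (umol mol-1).
#' @param LAI Leaf area index.
#' @param zenith,azimuth Solar position for the radiation partition. The
#'   default zenith of 33 degrees is the mean solar zenith of
#'   saturating-light (PAR > 1200) hours over the chamber measurement
#'   period at the site.
#' @param params,kin,stomatal,structure Parameter objects (`structure$LAI`
#'   is overridden by `LAI`).
#' @param gb_leaf Boundary-layer conductance used for the `"leaf"` scheme
#'   (mol m-2 s-1). The default (infinite, the well-coupled limit) pins
#'   leaf temperature at air temperature, matching the cuvette-controlled
#'   leaf-scale measurement protocol; finite values model open-air leaves.
#'   Canopy schemes use the chamber aerodynamics of [env_conditions()].
#' @param geom Crown geometry for the multilayer scheme; default is a
#'   chamber-like cylinder (3 m crown depth, 0.6 m radius) whose leaf area
#'   matches `LAI` on its plan area.
#' @param layout Neighbour layout for the multilayer scheme.
#' @return data.frame with `Tair` and `Anet` (per unit leaf area; for
#'   `"leaf"`, leaf net photosynthesis).
#' @export
temperature_sweep <- function(scheme = c("leaf", "bigleaf", "twoleaf",
                                         "multilayer"),
                              Tair = seq(10, 45, by = 0.5),
                              PAR = 1500, VPD = 1, Ca = 400, LAI = 3.3,
                              zenith = 33, azimuth = 180,
                              params = photo_params(),
                              kin = kinetic_constants(),
                              stomatal = stomatal_params(),
                              structure = canopy_structure(),
                              geom = NULL, layout = chamber_layout(),
                              gb_leaf = Inf) {
  scheme <- match.arg(scheme)
  structure$LAI <- LAI
  if (scheme == "multilayer") {
    if (is.null(geom)) {
      geom <- crown_geometry(height = 3.45, radius = 0.6,
                             leaf_area = LAI * pi * 0.6^2, crown_base = 0.45)
    }
    ctr <- c(mean(layout$x_m), mean(layout$y_m))
    target_id <- layout$tree_id[
      which.min((layout$x_m - ctr[1])^2 + (layout$y_m - ctr[2])^2)]
    geom$x <- layout$x_m[layout$tree_id == target_id]
    geom$y <- layout$y_m[layout$tree_id == target_id]
    nbs <- neighbour_crowns(layout, target_id, geom)
    grid <- gridpoint_apar(build_crown_grid(geom), PAR, zenith, azimuth,
                           structure, nbs)
  }
  anet <- vapply(Tair, function(tt) {
    env <- env_conditions(tt, VPD, PAR, Ca)
    switch(scheme,
           leaf = solve_coupled_leaf(env, params, kin, stomatal,
                                     absorptance = structure$absorptance,
                                     gb = gb_leaf)$Anet,
           bigleaf = bigleaf_flux(env, params, structure, kin, stomatal)$Anet,
           twoleaf = twoleaf_flux(env, params, structure, kin, stomatal,
                                  zenith = zenith)$Anet,
           multilayer = multilayer_flux(env, grid, params,
                                        kin = kin, stomatal = stomatal)$Anet)
  }, numeric(1))
  data.frame(Tair = Tair, Anet = anet)
}
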