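# Synthetic whole-tree-chamber data: meteorological forcing, tree growth
# trajectories, and noisy pseudo-observations of canopy flux. All
# generators are pure functions of their configuration and seed, so every
# pipeline stage runs without external data.

#' Synthetic meteorology configuration
#'
#' Defaults emulate the chamber experiment's measurement period at the
#' Richmond NSW site: austral spring through late autumn, 15-min cadence,
#' daytime mean temperature 21.9 degC, daytime mean VPD 1.3 kPa, CO2 fixed
#' at 400 umol mol-1.
#'
#' @param start,end Dates (coerced with [as.Date()]).
#' @param cadence_min Sampling interval in minutes; must divide 60.
#' @param t_day_mean Target mean daytime air temperature (degC).
#' @param t_day_range Plausible range of daily daytime means (degC);
#'   informational, not enforced pointwise.
#' @param vpd_day_mean Target mean daytime VPD (kPa).
#' @param vpd_range Daytime VPD range (kPa); the upper bound clips the
#'   series.
#' @param ca CO2 mole fraction (umol mol-1).
#' @param lat,lon Site coordinates (degrees).
#' @param utc_offset Civil time offset of the timestamps (hours).
#' @param seed Random seed.
#' @return List of class `synth_met_config`.
#' @export
synth_met_config <- function(start = "2013-09-13", end = "2014-05-26",
                             cadence_min = 15,
                             t_day_mean = 21.9, t_day_range = c(13.6, 31.4),
                             vpd_day_mean = 1.3, vpd_range = c(1.1, 6.1),
                             ca = 400, lat = -33.62, lon = 150.74,
                             utc_offset = 10, seed = 1) {
  start <- as.Date(start); end <- as.Date(end)
  if (end <= start) stop("degenerate date range: end must follow start")
  if (60 %% cadence_min != 0) stop("cadence must divide 60 minutes")
  stopifnot(t_day_mean >= t_day_range[1], t_day_mean <= t_day_range[2],
            vpd_day_mean >= vpd_range[1] - 0.5, vpd_day_mean <= vpd_range[2])
  structure(list(start = start, end = end, cadence_min = cadence_min,
                 t_day_mean = t_day_mean, t_day_range = t_day_range,
                 vpd_day_mean = vpd_day_mean, vpd_range = vpd_range,
                 ca = ca, lat = lat, lon = lon, utc_offset = utc_offset,
                 seed = seed),
            class = "synth_met_config")
}

#' Generate synthetic chamber meteorology
#'
#' Diurnal temperature follows a sinusoid (afternoon maximum) around a
#' seasonally drifting daily mean with AR(1) day-to-day anomalies; PAR is a
#' clear-sky envelope from solar geometry scaled by a per-day sky-quality
#' multiplier; VPD derives from temperature and a slowly varying humidity
#' state. After generation the series is calibrated with a constant
#' temperature offset and a VPD scale factor so the daytime means equal the
#' configured targets exactly.
#'
#' @param config A [synth_met_config()].
#' @return data.frame with `timestamp` (POSIXct, fixed civil offset),
#'   `tair_c`, `vpd_kpa`, `par_umol_m2_s`, `ca_umol_mol`.
#' @export
synth_met <- function(config = synth_met_config()) {
  set.seed(config$seed)
  tz <- sprintf("Etc/GMT%+d", -config$utc_offset)  # POSIX sign convention
  days <- seq(config$start, config$end, by = "day")
  nd <- length(days)
  doy <- as.integer(format(days, "%j"))

  # seasonal daily-mean cycle peaking mid-January (austral summer)
  seas <- 17.5 + 6.5 * cos(2 * pi * (doy - 15) / 365.25)
  anom <- as.numeric(stats::arima.sim(list(ar = 0.6), nd, sd = 1.6))
  t_daily <- seas + anom
  dtr <- pmax(stats::rnorm(nd, 9, 1.5), 4)          # diurnal range
  quality <- 0.35 + 0.65 * stats::rbeta(nd, 4, 1.6) # sky clearness
  rh_state <- 0.55 + as.numeric(stats::arima.sim(list(ar = 0.75), nd, sd = 0.06))
  rh_state <- pmin(pmax(rh_state, 0.3), 0.9)

  steps <- 24 * 60 / config$cadence_min
  hour <- rep(seq(0, 24 - config$cadence_min / 60,
                  by = config$cadence_min / 60), nd)
  di <- rep(seq_len(nd), each = steps)
  timestamp <- as.POSIXct(paste(days[di], "00:00:00"), tz = tz) + hour * 3600

  tair <- t_daily[di] + 0.5 * dtr[di] * cos(2 * pi * (hour - 14.5) / 24)

  sp <- solar_position(timestamp, config$lat, config$lon)
  cosz <- pmax(cos(sp$zenith * pi / 180), 0)
  par <- 2350 * cosz^1.15 * quality[di]
  par[par < 1] <- 0

  rh <- pmin(pmax(rh_state[di] - 0.012 * (tair - t_daily[di]), 0.2), 0.98)
  vpd <- esat(tair) * (1 - rh)

  day_mask <- par > 0
  tair <- tair + (config$t_day_mean - mean(tair[day_mask]))
  vpd <- vpd * (config$vpd_day_mean / mean(vpd[day_mask]))
  vpd <- pmin(pmax(vpd, 0.05), config$vpd_range[2])
  # the multiplicative clip barely moves the mean; one more exact pass
  vpd[day_mask] <- vpd[day_mask] *
    (config$vpd_day_mean / mean(vpd[day_mask]))

  data.frame(timestamp = timestamp, tair_c = tair, vpd_kpa = vpd,
             par_umol_m2_s = par, ca_umol_mol = config$ca)
}

#' Synthetic tree growth configuration
#'
#' @param initial_height,final_height Tree height at the start and end of
#'   the period (m).
#' @param radius_coef,radius_exp Allometric crown radius = coef x
#'   height^exp (m); defaults give a 0.6 m radius at 3 m height.
#' @param max_radius Chamber-imposed cap on crown radius (m; chambers are
#'   3.25 m in diameter).
#' @param crown_base Height to crown base (m).
#' @param leaf_area_mean Target period-mean crown leaf area (m2).
#' @param measure_interval Days between synthetic height "measurements"
#'   (linearly interpolated in between, mirroring fortnightly surveys).
#' @param seed Random seed.
#' @return List of class `tree_growth_config`.
#' @export
tree_growth_config <- function(initial_height = 3, final_height = 8,
                               radius_coef = 0.6 / 3^0.8, radius_exp = 0.8,
                               max_radius = 1.625, crown_base = 0.45,
                               leaf_area_mean = 3.3,
                               measure_interval = 14, seed = 1) {
  stopifnot(final_height >= initial_height, radius_coef > 0,
            leaf_area_mean > 0, measure_interval >= 1)
  structure(list(initial_height = initial_height,
                 final_height = final_height,
                 radius_coef = radius_coef, radius_exp = radius_exp,
                 max_radius = max_radius, crown_base = crown_base,
                 leaf_area_mean = leaf_area_mean,
                 measure_interval = measure_interval, seed = seed),
            class = "tree_growth_config")
}

#' Generate a daily tree-structure series
#'
#' Height grows monotonically between noisy fortnightly "measurements"
#' (piecewise-linear interpolation to daily values), crown radius follows
#' the power-law allometry capped at the chamber radius, and leaf area
#' follows a logistic trajectory rescaled so its period mean equals the
#' configured target.
#'
#' @param config A [tree_growth_config()].
#' @param start,end Date range (defaults match [synth_met_config()]).
#' @param tree_id Identifier written to the series.
#' @return data.frame with `date`, `tree_id`, `height_m`, `crown_base_m`,
#'   `crown_radius_m`, `leaf_area_m2`.
#' @export
synth_trees <- function(config = tree_growth_config(),
                        start = "2013-09-13", end = "2014-05-26",
                        tree_id = "C01") {
  set.seed(config$seed)
  dates <- seq(as.Date(start), as.Date(end), by = "day")
  nd <- length(dates)
  t_rel <- (seq_len(nd) - 1) / (nd - 1)

  meas_idx <- unique(c(seq(1, nd, by = config$measure_interval), nd))
  h_true <- config$initial_height +
    (config$final_height - config$initial_height) * t_rel[meas_idx]
  h_meas <- cummax(h_true + stats::rnorm(length(meas_idx), 0, 0.03))
  height <- stats::approx(meas_idx, h_meas, xout = seq_len(nd))$y
  height <- cummax(height)

  radius <- pmin(config$radius_coef * height^config$radius_exp,
                 config$max_radius)

  la <- 1 / (1 + exp(-6 * (t_rel - 0.45)))  # logistic growth shape
  la <- la * (config$leaf_area_mean / mean(la))

  data.frame(date = dates, tree_id = tree_id, height_m = height,
             crown_base_m = config$crown_base, crown_radius_m = radius,
             leaf_area_m2 = la)
}

#' Add measurement noise to a modelled flux series
#'
#' Pseudo-observations are the truth plus AR(1) Gaussian noise, standing in
#' for the temporally correlated measurement error of a chamber flux
#' system.
#'
#' @param truth A flux-series data.frame (e.g. from [run_scenario()]).
#' @param sigma Marginal noise standard deviation (umol m-2 s-1).
#' @param ar1 Lag-1 autocorrelation of the noise, |ar1| < 1.
#' @param seed Random seed.
#' @return The series with noise added and `source = "observed"`.
#' @export
synth_observations <- function(truth, sigma = 1.5, ar1 = 0.4, seed = 1) {
  stopifnot(sigma >= 0, abs(ar1) < 1)
  set.seed(seed)
  out <- truth
  n <- nrow(truth)
  if (sigma > 0) {
    noise <- if (ar1 == 0) {
      stats::rnorm(n, 0, sigma)
    } else {
      as.numeric(stats::arima.sim(list(ar = ar1), n,
                                  sd = sigma * sqrt(1 - ar1^2)))
    }
    out$anet_umol_m2leaf_s <- out$anet_umol_m2leaf_s + noise
  }
  out$source <- "observed"
  out
}
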