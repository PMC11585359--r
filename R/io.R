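# Configuration and tabular I/O. CSV is the single tabular dialect (comma,
# header row, '.' decimal, empty fields for missing); timestamps are ISO
# 8601 in a fixed civil offset.

.TIMESTAMP_FMT <- "%Y-%m-%dT%H:%M:%S%z"

#' Write / read the meteorological forcing CSV
#'
#' Columns: `timestamp`, `tair_c`, `vpd_kpa`, `par_umol_m2_s`,
#' `ca_umol_mol`.
#'
#' @param met Met data.frame (see [synth_met()]).
#' @param path File path.
#' @param utc_offset Civil offset (hours) used to render and parse
#'   timestamps.
#' @return `read_met_csv` returns the data.frame; `write_met_csv` its path,
#'   invisibly.
#' @export
write_met_csv <- function(met, path, utc_offset = 10) {
  out <- met
  out$timestamp <- format(met$timestamp, .TIMESTAMP_FMT,
                          tz = sprintf("Etc/GMT%+d", -utc_offset))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_met_csv
#' @export
read_met_csv <- function(path, utc_offset = 10) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  tz <- sprintf("Etc/GMT%+d", -utc_offset)
  x$timestamp <- as.POSIXct(x$timestamp, format = .TIMESTAMP_FMT, tz = tz)
  x
}

#' Write / read a flux-series CSV
#'
#' Columns: `timestamp`, `chamber_id`, `anet_umol_m2leaf_s`,
#' `par_umol_m2_s`, `tair_c`, `vpd_kpa` (extra columns pass through).
#'
#' @param series Flux-series data.frame.
#' @inheritParams write_met_csv
#' @export
write_flux_csv <- function(series, path, utc_offset = 10) {
  out <- series
  out$timestamp <- format(series$timestamp, .TIMESTAMP_FMT,
                          tz = sprintf("Etc/GMT%+d", -utc_offset))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_flux_csv
#' @export
read_flux_csv <- function(path, utc_offset = 10) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  tz <- sprintf("Etc/GMT%+d", -utc_offset)
  x$timestamp <- as.POSIXct(x$timestamp, format = .TIMESTAMP_FMT, tz = tz)
  class(x) <- c("flux_series", "data.frame")
  x
}

#' Read a tree-structure CSV
#'
#' Columns: `date`, `tree_id`, `height_m`, `crown_base_m`,
#' `crown_radius_m`, `leaf_area_m2`.
#'
#' @param path File path.
#' @export
read_tree_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$date <- as.Date(x$date)
  x
}

#' Read a stand-layout CSV
#'
#' Columns: `tree_id`, `x_m`, `y_m`.
#'
#' @param path File path.
#' @export
read_layout_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# every user-overridable scalar parameter, with its default
default_config_values <- function() {
  list(
    vcmax25 = 103.6, jmax25 = 178.2,
    ea_vcmax = 59700, ds_vcmax = 634,
    ea_jmax = 23800, ds_jmax = 627,
    hd = 200000, alpha_j = 0.26, theta_j = 0.57,
    rl25 = 0.9, q10 = 2.0,
    g1 = 2.4, g0 = 0,
    k = 0.5, kn = 0.3, kb = 0.5,
    leaf_reflectance_par = 0.093, leaf_reflectance_nir = 0.34,
    leaf_reflectance_thermal = 0.01,
    leaf_transmittance_par = 0.082, leaf_transmittance_nir = 0.49,
    leaf_transmittance_thermal = 0.05,
    soil_reflectance_par = 0.1, soil_reflectance_nir = 0.3,
    soil_reflectance_thermal = 0.05,
    gamma_star25 = 42.75, kc25 = 404.9, ko25 = 278.4,
    ea_gamma_star = 37830, ea_kc = 79430, ea_ko = 36380, oi = 210,
    acclim_slope_vcmax = -1.9, acclim_slope_jmax = -3.7,
    acclim_t_ref = 19.4, acclim_window = 30,
    shade_reduction_vcmax = 0.21, shade_reduction_jmax = 0.26,
    lat = -33.62, lon = 150.74, utc_offset = 10,
    wind = 2.5, scenario = "M3", seed = 1
  )
}

#' Load a run configuration
#'
#' Reads a YAML file of parameter overrides, merges it over the defaults
#' (the baseline parameter table), validates every key, and builds the
#' parameter objects used across the package. Unknown keys and out-of-range
#' values are rejected with the offending key named. With `path = NULL` the
#' pure defaults are returned.
#'
#' @param path Path to a YAML file, or `NULL` for defaults.
#' @return Object of class `run_config`: the resolved flat `values` list
#'   plus constructed `params`, `kin`, `stomatal`, `structure`, `acc`
#'   objects, `site`, `scenario` and `seed`.
#' @export
load_config <- function(path = NULL) {
  vals <- default_config_values()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (length(user)) {
      unknown <- setdiff(names(user), names(vals))
      if (length(unknown)) {
        stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
      }
      vals[names(user)] <- user
    }
  }
  cfg <- tryCatch({
    list(
      values = vals,
      params = photo_params(vals$vcmax25, vals$jmax25, vals$ea_vcmax,
                            vals$ds_vcmax, vals$ea_jmax, vals$ds_jmax,
                            vals$hd, vals$alpha_j, vals$theta_j,
                            vals$rl25, vals$q10),
      kin = kinetic_constants(vals$gamma_star25, vals$kc25, vals$ko25,
                              vals$ea_gamma_star, vals$ea_kc, vals$ea_ko,
                              vals$oi),
      stomatal = stomatal_params(vals$g1, vals$g0),
      structure = canopy_structure(
        k = vals$k, kn = vals$kn, kb = vals$kb,
        leaf_reflectance = c(par = vals$leaf_reflectance_par,
                             nir = vals$leaf_reflectance_nir,
                             thermal = vals$leaf_reflectance_thermal),
        leaf_transmittance = c(par = vals$leaf_transmittance_par,
                               nir = vals$leaf_transmittance_nir,
                               thermal = vals$leaf_transmittance_thermal),
        soil_reflectance = c(par = vals$soil_reflectance_par,
                             nir = vals$soil_reflectance_nir,
                             thermal = vals$soil_reflectance_thermal)),
      acc = acclimation_model(vals$acclim_slope_vcmax,
                              vals$acclim_slope_jmax,
                              vals$acclim_t_ref, vals$acclim_window),
      site = c(lat = vals$lat, lon = vals$lon),
      scenario = vals$scenario,
      seed = vals$seed
    )
  }, error = function(e) {
    stop("invalid configuration: ", conditionMessage(e), call. = FALSE)
  })
  scenario_spec(cfg$scenario)  # validates the label
  class(cfg) <- "run_config"
  cfg
}

#' Persist the resolved configuration beside run outputs
#'
#' @param config A `run_config` object.
#' @param path Output YAML path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config$values, path)
  invisible(path)
}
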