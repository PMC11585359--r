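#' Photosynthetic biochemistry parameters
#'
#' Constructs the parameter set describing leaf photosynthetic capacity and
#' its temperature dependence. Defaults are the baseline values for
#' field-grown *Eucalyptus tereticornis* sun leaves: Vcmax25 = 103.6 and
#' Jmax25 = 178.2 umol m-2 s-1 with peaked-Arrhenius temperature responses
#' (Hd fixed at 200 kJ mol-1 for both processes).
#'
#' @param Vcmax25 Maximum Rubisco carboxylation rate at 25 degC (umol m-2 s-1).
#' @param Jmax25 Potential electron transport rate at 25 degC (umol m-2 s-1).
#' @param Ea_V,dS_V Activation energy (J mol-1) and entropy term
#'   (J mol-1 K-1) for Vcmax.
#' @param Ea_J,dS_J Same for Jmax.
#' @param Hd Deactivation energy (J mol-1), shared by both processes.
#' @param alpha_J Quantum yield of electron transport on an absorbed-PAR
#'   basis (mol mol-1).
#' @param theta_J Curvature of the electron-transport light response
#'   (unitless, strictly between 0 and 1).
#' @param Rl25 Leaf respiration in light at 25 degC (umol m-2 s-1).
#' @param Q10 Proportional respiration increase per 10 degC.
#' @return An object of class `photo_params`.
#' @export
photo_params <- function(Vcmax25 = 103.6, Jmax25 = 178.2,
                         Ea_V = 59700, dS_V = 634,
                         Ea_J = 23800, dS_J = 627,
                         Hd = 200000,
                         alpha_J = 0.26, theta_J = 0.57,
                         Rl25 = 0.9, Q10 = 2.0) {
  stopifnot(Vcmax25 > 0, Jmax25 > 0, Ea_V > 0, dS_V > 0, Ea_J > 0, dS_J > 0,
            alpha_J > 0, Rl25 > 0, Q10 > 0)
  if (theta_J <= 0 || theta_J >= 1) {
    stop("theta_J must lie strictly between 0 and 1")
  }
  if (Hd <= Ea_V || Hd <= Ea_J) stop("Hd must exceed both activation energies")
  structure(list(Vcmax25 = Vcmax25, Jmax25 = Jmax25,
                 Ea_V = Ea_V, dS_V = dS_V, Ea_J = Ea_J, dS_J = dS_J,
                 Hd = Hd, alpha_J = alpha_J, theta_J = theta_J,
                 Rl25 = Rl25, Q10 = Q10),
            class = "photo_params")
}

#' Photosynthetic kinetic constants
#'
#' Michaelis constants, CO2 compensation point without day respiration, and
#' intercellular O2 used by the biochemical model, with simple Arrhenius
#' temperature scaling. Defaults are the widely used in-vivo estimates of
#' Bernacchi et al. (2001), expressed at 25 degC.
#'
#' @param GammaStar25 CO2 compensation point without day respiration at
#'   25 degC (umol mol-1).
#' @param Kc25 Michaelis constant for CO2 (umol mol-1).
#' @param Ko25 Michaelis constant for O2 (mmol mol-1).
#' @param Ea_GammaStar,Ea_Kc,Ea_Ko Activation energies (J mol-1).
#' @param Oi Intercellular O2 (mmol mol-1).
#' @return An object of class `kinetic_constants`.
#' @export
kinetic_constants <- function(GammaStar25 = 42.75, Kc25 = 404.9, Ko25 = 278.4,
                              Ea_GammaStar = 37830, Ea_Kc = 79430,
                              Ea_Ko = 36380, Oi = 210) {
  stopifnot(GammaStar25 > 0, Kc25 > 0, Ko25 > 0, Ea_GammaStar > 0,
            Ea_Kc > 0, Ea_Ko > 0, Oi > 0)
  structure(list(GammaStar25 = GammaStar25, Kc25 = Kc25, Ko25 = Ko25,
                 Ea_GammaStar = Ea_GammaStar, Ea_Kc = Ea_Kc, Ea_Ko = Ea_Ko,
                 Oi = Oi),
            class = "kinetic_constants")
}

#' Stomatal conductance parameters
#'
#' Parameters of the Medlyn optimal stomatal conductance model. The default
#' slope g1 = 2.4 kPa^0.5 with zero minimum conductance matches the baseline
#' leaf gas-exchange fits.
#'
#' @param g1 Slope parameter related to the marginal water cost of carbon
#'   (kPa^0.5).
#' @param g0 Minimum stomatal conductance to water vapour (mol m-2 s-1).
#' @return An object of class `stomatal_params`.
#' @export
stomatal_params <- function(g1 = 2.4, g0 = 0) {
  stopifnot(g1 > 0, g0 >= 0)
  structure(list(g1 = g1, g0 = g0), class = "stomatal_params")
}

#' Canopy structure and optical properties
#'
#' Canopy-level extinction coefficients and leaf/soil optical properties per
#' waveband. Defaults: extinction coefficient k = 0.5 for the big-leaf fPAR,
#' nitrogen (capacity) extinction kn = 0.3, nominal beam extinction kb = 0.5,
#' and PAR/NIR/thermal reflectance and transmittance from leaf optical
#' measurements on chamber-grown eucalypts.
#'
#' @param LAI Leaf area index (m2 m-2).
#' @param k Extinction coefficient for the big-leaf fPAR model.
#' @param kn Extinction coefficient of photosynthetic capacity (nitrogen).
#' @param kb Nominal (overhead sun) beam extinction coefficient.
#' @param leaf_reflectance,leaf_transmittance,soil_reflectance Named numeric
#'   vectors with elements `par`, `nir`, `thermal` (fractions).
#' @return An object of class `canopy_structure`. The PAR-band leaf
#'   absorptance `1 - reflectance - transmittance` is stored as
#'   `$absorptance`.
#' @export
canopy_structure <- function(LAI = 3.3, k = 0.5, kn = 0.3, kb = 0.5,
                             leaf_reflectance = c(par = 0.093, nir = 0.34, thermal = 0.01),
                             leaf_transmittance = c(par = 0.082, nir = 0.49, thermal = 0.05),
                             soil_reflectance = c(par = 0.1, nir = 0.3, thermal = 0.05)) {
  stopifnot(LAI >= 0, k > 0, k <= 1.5, kb > 0, kb <= 1.5, kn >= 0)
  for (v in list(leaf_reflectance, leaf_transmittance, soil_reflectance)) {
    stopifnot(all(v >= 0), all(v < 1))
  }
  if (any(leaf_reflectance + leaf_transmittance >= 1)) {
    stop("leaf reflectance + transmittance must be < 1 in every waveband")
  }
  structure(list(LAI = LAI, k = k, kn = kn, kb = kb,
                 leaf_reflectance = leaf_reflectance,
                 leaf_transmittance = leaf_transmittance,
                 soil_reflectance = soil_reflectance,
                 absorptance = unname(1 - leaf_reflectance["par"] -
                                        leaf_transmittance["par"])),
            class = "canopy_structure")
}

#' Environmental forcing for a leaf or canopy computation
#'
#' @param Tair Air temperature (degC).
#' @param VPD Air vapour pressure deficit (kPa).
#' @param PAR Incident photosynthetically active radiation (umol m-2 s-1).
#' @param Ca Ambient CO2 mole fraction (umol mol-1).
#' @param wind Wind speed at the leaf (m s-1); chamber default 2.5.
#' @param pressure Atmospheric pressure (kPa).
#' @return An object of class `env_conditions`.
#' @export
env_conditions <- function(Tair, VPD, PAR, Ca = 400, wind = 2.5,
                           pressure = 101.325) {
  stopifnot(PAR >= 0, VPD >= 0, Ca > 0, wind > 0, pressure > 0)
  structure(list(Tair = Tair, VPD = VPD, PAR = PAR, Ca = Ca,
                 wind = wind, pressure = pressure),
            class = "env_conditions")
}

#' Cylindrical crown geometry
#'
#' Tree crowns are approximated as upright cylinders with uniform leaf area
#' density.
#'
#' @param x,y Stem position (m); x east, y north.
#' @param height Total tree height (m).
#' @param crown_base Height to crown base (m).
#' @param radius Crown radius (m).
#' @param leaf_area Total one-sided crown leaf area (m2).
#' @return An object of class `crown_geometry`.
#' @export
crown_geometry <- function(height, radius, leaf_area,
                           crown_base = 0, x = 0, y = 0) {
  if (!(height > crown_base) || crown_base < 0 || radius <= 0 || leaf_area < 0) {
    stop("degenerate crown: need height > crown_base >= 0 and radius > 0")
  }
  depth <- height - crown_base
  structure(list(x = x, y = y, height = height, crown_base = crown_base,
                 radius = radius, leaf_area = leaf_area,
                 depth = depth,
                 volume = pi * radius^2 * depth,
                 plan_area = pi * radius^2,
                 lad = leaf_area / (pi * radius^2 * depth)),
            class = "crown_geometry")
}
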