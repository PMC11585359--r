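#' Peaked Arrhenius temperature response
#'
#' Evaluates the peaked (deactivating) Arrhenius function used for the
#' temperature dependence of Vcmax and Jmax:
#' \deqn{k(T_k) = k_{25} \exp\!\left[\frac{E_a (T_k - 298.15)}{298.15\, R\, T_k}\right]
#'   \frac{1 + \exp\!\left(\frac{298.15\,\Delta S - H_d}{298.15\, R}\right)}
#'        {1 + \exp\!\left(\frac{T_k\,\Delta S - H_d}{T_k\, R}\right)}}
#' The function equals `k25` exactly at 298.15 K and has a single interior
#' maximum when `Hd > Ea`.
#'
#' @param Tk Absolute temperature (K). Vectorized.
#' @param k25 Process rate at 25 degC (umol m-2 s-1).
#' @param Ea Activation energy (J mol-1).
#' @param dS Entropy term (J mol-1 K-1).
#' @param Hd Deactivation energy (J mol-1); must exceed `Ea`.
#' @return Process rate at `Tk`, same units as `k25`.
#' @seealso [peaked_arrhenius_topt()] for the closed-form optimum.
#' @export
#' @examples
#' peaked_arrhenius(298.15, 103.6, 59700, 634, 200000)  # = 103.6
peaked_arrhenius <- function(Tk, k25, Ea, dS, Hd = 200000) {
  stopifnot(k25 > 0, Ea > 0, dS > 0)
  if (Hd <= Ea) {
    stop("non-physical parameters: deactivation energy Hd must exceed Ea")
  }
  R <- 8.314
  Tref <- 298.15
  rise <- exp(Ea * (Tk - Tref) / (Tref * R * Tk))
  peak <- (1 + exp((Tref * dS - Hd) / (Tref * R))) /
    (1 + exp((Tk * dS - Hd) / (Tk * R)))
  k25 * rise * peak
}

#' Closed-form optimum of the peaked Arrhenius function
#'
#' The temperature at which [peaked_arrhenius()] attains its maximum:
#' \deqn{T_{opt} = \frac{H_d}{\Delta S - R \ln\!\left(E_a / (H_d - E_a)\right)}}
#'
#' @inheritParams peaked_arrhenius
#' @return Optimum temperature (K).
#' @export
peaked_arrhenius_topt <- function(Ea, dS, Hd = 200000) {
  if (Hd <= Ea) stop("non-physical parameters: Hd must exceed Ea")
  R <- 8.314
  Hd / (dS - R * log(Ea / (Hd - Ea)))
}

#' Simple Arrhenius temperature scaling
#'
#' Non-peaked Arrhenius scaling used for the photosynthetic kinetic constants
#' (Gamma*, Kc, Ko).
#'
#' @param Tk Absolute temperature (K). Vectorized.
#' @param k25 Value at 25 degC.
#' @param Ea Activation energy (J mol-1).
#' @return Value at `Tk`.
#' @export
arrhenius <- function(Tk, k25, Ea) {
  R <- 8.314
  Tref <- 298.15
  k25 * exp(Ea * (Tk - Tref) / (Tref * R * Tk))
}

#' Quadratic (parabolic) temperature response
#'
#' The symmetric parabola commonly fitted to light-saturated net
#' photosynthesis: \eqn{A_{sat} = A_{opt} - b (T - T_{optA})^2}.
#'
#' @param T Temperature (degC). Vectorized.
#' @param Aopt Rate at the optimum (umol m-2 s-1).
#' @param Topt Optimum temperature (degC).
#' @param b Curvature (umol m-2 s-1 degC-2); positive for a peaked response.
#' @return Rate at `T`.
#' @export
quadratic_response <- function(T, Aopt, Topt, b) {
  Aopt - b * (T - Topt)^2
}

#' Leaf day respiration
#'
#' Q10 scaling of leaf respiration in the light from its rate at 25 degC:
#' \eqn{R_l = R_{l25} \cdot Q_{10}^{(T_{leaf} - 25)/10}}.
#'
#' @param Tleaf Leaf temperature (degC). Vectorized.
#' @param Rl25 Respiration in light at 25 degC (umol m-2 s-1).
#' @param Q10 Proportional increase per 10 degC (unitless).
#' @return Respiration rate (umol m-2 s-1).
#' @export
day_respiration <- function(Tleaf, Rl25 = 0.9, Q10 = 2.0) {
  stopifnot(Rl25 > 0, Q10 > 0)
  Rl25 * Q10^((Tleaf - 25) / 10)
}
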