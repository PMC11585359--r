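# Leaf-scale gas exchange: FvCB biochemistry, Medlyn conductance and the
# coupled leaf energy balance. All canopy schemes call solve_coupled_leaf().

# Physical constants used throughout the energy balance
.CP_MOL <- 29.3        # molar heat capacity of air, J mol-1 K-1
.LAMBDA <- 44100       # latent heat of vaporisation, J mol-1
.SIGMA <- 5.67e-8      # Stefan-Boltzmann, W m-2 K-4
.PAR_J_PER_UMOL <- 0.2175  # energy content of PAR quanta, J umol-1 (4.6 umol J-1)

#' Saturation vapour pressure
#'
#' Tetens formula over water.
#'
#' @param T Temperature (degC). Vectorized.
#' @return Saturation vapour pressure (kPa).
#' @export
esat <- function(T) {
  0.61078 * exp(17.269 * T / (T + 237.3))
}

#' Electron transport rate
#'
#' Potential electron transport J as the lower root of the non-rectangular
#' hyperbola \eqn{\theta J^2 - (\alpha I + J_{max}) J + \alpha I J_{max} = 0}
#' where I is absorbed PAR.
#'
#' @param APAR Absorbed PAR (umol m-2 s-1). Vectorized.
#' @param Jmax Maximum electron transport rate at the current leaf
#'   temperature (umol m-2 s-1).
#' @param alpha_J Quantum yield on an absorbed-PAR basis (mol mol-1).
#' @param theta_J Curvature (unitless, in (0,1)).
#' @return Electron transport rate J (umol m-2 s-1).
#' @export
electron_transport <- function(APAR, Jmax, alpha_J = 0.26, theta_J = 0.57) {
  stopifnot(all(APAR >= 0), Jmax >= 0)
  if (theta_J <= 0 || theta_J >= 1) {
    stop("theta_J must lie strictly between 0 and 1")
  }
  aI <- alpha_J * APAR
  b <- aI + Jmax
  (b - sqrt(b^2 - 4 * theta_J * aI * Jmax)) / (2 * theta_J)
}

# Temperature-adjusted capacities and kinetic constants at Tleaf (degC)
leaf_biochem_at <- function(Tleaf, params, kin) {
  Tk <- Tleaf + 273.15
  list(
    Vcmax = peaked_arrhenius(Tk, params$Vcmax25, params$Ea_V, params$dS_V, params$Hd),
    Jmax = peaked_arrhenius(Tk, params$Jmax25, params$Ea_J, params$dS_J, params$Hd),
    GammaStar = arrhenius(Tk, kin$GammaStar25, kin$Ea_GammaStar),
    Kc = arrhenius(Tk, kin$Kc25, kin$Ea_Kc),
    Ko = arrhenius(Tk, kin$Ko25, kin$Ea_Ko),
    Rl = day_respiration(Tleaf, params$Rl25, params$Q10)
  )
}

#' FvCB net assimilation at given intercellular CO2
#'
#' Net photosynthesis as the minimum of the Rubisco-limited and
#' RuBP-regeneration-limited rates minus day respiration:
#' \deqn{A_c = V_{cmax} \frac{C_i - \Gamma^*}{C_i + K_c (1 + O_i/K_o)}, \quad
#'       A_j = \frac{J}{4} \frac{C_i - \Gamma^*}{C_i + 2\Gamma^*}}
#' Below the compensation point (\eqn{C_i \le \Gamma^*}) the gross term is
#' clamped at zero so that \eqn{A_{net} = -R_l}, keeping the response
#' continuous through zero.
#'
#' @param Ci Intercellular CO2 (umol mol-1). Vectorized.
#' @param Tleaf Leaf temperature (degC).
#' @param APAR Absorbed PAR (umol m-2 s-1).
#' @param params A [photo_params()] object.
#' @param kin A [kinetic_constants()] object.
#' @return List with `Anet`, gross branches `Ac` and `Aj`, `Rl`,
#'   `GammaStar`, and `limitation` ("Rubisco" or "RuBP").
#' @export
fvcb_assimilation <- function(Ci, Tleaf, APAR, params = photo_params(),
                              kin = kinetic_constants()) {
  stopifnot(all(Ci > 0))
  bc <- leaf_biochem_at(Tleaf, params, kin)
  J <- electron_transport(APAR, bc$Jmax, params$alpha_J, params$theta_J)
  Km <- bc$Kc * (1 + kin$Oi / bc$Ko)
  co2_lim <- pmax(Ci - bc$GammaStar, 0)
  Ac <- bc$Vcmax * co2_lim / (Ci + Km)
  Aj <- (J / 4) * co2_lim / (Ci + 2 * bc$GammaStar)
  gross <- pmin(Ac, Aj)
  list(Anet = gross - bc$Rl, Ac = Ac, Aj = Aj, Rl = bc$Rl,
       GammaStar = bc$GammaStar,
       limitation = ifelse(Ac <= Aj, "Rubisco", "RuBP"))
}

#' Medlyn optimal stomatal conductance
#'
#' \deqn{g_s = g_0 + 1.6 \left(1 + \frac{g_1}{\sqrt{D}}\right) \frac{A_{net}}{C_a}}
#' with D the leaf-to-air vapour pressure deficit floored at 0.05 kPa.
#' Negative assimilation returns the minimum conductance `g0`.
#'
#' @param Anet Net assimilation (umol m-2 s-1). Vectorized.
#' @param Ca Ambient CO2 (umol mol-1).
#' @param D Vapour pressure deficit (kPa).
#' @param stomatal A [stomatal_params()] object.
#' @return Stomatal conductance to water vapour (mol m-2 s-1).
#' @export
medlyn_gs <- function(Anet, Ca, D, stomatal = stomatal_params()) {
  stopifnot(Ca > 0)
  D <- pmax(D, 0.05)
  gs <- stomatal$g0 + 1.6 * (1 + stomatal$g1 / sqrt(D)) * Anet / Ca
  pmax(gs, stomatal$g0)
}

# Closed-stomata branch: no net CO2 exchange is possible. If gross
# photosynthesis at Ci = Ca would still be positive, internal CO2 rises to
# the point where demand vanishes and the measurable net flux is zero;
# otherwise (true dark) the flux is -Rl at Ci = Ca.
closed_stomata_state <- function(Tleaf, APAR, Ca, params, kin, g0) {
  a <- fvcb_assimilation(Ca, Tleaf, APAR, params, kin)
  if (a$Anet <= 0) {
    return(list(Ci = Ca, Anet = a$Anet, gs = g0, limitation = a$limitation,
                Rl = a$Rl))
  }
  root <- stats::uniroot(function(ci)
    fvcb_assimilation(ci, Tleaf, APAR, params, kin)$Anet,
    c(1e-3, Ca), tol = 1e-4)$root
  list(Ci = root, Anet = 0, gs = g0, limitation = a$limitation, Rl = a$Rl)
}

# Solve the A-Ci supply/demand intersection at fixed leaf temperature and D.
# With g0 = 0 the Medlyn model fixes Ci/Ca in closed form; otherwise a root
# of supply - demand is bracketed on (GammaStar, Ca).
solve_ci <- function(Tleaf, D, APAR, Ca, params, kin, stomatal) {
  D <- max(D, 0.05)
  if (stomatal$g0 == 0) {
    g1s <- stomatal$g1 / sqrt(D)
    Ci <- Ca * g1s / (1 + g1s)
    a <- fvcb_assimilation(Ci, Tleaf, APAR, params, kin)
    if (a$Anet <= 0) {
      return(closed_stomata_state(Tleaf, APAR, Ca, params, kin, stomatal$g0))
    }
    gs <- medlyn_gs(a$Anet, Ca, D, stomatal)
    return(list(Ci = Ci, Anet = a$Anet, gs = gs, limitation = a$limitation,
                Rl = a$Rl))
  }
  gstar <- arrhenius(Tleaf + 273.15, kin$GammaStar25, kin$Ea_GammaStar)
  fmis <- function(Ci) {
    a <- fvcb_assimilation(Ci, Tleaf, APAR, params, kin)
    gs <- medlyn_gs(a$Anet, Ca, D, stomatal)
    (gs / 1.6) * (Ca - Ci) - a$Anet
  }
  lo <- min(gstar + 1e-6, Ca * 0.5)
  if (fmis(Ca) >= 0) {
    # net efflux: with g0 > 0 respiration escapes and Ci settles above Ca
    root <- stats::uniroot(fmis, c(Ca, 3 * Ca), tol = 1e-4, extendInt = "downX")$root
    a <- fvcb_assimilation(root, Tleaf, APAR, params, kin)
    return(list(Ci = root, Anet = a$Anet,
                gs = medlyn_gs(a$Anet, Ca, D, stomatal),
                limitation = a$limitation, Rl = a$Rl))
  }
  root <- stats::uniroot(fmis, c(lo, Ca), tol = 1e-4)$root
  a <- fvcb_assimilation(root, Tleaf, APAR, params, kin)
  list(Ci = root, Anet = a$Anet, gs = medlyn_gs(a$Anet, Ca, D, stomatal),
       limitation = a$limitation, Rl = a$Rl)
}

#' Coupled leaf photosynthesis, conductance and energy balance
#'
#' Solves the fixed point of (i) FvCB demand A(Ci), (ii) diffusion supply
#' \eqn{A = (g_s/1.6)(C_a - C_i)} with Medlyn stomatal conductance, and
#' (iii) an isothermal-net-radiation leaf energy balance giving leaf
#' temperature from absorbed radiation, sensible and latent heat with a
#' fixed boundary-layer conductance. The leaf-to-air vapour pressure deficit
#' driving the stomata is recomputed at leaf temperature each iteration, and
#' leaf temperature updates are damped by 0.5.
#'
#' @param env An [env_conditions()] object.
#' @param params A [photo_params()] object; for canopy calls the capacities
#'   may already be canopy-integrated.
#' @param kin A [kinetic_constants()] object.
#' @param stomatal A [stomatal_params()] object.
#' @param APAR Absorbed PAR driving biochemistry (umol m-2 s-1). If `NULL`,
#'   computed as incident PAR x PAR-band leaf absorptance.
#' @param APAR_energy Absorbed PAR used as the radiation load of the energy
#'   balance, per unit leaf area (defaults to `APAR`). Canopy schemes that
#'   pass ground-area-integrated `APAR` should supply the per-leaf-area mean
#'   here.
#' @param absorptance PAR-band leaf absorptance used when `APAR` is `NULL`.
#' @param area_scale Leaf area represented by this "leaf" (m2 leaf per m2 of
#'   the flux basis); scales boundary-layer and radiative conductances so
#'   canopy-integrated calls remain energetically consistent.
#' @param gb Boundary-layer conductance to heat, one-sided (mol m-2 s-1).
#'   Default computed from leaf width `d` and wind speed; `Inf` gives the
#'   perfectly coupled limit (Tleaf = Tair when the radiation load is
#'   balanced).
#' @param d Characteristic leaf width (m).
#' @param nir_frac Additional shortwave load absorbed outside the PAR band,
#'   as a fraction of absorbed PAR energy.
#' @param tol_T,tol_Ci Convergence tolerances on leaf temperature (degC) and
#'   Ci (umol mol-1).
#' @param max_iter Maximum iterations before failure.
#' @return An object of class `leaf_state`: list with `Tleaf`, `Anet`, `gs`,
#'   `Ci`, `E` (transpiration, mmol m-2 s-1), `D` (leaf-to-air VPD, kPa),
#'   `limitation`, `Rl`, and `iterations`.
#' @export
solve_coupled_leaf <- function(env, params = photo_params(),
                               kin = kinetic_constants(),
                               stomatal = stomatal_params(),
                               APAR = NULL, APAR_energy = NULL,
                               absorptance = 0.825, area_scale = 1,
                               gb = NULL, d = 0.02, nir_frac = 0.2,
                               tol_T = 0.01, tol_Ci = 0.01, max_iter = 100) {
  if (is.null(APAR)) APAR <- env$PAR * absorptance
  if (is.null(APAR_energy)) APAR_energy <- APAR / area_scale
  if (is.null(gb)) gb <- 0.135 * sqrt(env$wind / d)

  Ta <- env$Tair
  ea <- max(esat(Ta) - env$VPD, 0)     # air vapour pressure, kPa
  gr1 <- 4 * 0.97 * .SIGMA * (Ta + 273.15)^3 / .CP_MOL  # radiative, per side
  Rabs <- APAR_energy * .PAR_J_PER_UMOL * (1 + nir_frac) # W m-2 leaf

  Tleaf <- Ta
  Ci_prev <- Inf
  sol <- NULL
  for (it in seq_len(max_iter)) {
    D <- max(esat(Tleaf) - ea, 0.05)
    sol <- solve_ci(Tleaf, D, APAR, env$Ca, params, kin, stomatal)
    # energy balance (per unit leaf area)
    gbw <- 1.075 * gb
    gs_leaf <- sol$gs / area_scale
    gw <- if (is.infinite(gbw)) gs_leaf else 1 / (1 / max(gs_leaf, 1e-9) + 1 / gbw)
    E <- gw * D / env$pressure                 # mol m-2 s-1
    gH <- 2 * gb + 2 * gr1                     # heat + radiative, both sides
    dT <- if (is.infinite(gH)) 0 else (Rabs - .LAMBDA * E) / (.CP_MOL * gH)
    Tnew <- Ta + dT
    conv <- abs(Tnew - Tleaf) < tol_T && abs(sol$Ci - Ci_prev) < tol_Ci
    Ci_prev <- sol$Ci
    Tleaf <- Tleaf + 0.5 * (Tnew - Tleaf)
    if (conv) {
      return(structure(list(Tleaf = Tleaf, Anet = sol$Anet, gs = sol$gs,
                            Ci = sol$Ci, E = E * 1000 * area_scale, D = D,
                            limitation = sol$limitation, Rl = sol$Rl,
                            iterations = it),
                       class = "leaf_state"))
    }
  }
  stop(sprintf(paste0("leaf energy balance failed to converge after %d ",
                      "iterations (last Tleaf = %.3f degC, Ci = %.2f)"),
               max_iter, Tleaf, Ci_prev))
}

#' @export
print.leaf_state <- function(x, ...) {
  cat(sprintf(
    "Leaf state: Tleaf %.2f degC  Anet %.2f  gs %.3f  Ci %.1f  (%s-limited)\n",
    x$Tleaf, x$Anet, x$gs, x$Ci, x$limitation))
  invisible(x)
}
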