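# Vectorized coupled-leaf solver for the multilayer scheme: solves many
# independent leaves (one per sub-volume light class) sharing the same air
# state in a single damped fixed-point iteration. Requires g0 = 0 (the
# default); callers fall back to solve_coupled_leaf() otherwise. Results
# match the scalar solver to the shared tolerances.

solve_leaf_vec <- function(env, APAR, Vcmax25, Jmax25,
                           params = photo_params(),
                           kin = kinetic_constants(),
                           stomatal = stomatal_params(),
                           gb = NULL, d = 0.02, nir_frac = 0.2,
                           tol_T = 0.01, max_iter = 100) {
  stopifnot(stomatal$g0 == 0)
  n <- length(APAR)
  stopifnot(length(Vcmax25) == n, length(Jmax25) == n)
  if (is.null(gb)) gb <- 0.135 * sqrt(env$wind / d)

  Ta <- env$Tair
  Ca <- env$Ca
  ea <- max(esat(Ta) - env$VPD, 0)
  gr1 <- 4 * 0.97 * .SIGMA * (Ta + 273.15)^3 / .CP_MOL
  gH <- 2 * gb + 2 * gr1
  Rabs <- APAR * .PAR_J_PER_UMOL * (1 + nir_frac)
  gbw <- 1.075 * gb

  anet_at <- function(Ci, Tk, Vcmax, Jmax, GammaStar, Km, Rl) {
    J <- electron_transport(APAR, Jmax, params$alpha_J, params$theta_J)
    co2 <- pmax(Ci - GammaStar, 0)
    pmin(Vcmax * co2 / (Ci + Km), (J / 4) * co2 / (Ci + 2 * GammaStar)) - Rl
  }

  Tleaf <- rep(Ta, n)
  for (it in seq_len(max_iter)) {
    Tk <- Tleaf + 273.15
    Vcmax <- peaked_arrhenius(Tk, Vcmax25, params$Ea_V, params$dS_V, params$Hd)
    Jmax <- peaked_arrhenius(Tk, Jmax25, params$Ea_J, params$dS_J, params$Hd)
    GammaStar <- arrhenius(Tk, kin$GammaStar25, kin$Ea_GammaStar)
    Kc <- arrhenius(Tk, kin$Kc25, kin$Ea_Kc)
    Km <- Kc * (1 + kin$Oi / arrhenius(Tk, kin$Ko25, kin$Ea_Ko))
    Rl <- day_respiration(Tleaf, params$Rl25, params$Q10)

    D <- pmax(esat(Tleaf) - ea, 0.05)
    g1s <- stomatal$g1 / sqrt(D)
    Ci <- Ca * g1s / (1 + g1s)
    A <- anet_at(Ci, Tk, Vcmax, Jmax, GammaStar, Km, Rl)
    open <- A > 0
    if (any(!open)) {
      # closed stomata: flux pinned at 0 while gross assimilation at Ca
      # would still be positive (hot limit), else true dark efflux -Rl
      Aca <- anet_at(rep(Ca, n), Tk, Vcmax, Jmax, GammaStar, Km, Rl)
      A[!open] <- pmin(Aca[!open], 0)
      Ci[!open] <- Ca
    }
    gs <- ifelse(open, 1.6 * (1 + g1s) * A / Ca, 0)
    gw <- ifelse(gs > 0, 1 / (1 / pmax(gs, 1e-9) + 1 / gbw), 0)
    E <- gw * D / env$pressure
    Tnew <- Ta + (Rabs - .LAMBDA * E) / (.CP_MOL * gH)
    if (max(abs(Tnew - Tleaf)) < tol_T) {
      return(list(Anet = A, Tleaf = Tleaf, gs = gs, Ci = Ci,
                  E = E * 1000, iterations = it))
    }
    Tleaf <- Tleaf + 0.5 * (Tnew - Tleaf)
  }
  stop(sprintf("vectorized leaf solver failed to converge after %d iterations",
               max_iter))
}
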