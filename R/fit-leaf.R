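# Leaf-physiology estimation from gas-exchange data: A/Ci curve fitting for
# Vcmax/Jmax and the Medlyn stomatal slope g1.

#' Fit an A/Ci curve
#'
#' Two-branch FvCB least squares: net assimilation is modelled as
#' min(Ac, Aj) - Rl with the package's kinetic constants evaluated at the
#' measurement leaf temperature, and Vcmax and Jmax (at that temperature)
#' are estimated jointly. Branch assignment uses the minimum rule; a
#' `transition_Ci` override can force the Rubisco branch below a chosen Ci.
#' Curves with no RuBP-limited region (all points Rubisco-limited at the
#' optimum) return Jmax as not estimable.
#'
#' @param A Net assimilation (umol m-2 s-1).
#' @param Ci Intercellular CO2 (umol mol-1).
#' @param Tleaf Leaf temperature of the curve (degC, single value).
#' @param APAR Absorbed PAR during the curve (umol m-2 s-1).
#' @param params A [photo_params()] used for `alpha_J`, `theta_J`, `Rl25`,
#'   `Q10` (capacities are estimated, not taken from here).
#' @param kin A [kinetic_constants()] object.
#' @param transition_Ci Optional Ci (umol mol-1) below which points are
#'   forced to the Rubisco branch.
#' @return Object of class `aci_fit` with `Vcmax`, `Jmax` (at `Tleaf`),
#'   standard errors, `jmax_estimable` flag, and the residual standard
#'   error.
#' @export
fit_aci <- function(A, Ci, Tleaf, APAR = 1500, params = photo_params(),
                    kin = kinetic_constants(), transition_Ci = NULL) {
  ok <- is.finite(A) & is.finite(Ci)
  A <- A[ok]; Ci <- Ci[ok]
  if (length(A) < 6) stop("need at least 6 points on the A/Ci curve")
  Tk <- Tleaf + 273.15
  GammaStar <- arrhenius(Tk, kin$GammaStar25, kin$Ea_GammaStar)
  Kc <- arrhenius(Tk, kin$Kc25, kin$Ea_Kc)
  Ko <- arrhenius(Tk, kin$Ko25, kin$Ea_Ko)
  Km <- Kc * (1 + kin$Oi / Ko)
  Rl <- day_respiration(Tleaf, params$Rl25, params$Q10)

  model_A <- function(Vcmax, Jmax) {
    J <- electron_transport(APAR, Jmax, params$alpha_J, params$theta_J)
    co2 <- pmax(Ci - GammaStar, 0)
    Ac <- Vcmax * co2 / (Ci + Km)
    Aj <- (J / 4) * co2 / (Ci + 2 * GammaStar)
    gross <- if (is.null(transition_Ci)) {
      pmin(Ac, Aj)
    } else {
      ifelse(Ci < transition_Ci, Ac, pmin(Ac, Aj))
    }
    gross - Rl
  }
  # one-point starting guesses from low- and high-Ci ends
  i_lo <- which.min(Ci); i_hi <- which.max(Ci)
  v0 <- max((A[i_lo] + Rl) * (Ci[i_lo] + Km) / max(Ci[i_lo] - GammaStar, 1), 10)
  j0 <- max(4 * (A[i_hi] + Rl) * (Ci[i_hi] + 2 * GammaStar) /
              max(Ci[i_hi] - GammaStar, 1), 10)
  fit <- try(minpack.lm::nlsLM(
    A ~ model_A(Vcmax, Jmax),
    start = list(Vcmax = v0, Jmax = min(j0 * 1.5, 1000)),
    lower = c(Vcmax = 1, Jmax = 1),
    control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    # Jmax unidentifiable (no RuBP-limited points): Rubisco-only fit
    jfix <- 20 * v0
    fit <- minpack.lm::nlsLM(A ~ model_A(Vcmax, jfix),
                             start = list(Vcmax = v0), lower = c(Vcmax = 1),
                             control = minpack.lm::nls.lm.control(maxiter = 300))
    est <- c(stats::coef(fit), Jmax = NA_real_)
    se <- c(tryCatch(summary(fit)$coefficients[, "Std. Error"],
                     error = function(e) NA_real_), Jmax = NA_real_)
    return(structure(list(Vcmax = unname(est["Vcmax"]), Jmax = NA_real_,
                          se = se, jmax_estimable = FALSE,
                          sigma = summary(fit)$sigma, fit = fit,
                          Tleaf = Tleaf),
                     class = "aci_fit"))
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 2))
  # is any observed point actually on the RuBP branch at the estimate?
  J <- electron_transport(APAR, est["Jmax"], params$alpha_J, params$theta_J)
  co2 <- pmax(Ci - GammaStar, 0)
  on_aj <- (J / 4) * co2 / (Ci + 2 * GammaStar) <
    est["Vcmax"] * co2 / (Ci + Km)
  jmax_estimable <- any(on_aj & Ci > GammaStar)
  structure(list(Vcmax = unname(est["Vcmax"]), Jmax = unname(est["Jmax"]),
                 se = se, jmax_estimable = jmax_estimable,
                 sigma = summary(fit)$sigma, fit = fit, Tleaf = Tleaf),
            class = "aci_fit")
}

#' @export
print.aci_fit <- function(x, ...) {
  cat(sprintf("A/Ci fit at %.1f degC: Vcmax = %.1f (SE %.2f)", x$Tleaf,
              x$Vcmax, x$se["Vcmax"]))
  if (x$jmax_estimable) {
    cat(sprintf(", Jmax = %.1f (SE %.2f)\n", x$Jmax, x$se["Jmax"]))
  } else {
    cat(", Jmax not estimable (no RuBP-limited region)\n")
  }
  invisible(x)
}

#' Fit the Medlyn stomatal slope g1
#'
#' Least-squares fit of \eqn{g_s = 1.6 (1 + g_1/\sqrt{D}) A / C_a} with
#' zero minimum conductance. Because the model is linear in g1 given the
#' data, the estimate has a closed form; standard errors come from the
#' linear model.
#'
#' @param gs Stomatal conductance to water vapour (mol m-2 s-1).
#' @param A Net assimilation (umol m-2 s-1).
#' @param Ca Ambient CO2 (umol mol-1), scalar or vector.
#' @param D Vapour pressure deficit (kPa), must be positive.
#' @return Object of class `g1_fit` with `g1`, its standard error, and
#'   flags: `nonpositive` (fitted slope not positive) and
#'   `low_information` (single D level, slope poorly identified).
#' @export
fit_g1 <- function(gs, A, Ca, D) {
  stopifnot(all(D > 0))
  ok <- is.finite(gs) & is.finite(A) & is.finite(D)
  gs <- gs[ok]; A <- A[ok]; D <- D[ok]
  Ca <- if (length(Ca) == 1) rep(Ca, length(gs)) else Ca[ok]
  y <- gs - 1.6 * A / Ca
  x <- 1.6 * A / (Ca * sqrt(D))
  lmfit <- stats::lm(y ~ x - 1)
  g1 <- unname(stats::coef(lmfit)[1])
  se <- tryCatch(summary(lmfit)$coefficients[1, 2],
                 error = function(e) NA_real_)
  structure(list(g1 = g1, se = se,
                 nonpositive = g1 <= 0,
                 low_information = length(unique(round(D, 6))) < 2,
                 fit = lmfit),
            class = "g1_fit")
}

#' @export
print.g1_fit <- function(x, ...) {
  cat(sprintf("Medlyn g1 fit: g1 = %.3f (SE %.3f) kPa^0.5%s%s\n",
              x$g1, x$se,
              if (x$nonpositive) "  [non-positive]" else "",
              if (x$low_information) "  [single-D data]" else ""))
  invisible(x)
}
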