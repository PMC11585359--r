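# Temperature-response fitting: quadratic optimum curves for net
# photosynthesis and peaked Arrhenius functions for Vcmax/Jmax.

#' Fit the quadratic temperature response of photosynthesis
#'
#' Nonlinear least squares of \eqn{A = A_{opt} - b (T - T_{optA})^2}
#' directly in the (Aopt, Topt, b) parameterization, so standard errors of
#' the optimum temperature come straight from the Jacobian.
#'
#' @param T Temperature (degC).
#' @param A Net photosynthesis (umol m-2 s-1).
#' @return Object of class `topt_fit`: coefficients (`Aopt`, `Topt`, `b`),
#'   standard errors, `boundary` flag (TRUE when no interior optimum is
#'   supported: non-positive curvature or fitted optimum outside the data
#'   range), and the underlying `nls` fit.
#' @export
fit_quadratic_topt <- function(T, A) {
  ok <- is.finite(T) & is.finite(A)
  T <- T[ok]; A <- A[ok]
  if (length(T) < 5) stop("need at least 5 points")
  if (diff(range(T)) < 8) {
    warning("temperature span below 8 degC; optimum poorly constrained")
  }
  # starting values from the linear-in-coefficients parabola
  lmfit <- stats::lm(A ~ T + I(T^2))
  cf <- stats::coef(lmfit)
  b0 <- -cf[3]
  t0 <- if (abs(cf[3]) > 1e-12) -cf[2] / (2 * cf[3]) else mean(T)
  start <- list(Aopt = max(A), Topt = min(max(t0, min(T)), max(T)),
                b = max(b0, 1e-3))
  fit <- try(minpack.lm::nlsLM(A ~ Aopt - b * (T - Topt)^2, start = start,
                               control = minpack.lm::nls.lm.control(maxiter = 200)),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    stop("quadratic temperature-response fit did not converge")
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  boundary <- est["b"] <= 0 || est["Topt"] < min(T) || est["Topt"] > max(T)
  structure(list(coefficients = est, se = se, boundary = boundary,
                 fit = fit, data = data.frame(T = T, A = A)),
            class = "topt_fit")
}

#' @export
coef.topt_fit <- function(object, ...) object$coefficients

#' @export
print.topt_fit <- function(x, ...) {
  cat("Quadratic temperature-response fit\n")
  cat(sprintf("  Aopt = %.2f (SE %.2f) umol m-2 s-1\n",
              x$coefficients["Aopt"], x$se["Aopt"]))
  cat(sprintf("  Topt = %.2f (SE %.2f) degC%s\n",
              x$coefficients["Topt"], x$se["Topt"],
              if (x$boundary) "  [no interior optimum]" else ""))
  cat(sprintf("  b    = %.4f (SE %.4f)\n", x$coefficients["b"], x$se["b"]))
  invisible(x)
}

#' @export
predict.topt_fit <- function(object, newdata = NULL, ...) {
  T <- if (is.null(newdata)) object$data$T else newdata$T
  cf <- object$coefficients
  unname(quadratic_response(T, cf["Aopt"], cf["Topt"], cf["b"]))
}

#' Fit the peaked Arrhenius temperature response
#'
#' Nonlinear least squares of [peaked_arrhenius()] to rates measured across
#' leaf temperatures, estimating `k25`, `Ea` and `dS` with the deactivation
#' energy fixed (default 200,000 J mol-1) to avoid over-parameterization.
#'
#' @param T Leaf temperature (degC).
#' @param rates Process rates, e.g. Vcmax (umol m-2 s-1).
#' @param Hd_fixed Fixed deactivation energy (J mol-1).
#' @param start Optional named list of starting values.
#' @return Object of class `arrhenius_fit` with coefficients (`k25`, `Ea`,
#'   `dS`), standard errors, the implied optimum temperature `Topt_C`, a
#'   `no_peak` flag (entropy estimate at a bound, i.e. no decline within
#'   the data), and the `nls` fit.
#' @export
fit_peaked_arrhenius <- function(T, rates, Hd_fixed = 200000, start = NULL) {
  ok <- is.finite(T) & is.finite(rates)
  T <- T[ok]; rates <- rates[ok]
  if (length(unique(round(T, 4))) < 5) {
    stop("need rates at 5 or more temperatures")
  }
  Tk <- T + 273.15
  if (is.null(start)) {
    k25_0 <- stats::approx(T, rates, xout = 25, rule = 2)$y
    start <- list(k25 = max(k25_0, 1), Ea = 50000, dS = 635)
  }
  lower <- c(k25 = 1e-3, Ea = 1000, dS = 550)
  upper <- c(k25 = Inf, Ea = 1.9e5, dS = 700)
  fit <- try(minpack.lm::nlsLM(
    rates ~ peaked_arrhenius(Tk, k25, Ea, dS, Hd_fixed),
    start = start, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    stop("peaked Arrhenius fit did not converge (last start: ",
         paste(sprintf("%s=%.3g", names(start), unlist(start)),
               collapse = ", "), ")")
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  no_peak <- est["dS"] <= lower["dS"] + 1e-6 || est["dS"] >= upper["dS"] - 1e-6
  topt <- peaked_arrhenius_topt(est["Ea"], est["dS"], Hd_fixed) - 273.15
  structure(list(coefficients = est, se = se, Hd = Hd_fixed,
                 Topt_C = unname(topt), no_peak = no_peak, fit = fit),
            class = "arrhenius_fit")
}

#' @export
coef.arrhenius_fit <- function(object, ...) object$coefficients

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat("Peaked Arrhenius fit (Hd fixed at", x$Hd, "J mol-1)\n")
  cat(sprintf("  k25 = %.1f (SE %.2f)\n", x$coefficients["k25"], x$se["k25"]))
  cat(sprintf("  Ea  = %.0f (SE %.0f) J mol-1\n",
              x$coefficients["Ea"], x$se["Ea"]))
  cat(sprintf("  dS  = %.1f (SE %.2f) J mol-1 K-1%s\n",
              x$coefficients["dS"], x$se["dS"],
              if (x$no_peak) "  [no peak within data]" else ""))
  cat(sprintf("  implied Topt = %.1f degC\n", x$Topt_C))
  invisible(x)
}

#' @export
predict.arrhenius_fit <- function(object, newdata = NULL, ...) {
  Tk <- if (is.null(newdata)) {
    stats::fitted(object$fit)
  } else {
    cf <- object$coefficients
    return(peaked_arrhenius(newdata$T + 273.15, cf["k25"], cf["Ea"],
                            cf["dS"], object$Hd))
  }
  Tk
}
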