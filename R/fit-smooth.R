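# Data-driven (penalized-spline) characterization of the canopy
# temperature response and extraction of its optimum.

#' Smooth temperature response with optimum extraction
#'
#' Fits a penalized cubic regression spline (generalized additive model,
#' smoothness chosen by generalized cross-validation) of flux against
#' temperature, evaluates the fitted smooth on a 0.1 degC grid, and locates
#' the optimum temperature as the argmax, with a pointwise 95% confidence
#' band from the smoother's covariance. An optimum on the edge of the data
#' range is flagged as a boundary optimum (a monotone response has no
#' interior optimum).
#'
#' @param T Temperature (degC).
#' @param A Flux (umol m-2 s-1).
#' @param k Spline basis dimension (default 8).
#' @return Object of class `smooth_response`: `Topt` (degC), `boundary`
#'   flag, prediction grid data.frame (`T`, `fit`, `lower`, `upper`), and
#'   the `gam` fit.
#' @export
fit_smooth_response <- function(T, A, k = 8) {
  ok <- is.finite(T) & is.finite(A)
  T <- T[ok]; A <- A[ok]
  if (length(T) < 30) stop("need at least 30 points for the smooth fit")
  dat <- data.frame(T = T, A = A)
  fit <- mgcv::gam(A ~ s(T, k = k, bs = "cr"), data = dat, method = "GCV.Cp")
  grid <- data.frame(T = seq(min(T), max(T), by = 0.1))
  pr <- mgcv::predict.gam(fit, newdata = grid, se.fit = TRUE)
  grid$fit <- as.numeric(pr$fit)
  grid$lower <- grid$fit - 1.96 * as.numeric(pr$se.fit)
  grid$upper <- grid$fit + 1.96 * as.numeric(pr$se.fit)
  i <- which.max(grid$fit)
  boundary <- i == 1L || i == nrow(grid)
  structure(list(Topt = grid$T[i], boundary = boundary, grid = grid,
                 fit = fit),
            class = "smooth_response")
}

#' @export
print.smooth_response <- function(x, ...) {
  cat(sprintf("Smooth temperature response: Topt = %.1f degC%s\n", x$Topt,
              if (x$boundary) " (boundary of data range)" else ""))
  invisible(x)
}

#' Are two smooth temperature responses different?
#'
#' Two responses are deemed different where their pointwise 95% confidence
#' bands are disjoint on the shared temperature range.
#'
#' @param a,b `smooth_response` objects.
#' @return List with `different` (TRUE if the bands separate anywhere) and
#'   `fraction_separated` (share of the shared grid where they do).
#' @export
smooth_responses_differ <- function(a, b) {
  lo <- max(min(a$grid$T), min(b$grid$T))
  hi <- min(max(a$grid$T), max(b$grid$T))
  if (lo >= hi) stop("no overlapping temperature range")
  g <- seq(lo, hi, by = 0.1)
  ga <- a$grid[match(round(g, 1), round(a$grid$T, 1)), ]
  gb <- b$grid[match(round(g, 1), round(b$grid$T, 1)), ]
  sep <- ga$lower > gb$upper | gb$lower > ga$upper
  sep <- sep[!is.na(sep)]
  list(different = any(sep), fraction_separated = mean(sep))
}
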