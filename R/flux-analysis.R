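# Flux-series processing and model-observation evaluation.

#' Average a 15-min flux series to hourly
#'
#' Arithmetic mean of flux, PAR, temperature and VPD per clock hour and
#' chamber. Hours with fewer than `min_subintervals` contributing records
#' are dropped; hours with some (but not all) sub-intervals missing are
#' kept and flagged.
#'
#' @param series A flux-series data.frame (columns `timestamp`,
#'   `chamber_id`, `anet_umol_m2leaf_s`, `par_umol_m2_s`, `tair_c`,
#'   `vpd_kpa`; extra columns are carried through from the first row of
#'   each hour).
#' @param min_subintervals Minimum records per hour (default 2).
#' @param expected Expected records per full hour (default 4, a 15-min
#'   cadence).
#' @return Hourly flux series with `n_subintervals` and logical `partial`.
#' @export
hourly_average <- function(series, min_subintervals = 2, expected = 4) {
  if (nrow(series) == 0) stop("empty flux series")
  tz <- attr(series$timestamp, "tzone") %||% "UTC"
  hour <- as.POSIXct(trunc(series$timestamp, "hours"), tz = tz)
  key <- paste(series$chamber_id, format(hour, "%Y-%m-%d %H"))
  num_cols <- c("anet_umol_m2leaf_s", "par_umol_m2_s", "tair_c", "vpd_kpa")
  parts <- split(seq_len(nrow(series)), key)
  rows <- lapply(parts, function(idx) {
    n <- sum(is.finite(series$anet_umol_m2leaf_s[idx]))
    if (n < min_subintervals) return(NULL)
    out <- series[idx[1], , drop = FALSE]
    out$timestamp <- hour[idx[1]]
    for (cl in num_cols) out[[cl]] <- mean(series[[cl]][idx], na.rm = TRUE)
    out$n_subintervals <- n
    out$partial <- n < expected
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- series[0, , drop = FALSE]
    out$n_subintervals <- integer(0)
    out$partial <- logical(0)
    class(out) <- c("flux_series", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chamber_id, out$timestamp), ]
  rownames(out) <- NULL
  class(out) <- c("flux_series", "data.frame")
  out
}

#' High-light subset of a flux series
#'
#' Retains rows with incident PAR strictly above the threshold (default
#' 1200 umol m-2 s-1, the conventional saturating-light cutoff that
#' isolates the temperature response from light limitation).
#'
#' @param series A flux-series data.frame with `par_umol_m2_s`.
#' @param threshold PAR threshold (umol m-2 s-1); strict inequality.
#' @return The filtered series.
#' @export
highlight_subset <- function(series, threshold = 1200) {
  out <- series[series$par_umol_m2_s > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Regress modelled on observed canopy photosynthesis
#'
#' Ordinary least squares of modelled flux on observed flux (observed on
#' the x axis), after aligning the two series on timestamp and chamber.
#' RMSE is the root mean squared paired difference modelled - observed.
#'
#' @param modelled,observed Flux-series data.frames.
#' @return Object of class `model_obs_regression`: `intercept`, `slope`,
#'   `r2`, `rmse`, `n`, and the `lm` fit.
#' @export
regress_model_obs <- function(modelled, observed) {
  key_m <- paste(modelled$chamber_id, format(modelled$timestamp, "%Y-%m-%d %H:%M"))
  key_o <- paste(observed$chamber_id, format(observed$timestamp, "%Y-%m-%d %H:%M"))
  i <- match(key_o, key_m)
  ok <- !is.na(i) & is.finite(observed$anet_umol_m2leaf_s) &
    is.finite(modelled$anet_umol_m2leaf_s[i])
  x <- observed$anet_umol_m2leaf_s[ok]
  y <- modelled$anet_umol_m2leaf_s[i[ok]]
  if (length(x) < 10) stop("fewer than 10 paired points")
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  structure(list(intercept = unname(cf[1]), slope = unname(cf[2]),
                 r2 = summary(fit)$r.squared,
                 rmse = sqrt(mean((y - x)^2)),
                 n = length(x), fit = fit),
            class = "model_obs_regression")
}

#' @export
print.model_obs_regression <- function(x, ...) {
  cat(sprintf(
    "Modelled ~ observed: intercept %.2f, slope %.3f, r2 %.3f, RMSE %.2f (n = %d)\n",
    x$intercept, x$slope, x$r2, x$rmse, x$n))
  invisible(x)
}
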