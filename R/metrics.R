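#' Pearson correlation with a zero-variance guard
#'
#' Standard Pearson correlation over flattened arrays; returns 0 with a
#' warning when either input has zero variance (the convention used by
#' the memory-correlation readouts).
#'
#' @param a,b numeric arrays of equal length (>= 2).
#' @export
pearson <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 2) stop("need at least two values")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance; returning 0")
    return(0)
  }
  stats::cor(a, b)
}

#' Compare power-law and exponential decay fits
#'
#' Fits, by ordinary least squares above the noise floor,
#' a power law `log(y - floor) ~ log(t)` and an exponential
#' `log(y - floor) ~ t`, over the days where the signal exceeds
#' `signal_mult` times the noise floor.  The model with the smaller RMSE
#' in its own linearizing coordinates is selected.
#'
#' @param series positive decay series (e.g. max memory correlation).
#' @param days time points (same length).
#' @param noise_floor additive noise floor subtracted before fitting.
#' @param signal_mult keep days with `series > signal_mult * noise_floor`
#'   (default 3).
#' @param min_points minimum number of usable points (default 10).
#' @return list with `powerlaw` (exponent, intercept, rmse on log-log
#'   axes), `exponential` (rate, intercept, rmse on semi-log axes),
#'   `selected`, and the days used.
#' @export
compare_decay_models <- function(series, days, noise_floor = 0,
                                 signal_mult = 3, min_points = 10) {
  stopifnot(length(series) == length(days))
  keep <- is.finite(series) & series > signal_mult * noise_floor & days > 0
  if (sum(keep) < min_points)
    stop("too few points above the noise floor (",
         sum(keep), " < ", min_points, ")")
  y <- log(series[keep] - noise_floor)
  t <- days[keep]
  pl <- stats::lm(y ~ log(t))
  ex <- stats::lm(y ~ t)
  rmse <- function(m) sqrt(mean(stats::residuals(m)^2))
  list(
    powerlaw = list(exponent = unname(stats::coef(pl)[2]),
                    intercept = unname(stats::coef(pl)[1]),
                    rmse = rmse(pl)),
    exponential = list(rate = unname(stats::coef(ex)[2]),
                       intercept = unname(stats::coef(ex)[1]),
                       rmse = rmse(ex)),
    selected = if (rmse(pl) <= rmse(ex)) "powerlaw" else "exponential",
    days_used = t
  )
}
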