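#' Fit a power law y = prefactor * x^exponent
#'
#' Unweighted least squares of log(y) on log(x) over a band of x. This is the
#' common fitting step for the modulus magnitude (|G| = G0 omega^alpha), the
#' MSD (C tau^beta) and power spectra (A omega^-gamma, via
#' [fit_force_powerlaw()]). The prefactor is reported at x = 1 (omega in
#' rad/s, lag in s).
#'
#' @param x positive abscissae (e.g. omega in rad/s or lag in s).
#' @param y positive ordinates.
#' @param band optional c(min, max) of x to restrict the fit; default all.
#' @return object of class `powerlaw_fit`: list with `prefactor`, `exponent`,
#'   `band`, `r_squared`, `n`.
#' @examples
#' w <- 10^seq(-1, 2, 0.1)
#' coef(fit_powerlaw(w, 8.6 * w^0.4))
#' @export
fit_powerlaw <- function(x, y, band = NULL) {
  if (length(x) != length(y)) stop_invalid("x and y lengths differ")
  keep <- is.finite(x) & is.finite(y) & x > 0
  if (!is.null(band)) {
    if (length(band) != 2 || band[1] >= band[2])
      stop_invalid("band must be c(min, max) with min < max")
    keep <- keep & x >= band[1] & x <= band[2]
  }
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3)
    stop_invalid("need at least 3 points in the fit band (got %d)", length(x))
  if (any(y <= 0))
    stop_invalid("non-positive values in fit band: log-log fit undefined")
  fit <- stats::lm(log(y) ~ log(x))
  ss_tot <- sum((log(y) - mean(log(y)))^2)
  r2 <- if (ss_tot > 0)
    max(0, min(1, 1 - sum(stats::residuals(fit)^2) / ss_tot)) else 1
  structure(list(prefactor = exp(unname(stats::coef(fit)[1])),
                 exponent = unname(stats::coef(fit)[2]),
                 band = c(min(x), max(x)),
                 r_squared = r2,
                 n = length(x)),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law fit: y = %.4g * x^%.4g  (band [%.3g, %.3g], n = %d, R2 = %.4f)\n",
    x$prefactor, x$exponent, x$band[1], x$band[2], x$n, x$r_squared))
  invisible(x)
}

#' @export
coef.powerlaw_fit <- function(object, ...) {
  c(prefactor = object$prefactor, exponent = object$exponent)
}

#' @export
predict.powerlaw_fit <- function(object, x, ...) {
  object$prefactor * x^object$exponent
}
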