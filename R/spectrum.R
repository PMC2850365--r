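## Spectral estimation and the generalized-Langevin force inversion.
##
## Convention: spectra are one-sided densities over angular frequency
## (rad/s) normalized so that  variance = integral S(omega) domega / (2 pi)
## over (0, Inf). Numerically S(omega = 2 pi f) equals the familiar one-sided
## per-Hz density 2 dt |X_k|^2 / (N U). Two properties pin this choice:
## a Brownian track has S_xx = 4 D / omega^2, and the equilibrium force
## spectrum is S_FF = 4 kB T K G''(omega) / omega.

#' One-sided power spectrum (frequency-indexed density)
#'
#' Container for position (m^2 s) or force (N^2 s) spectra over angular
#' frequency.
#'
#' @param omega angular frequencies in rad/s, increasing, positive.
#' @param value one-sided spectral density values (>= 0).
#' @param units unit string, e.g. "m^2 s" or "N^2 s".
#' @param meta optional list of estimator metadata.
#' @return object of class `endo_spectrum` (a data.frame).
#' @export
endo_spectrum <- function(omega, value, units = "", meta = list()) {
  if (length(omega) != length(value)) stop_invalid("omega/value length mismatch")
  if (any(diff(omega) <= 0)) stop_invalid("omega must be increasing")
  if (any(value < 0)) stop_invalid("spectral values must be non-negative")
  out <- data.frame(omega = omega, value = value)
  attr(out, "units") <- units
  attr(out, "meta") <- meta
  class(out) <- c("endo_spectrum", "data.frame")
  out
}

#' @export
print.endo_spectrum <- function(x, ...) {
  cat(sprintf("Spectrum (%s): %d points, omega in [%.3g, %.3g] rad/s\n",
              attr(x, "units"), nrow(x), min(x$omega), max(x$omega)))
  invisible(x)
}

#' @export
plot.endo_spectrum <- function(x, ...) {
  graphics::plot(x$omega, x$value, log = "xy", type = "l",
                 xlab = "omega (rad/s)", ylab = attr(x, "units"), ...)
  invisible(x)
}

#' Band integral of a one-sided spectrum
#'
#' Trapezoidal integral of S(omega) domega / (2 pi); for a position spectrum
#' this is bounded above by the signal variance (Parseval).
#'
#' @param spectrum an `endo_spectrum`.
#' @param band optional c(min, max) omega band.
#' @return scalar integral in the squared units of the underlying signal.
#' @export
spectrum_integral <- function(spectrum, band = NULL) {
  stopifnot(inherits(spectrum, "endo_spectrum"))
  w <- spectrum$omega; s <- spectrum$value
  if (!is.null(band)) {
    keep <- w >= band[1] & w <= band[2]
    w <- w[keep]; s <- s[keep]
  }
  if (length(w) < 2) return(0)
  sum(diff(w) * (s[-1] + s[-length(s)]) / 2) / (2 * pi)
}

## Welch-averaged one-sided periodogram of a uniformly sampled series.
## Returns omega (rad/s, excluding DC) and density S with the convention
## above. detrend: per-segment mean or linear removal (position tracks are
## nonstationary; mean removal is the default used throughout).
welch_psd <- function(z, dt, n_segments = 8, overlap = 0.5,
                      window = c("hann", "rectangular"),
                      detrend = c("mean", "linear", "none")) {
  window <- match.arg(window)
  detrend <- match.arg(detrend)
  n <- length(z)
  if (n < 16) stop_invalid("series too short for spectral estimation")
  if (n_segments < 1) stop_invalid("n_segments must be >= 1")
  L <- floor(n / (1 + (n_segments - 1) * (1 - overlap)))
  L <- max(8L, L)
  step <- max(1L, floor(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- if (window == "hann") {
    0.5 * (1 - cos(2 * pi * seq_len(L) / (L + 1)))
  } else rep(1, L)
  U <- mean(w^2)
  nf <- floor(L / 2)
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- z[s0:(s0 + L - 1L)]
    seg <- switch(detrend,
                  mean = seg - mean(seg),
                  linear = stats::residuals(stats::lm.fit(
                    cbind(1, seq_len(L)), seg)),
                  none = seg)
    X <- stats::fft(w * seg)
    P <- 2 * dt * Mod(X[2:(nf + 1)])^2 / (L * U)
    if (L %% 2 == 0) P[nf] <- P[nf] / 2    # Nyquist bin is not doubled
    acc <- acc + P
  }
  S <- acc / length(starts)
  freqs <- (1:nf) / (L * dt)             # Hz
  list(omega = 2 * pi * freqs, S = S,
       meta = list(n_segments = length(starts), segment_length = L,
                   window = window, overlap = overlap, detrend = detrend))
}

#' Position power spectrum of a track
#'
#' Welch-averaged one-sided spectral density of the probe position along an
#' axis, in m^2 s over angular frequency. For a Brownian track the mid-band
#' density is 4 D / omega^2; this (together with Parseval) fixes the
#' normalization used by the force inversion.
#'
#' @param track an [endo_track()].
#' @param axis "parallel" (default: the chain/transport axis),
#'   "perpendicular", "x", "y", or "both" (sum of parallel and
#'   perpendicular densities).
#' @param n_segments,overlap,window,detrend Welch estimator settings;
#'   defaults 8 segments, 50 % overlap, Hann window, per-segment mean
#'   removal.
#' @param method "welch" (default): windowed periodogram of the positions —
#'   the better variance/level estimator; "differenced": periodogram of the
#'   position increments divided by the squared transfer function
#'   4 sin^2(omega dt / 2) of the difference filter. Increments of a
#'   power-law process are stationary with a nearly flat spectrum, so the
#'   differenced estimator is essentially leakage-free and is the choice for
#'   fitting steep spectral exponents.
#' @return an `endo_spectrum` (units m^2 s).
#' @export
position_spectrum <- function(track,
                              axis = c("parallel", "perpendicular",
                                       "x", "y", "both"),
                              n_segments = 8, overlap = 0.5,
                              window = "hann", detrend = "mean",
                              method = c("welch", "differenced")) {
  stopifnot(inherits(track, "endo_track"))
  axis <- match.arg(axis)
  method <- match.arg(method)
  if (axis == "both") {
    sp <- position_spectrum(track, "parallel", n_segments, overlap,
                            window, detrend, method)
    sq <- position_spectrum(track, "perpendicular", n_segments, overlap,
                            window, detrend, method)
    return(endo_spectrum(sp$omega, sp$value + sq$value, units = "m^2 s",
                         meta = attr(sp, "meta")))
  }
  z <- track_coordinate(track, axis)
  if (method == "differenced") {
    est <- welch_psd(diff(z), track$dt, n_segments = n_segments,
                     overlap = overlap, window = window, detrend = detrend)
    est$S <- est$S / (4 * sin(est$omega * track$dt / 2)^2)
  } else {
    est <- welch_psd(z, track$dt, n_segments = n_segments,
                     overlap = overlap, window = window, detrend = detrend)
  }
  endo_spectrum(est$omega, est$S, units = "m^2 s",
                meta = c(est$meta, list(axis = axis, method = method)))
}

#' Langevin context for force inversion
#'
#' Bundles what the generalized-Langevin inversion needs: the medium's
#' power-law modulus (fitted or known), the drag factor of the axis being
#' analysed, and the bath temperature.
#'
#' @param fit a [powerlaw_fit()] of |G| (prefactor Pa at omega = 1 rad/s,
#'   exponent alpha) or a [power_law_medium()].
#' @param drags a [drag_factors()] object.
#' @param temperature bath temperature (K).
#' @param axis which drag factor the spectra refer to: "parallel" (default)
#'   or "perpendicular".
#' @return object of class `langevin_context`.
#' @export
langevin_context <- function(fit, drags, temperature,
                             axis = c("parallel", "perpendicular")) {
  axis <- match.arg(axis)
  if (inherits(fit, "power_law_medium")) {
    medium <- fit
  } else if (inherits(fit, "powerlaw_fit")) {
    medium <- power_law_medium(fit$prefactor, min(1, max(0, fit$exponent)))
  } else stop_invalid("fit must be a powerlaw_fit or power_law_medium")
  stopifnot(inherits(drags, "drag_factors"))
  if (temperature <= 0) stop_invalid("temperature must be positive")
  K <- if (axis == "parallel") drags$K_parallel else drags$K_perpendicular
  structure(list(medium = medium, K = K, temperature = temperature,
                 axis = axis),
            class = "langevin_context")
}

#' Force power spectrum by generalized-Langevin inversion
#'
#' Inverts the overdamped generalized Langevin equation (memory friction set
#' by the medium through the generalized Stokes relation, inertia neglected
#' for micron-sized probes): S_FF(omega) = K^2 |G(omega)|^2 S_xx(omega),
#' valid in and out of equilibrium. |G| is evaluated from the fitted power
#' law, so the inversion extrapolates smoothly where the active and passive
#' frequency bands only partially overlap.
#'
#' @param track an [endo_track()], or an `endo_spectrum` of position (m^2 s)
#'   computed beforehand.
#' @param ctx a [langevin_context()].
#' @param ... passed to [position_spectrum()] when `track` is a track.
#' @return an `endo_spectrum` (units N^2 s).
#' @export
force_spectrum <- function(track, ctx, ...) {
  stopifnot(inherits(ctx, "langevin_context"))
  sxx <- if (inherits(track, "endo_spectrum")) track
         else position_spectrum(track, axis = ctx$axis, ...)
  Gmag <- Mod(modulus(ctx$medium, sxx$omega))
  endo_spectrum(sxx$omega, ctx$K^2 * Gmag^2 * sxx$value, units = "N^2 s",
                meta = attr(sxx, "meta"))
}

#' Thermal (equilibrium) force power spectrum
#'
#' At equilibrium the FDT combined with the Langevin inversion gives the
#' one-sided force spectrum S_FF^eq(omega) = 4 kB T K G''(omega) / omega.
#' For a Newtonian fluid (G'' = eta omega) this is the flat white-force level
#' 4 kB T K eta; for a power-law medium it decays as omega^(alpha - 1).
#'
#' @param ctx a [langevin_context()].
#' @param omega angular frequencies (rad/s).
#' @return an `endo_spectrum` (units N^2 s).
#' @export
thermal_force_spectrum <- function(ctx, omega) {
  stopifnot(inherits(ctx, "langevin_context"))
  if (any(omega <= 0)) stop_invalid("omega must be positive")
  Gpp <- Im(modulus(ctx$medium, omega))
  endo_spectrum(omega,
                4 * thermal_energy(ctx$temperature) * ctx$K * Gpp / omega,
                units = "N^2 s")
}

#' Fit S(omega) = A omega^-gamma to a force spectrum
#'
#' Log-log least squares over a frequency band; reports the decay exponent
#' gamma (positive for a decaying spectrum) and the prefactor A at
#' omega = 1 rad/s.
#'
#' @param spectrum an `endo_spectrum`.
#' @param band omega band (rad/s); default c(0.2, 20).
#' @param min_points minimum points required in band, default 5.
#' @return object of class `spectrum_fit` (a [fit_powerlaw()] fit): the raw
#'   log-log slope stays in `$exponent` (so `predict()` works unchanged) and
#'   the decay exponent is exposed as `$gamma = -exponent`, the amplitude as
#'   `$A = prefactor`.
#' @export
fit_force_powerlaw <- function(spectrum, band = c(0.2, 20), min_points = 5) {
  stopifnot(inherits(spectrum, "endo_spectrum"))
  keep <- spectrum$omega >= band[1] & spectrum$omega <= band[2]
  if (sum(keep) < min_points)
    stop_invalid("need >= %d spectrum points in band [%g, %g] rad/s (got %d)",
                 min_points, band[1], band[2], sum(keep))
  fit <- fit_powerlaw(spectrum$omega[keep], spectrum$value[keep])
  fit$gamma <- -fit$exponent
  fit$A <- fit$prefactor
  class(fit) <- c("spectrum_fit", class(fit))
  fit
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat(sprintf(
    "Spectrum fit: S = %.4g * omega^-%.4g  (band [%.3g, %.3g], n = %d, R2 = %.4f)\n",
    x$A, x$gamma, x$band[1], x$band[2], x$n, x$r_squared))
  invisible(x)
}

#' @export
coef.spectrum_fit <- function(object, ...) {
  c(A = object$A, gamma = object$gamma)
}
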