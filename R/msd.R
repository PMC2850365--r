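#' Time-averaged mean-square displacement of a track
#'
#' MSD(tau) = < [r(t + tau) - r(t)]^2 >_t using all overlapping pairs
#' (maximal time averaging). The displacement is resolved along the chosen
#' axis: "parallel"/"perpendicular" to the chain axis recorded with the
#' track, or "both" (sum of the two components, i.e. the full 2-D MSD).
#'
#' @param track an [endo_track()] with at least 10 samples.
#' @param axis "both" (default), "parallel" or "perpendicular".
#' @param max_lag_fraction largest lag as a fraction of the track duration,
#'   default 1/4.
#' @param n_lags if the number of available lags exceeds `n_lags`, evaluate
#'   the MSD on approximately `n_lags` log-spaced lags instead of every lag
#'   (power-law fitting loses nothing). Default 400.
#' @return data.frame of class `msd_curve` with columns `lag` (s), `value`
#'   (m^2), `n_pairs`; attribute `axis`.
#' @examples
#' tr <- simulate_newtonian_track(chain_probe(1, d_endo = 1e-6),
#'                                0.619, 10, 0.01, seed = 1)
#' msd <- compute_msd(tr)
#' @export
compute_msd <- function(track, axis = c("both", "parallel", "perpendicular"),
                        max_lag_fraction = 0.25, n_lags = 400) {
  stopifnot(inherits(track, "endo_track"))
  axis <- match.arg(axis)
  n <- length(track$times)
  if (n < 10) stop_invalid("compute_msd needs at least 10 samples")
  max_lag <- max(1L, floor((n - 1) * max_lag_fraction))
  lags <- seq_len(max_lag)
  if (length(lags) > n_lags) {
    lags <- unique(round(exp(seq(log(1), log(max_lag),
                                 length.out = n_lags))))
  }
  one_axis_msd <- function(z) {
    vapply(lags, function(l) mean((z[(1 + l):n] - z[1:(n - l)])^2),
           numeric(1))
  }
  vals <- switch(axis,
    both = one_axis_msd(track_coordinate(track, "parallel")) +
           one_axis_msd(track_coordinate(track, "perpendicular")),
    parallel = one_axis_msd(track_coordinate(track, "parallel")),
    perpendicular = one_axis_msd(track_coordinate(track, "perpendicular")))
  out <- data.frame(lag = lags * track$dt, value = vals, n_pairs = n - lags)
  attr(out, "axis") <- axis
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("MSD curve (%s axis): %d lags in [%.3g, %.3g] s\n",
              attr(x, "axis") %||% "?", nrow(x), min(x$lag), max(x$lag)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
plot.msd_curve <- function(x, ...) {
  graphics::plot(x$lag, x$value, log = "xy", xlab = "lag (s)",
                 ylab = expression(MSD ~ (m^2)), type = "l", ...)
  invisible(x)
}

#' Average several MSD curves on their common lags
#'
#' @param msds list of `msd_curve` objects with identical lag grids.
#' @return a single `msd_curve` (values averaged, pair counts summed).
#' @export
average_msd <- function(msds) {
  stopifnot(length(msds) >= 1, all(vapply(msds, inherits, TRUE, "msd_curve")))
  lag0 <- msds[[1]]$lag
  for (m in msds)
    if (length(m$lag) != length(lag0) || any(abs(m$lag - lag0) > 1e-12))
      stop_invalid("MSD curves have different lag grids")
  out <- data.frame(
    lag = lag0,
    value = Reduce(`+`, lapply(msds, `[[`, "value")) / length(msds),
    n_pairs = Reduce(`+`, lapply(msds, `[[`, "n_pairs")))
  attr(out, "axis") <- attr(msds[[1]], "axis")
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Fit the anomalous exponent of an MSD curve
#'
#' Log-log least squares of MSD versus lag over a band of lags; the exponent
#' beta distinguishes subdiffusive (beta < 1), diffusive (beta = 1) and
#' superdiffusive (beta > 1) motion.
#'
#' @param msd an `msd_curve`.
#' @param band lag band in seconds, default c(0.05, 5).
#' @return a [fit_powerlaw()] object (prefactor in m^2/s^beta, exponent beta).
#' @export
fit_msd_exponent <- function(msd, band = c(0.05, 5)) {
  stopifnot(inherits(msd, "msd_curve"))
  fit_powerlaw(msd$lag, msd$value, band = band)
}

#' Equilibrium MSD predicted by the fluctuation-dissipation theorem
#'
#' For a power-law medium G*(omega) = G0 (i omega)^alpha at equilibrium the
#' per-axis MSD of a probe with drag factor K is
#'   <dx^2(tau)> = 2 kB T / (K G0 Gamma(1 + alpha)) * tau^alpha.
#' In the viscous limit (alpha = 1, G0 = eta) this reduces to 2 D tau with
#' D = kB T / (K eta) (Stokes-Einstein), which pins the constant convention.
#'
#' @param fit a [powerlaw_fit()] of the modulus magnitude (prefactor G0 in Pa
#'   at omega = 1 rad/s, exponent alpha in (0, 1]) or a [power_law_medium()].
#' @param drags a [drag_factors()] object.
#' @param temperature bath temperature in K.
#' @param lags lag times (s) at which to evaluate the prediction.
#' @param axis "both" (default; sum of parallel and perpendicular
#'   predictions), "parallel" or "perpendicular".
#' @return an `msd_curve` of the equilibrium prediction.
#' @export
fdt_msd_prediction <- function(fit, drags, temperature, lags,
                               axis = c("both", "parallel",
                                        "perpendicular")) {
  axis <- match.arg(axis)
  if (inherits(fit, "power_law_medium")) {
    G0 <- fit$G0; alpha <- fit$alpha
  } else if (inherits(fit, "powerlaw_fit")) {
    G0 <- fit$prefactor; alpha <- fit$exponent
  } else stop_invalid("fit must be a powerlaw_fit or power_law_medium")
  if (alpha <= 0 || alpha > 1)
    stop_invalid("FDT prediction needs alpha in (0, 1], got %s",
                 format(alpha))
  if (any(lags <= 0)) stop_invalid("lags must be positive")
  stopifnot(inherits(drags, "drag_factors"))
  med <- power_law_medium(G0, alpha)
  pref_par <- equilibrium_msd_prefactor(med, drags$K_parallel, temperature)
  pref_perp <- equilibrium_msd_prefactor(med, drags$K_perpendicular,
                                         temperature)
  pref <- switch(axis, both = pref_par + pref_perp,
                 parallel = pref_par, perpendicular = pref_perp)
  out <- data.frame(lag = lags, value = pref * lags^alpha,
                    n_pairs = NA_integer_)
  attr(out, "axis") <- axis
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Effective temperature from measured versus equilibrium MSD
#'
#' Pointwise ratio of the measured MSD to the equilibrium (FDT) prediction on
#' their common lags, expressed in units of the bath temperature. A ratio of
#' 1 signals thermal equilibrium; ratios >> 1 growing with lag signal active
#' driving (the ratio grows as tau^(beta - alpha) when the measured exponent
#' beta exceeds the modulus exponent alpha).
#'
#' @param msd_measured,msd_eq `msd_curve` objects; `msd_eq` is typically from
#'   [fdt_msd_prediction()] evaluated on `msd_measured$lag`.
#' @param tol relative tolerance for matching lags, default 1e-8.
#' @return data.frame with columns `lag` (s) and `T_eff` (bath-temperature
#'   units).
#' @export
effective_temperature <- function(msd_measured, msd_eq, tol = 1e-8) {
  stopifnot(inherits(msd_measured, "msd_curve"), inherits(msd_eq, "msd_curve"))
  idx <- match_lags(msd_measured$lag, msd_eq$lag, tol)
  if (!nrow(idx)) stop_invalid("no common lag support")
  eq <- msd_eq$value[idx$j]
  if (any(eq <= 0)) stop_invalid("equilibrium MSD must be positive")
  data.frame(lag = msd_measured$lag[idx$i],
             T_eff = msd_measured$value[idx$i] / eq)
}

match_lags <- function(a, b, tol) {
  j <- vapply(a, function(l) {
    k <- which(abs(b - l) <= tol * max(l, .Machine$double.eps))
    if (length(k)) k[1] else NA_integer_
  }, integer(1))
  keep <- !is.na(j)
  data.frame(i = which(keep), j = j[keep])
}
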