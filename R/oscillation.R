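#' Oscillating-field protocol
#'
#' @param beta0 angular amplitude of the oscillating field direction (rad);
#'   must be positive and small-angle (<= 0.5 rad) for the linearized torque
#'   balance.
#' @param frequencies drive frequencies in Hz. Default: the standard active
#'   band 0.2, 0.5, 1, 5, 10, 20 Hz.
#' @return object of class `field_protocol`.
#' @export
field_protocol <- function(beta0 = 0.3,
                           frequencies = c(0.2, 0.5, 1, 5, 10, 20)) {
  if (beta0 <= 0 || beta0 > 0.5)
    stop_invalid("beta0 must be in (0, 0.5] rad for the small-angle regime")
  if (any(frequencies <= 0)) stop_invalid("frequencies must be positive (Hz)")
  structure(list(beta0 = beta0, frequencies = sort(frequencies)),
            class = "field_protocol")
}

#' Simulate forced-oscillation records of a chain in a medium
#'
#' In the linearized torque balance a chain driven by a field of angular
#' amplitude beta0 responds with amplitude theta0 and phase lag delta given by
#' (beta0/theta0) e^{i delta} = 1 + kappa V G*(omega) / Gamma_0. Optional
#' Gaussian angular noise of standard deviation `noise_sd` is added to the
#' measured chain amplitude and phase.
#'
#' @param probe a [chain_probe()] with N >= 2 and positive moment.
#' @param medium a [power_law_medium()].
#' @param protocol a [field_protocol()].
#' @param noise_sd angular noise s.d. in rad (applied to theta0 and delta).
#' @param seed integer seed (used only when noise_sd > 0).
#' @return data.frame of class `oscillation_records` with columns
#'   `freq_hz`, `beta0_rad`, `theta0_rad`, `delta_rad`.
#' @examples
#' rec <- simulate_oscillation_records(chain_probe(3),
#'                                     power_law_medium(8.6, 0.40),
#'                                     field_protocol())
#' @export
simulate_oscillation_records <- function(probe, medium, protocol,
                                         noise_sd = 0, seed = NULL) {
  stopifnot(inherits(probe, "chain_probe"),
            inherits(medium, "power_law_medium"),
            inherits(protocol, "field_protocol"))
  G0t <- magnetic_prefactor(probe)  # errors for N < 2 or zero moment
  kV <- kappa_factor(probe$n_endosomes) * chain_volume(probe)
  omega <- 2 * pi * protocol$frequencies
  ratio <- 1 + kV * modulus(medium, omega) / G0t
  theta0 <- protocol$beta0 / Mod(ratio)
  delta <- Arg(ratio)
  if (noise_sd > 0) {
    with_seed(seed, {
      theta0 <- pmax(theta0 + stats::rnorm(length(theta0), sd = noise_sd),
                     1e-12)
      delta <- delta + stats::rnorm(length(delta), sd = noise_sd)
    })
  }
  out <- data.frame(freq_hz = protocol$frequencies,
                    beta0_rad = protocol$beta0,
                    theta0_rad = theta0,
                    delta_rad = delta)
  class(out) <- c("oscillation_records", "data.frame")
  out
}

#' Complex modulus from forced-oscillation records (torque balance)
#'
#' Inverts the linearized magnetic torque balance per frequency point:
#' G' = Gamma_0/(kappa V) (beta0/theta0 cos(delta) - 1),
#' G'' = Gamma_0/(kappa V) beta0/theta0 sin(delta).
#' Points with theta0 <= 0 are unmeasurable and dropped with a warning;
#' negative G' points (possible under measurement noise) are kept and
#' flagged in the `negative_Gp` column.
#'
#' @param records an `oscillation_records` data.frame (columns `freq_hz`,
#'   `beta0_rad`, `theta0_rad`, `delta_rad`); several chains may be
#'   concatenated.
#' @param probe the [chain_probe()] the records were measured with.
#' @return data.frame of class `modulus_spectrum` with columns `omega`
#'   (rad/s), `G_prime`, `G_dprime`, `magnitude` (Pa), `phase` (rad) and
#'   `negative_Gp`.
#' @export
active_modulus <- function(records, probe) {
  stopifnot(inherits(probe, "chain_probe"))
  need <- c("freq_hz", "beta0_rad", "theta0_rad", "delta_rad")
  if (!all(need %in% names(records)))
    stop_invalid("records must have columns %s", paste(need, collapse = ", "))
  bad <- records$theta0_rad <= 0
  if (any(bad)) {
    warning(sprintf("%d unmeasurable point(s) with theta0 <= 0 dropped",
                    sum(bad)))
    records <- records[!bad, , drop = FALSE]
  }
  if (!nrow(records)) stop_invalid("no measurable oscillation records")
  pref <- magnetic_prefactor(probe) /
    (kappa_factor(probe$n_endosomes) * chain_volume(probe))
  r <- records$beta0_rad / records$theta0_rad
  Gp <- pref * (r * cos(records$delta_rad) - 1)
  Gpp <- pref * r * sin(records$delta_rad)
  out <- data.frame(omega = 2 * pi * records$freq_hz,
                    G_prime = Gp, G_dprime = Gpp,
                    magnitude = sqrt(Gp^2 + Gpp^2),
                    phase = atan2(Gpp, Gp),
                    negative_Gp = Gp < 0)
  out <- out[order(out$omega), ]
  rownames(out) <- NULL
  class(out) <- c("modulus_spectrum", "data.frame")
  out
}

#' @export
print.modulus_spectrum <- function(x, ...) {
  cat(sprintf("Modulus spectrum: %d points, omega in [%.3g, %.3g] rad/s\n",
              nrow(x), min(x$omega), max(x$omega)))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Check the power-law phase relation of a modulus spectrum
#'
#' For a pure power-law medium the loss angle satisfies phi = alpha pi/2 at
#' every frequency. Compares the measured per-frequency phase with the value
#' implied by a fitted exponent.
#'
#' @param spectrum a `modulus_spectrum`.
#' @param fit a [powerlaw_fit()] of the modulus magnitude (exponent = alpha).
#' @param tol tolerance on the mean phase residual (rad), default 0.1.
#' @return list with `expected` (alpha pi/2), `mean_phase`, `consistent`
#'   (logical) and per-frequency `residuals`.
#' @export
check_phase_consistency <- function(spectrum, fit, tol = 0.1) {
  stopifnot(inherits(spectrum, "modulus_spectrum"),
            inherits(fit, "powerlaw_fit"))
  expected <- fit$exponent * pi / 2
  res <- spectrum$phase - expected
  list(expected = expected,
       mean_phase = mean(spectrum$phase),
       consistent = abs(mean(spectrum$phase) - expected) <= tol,
       residuals = data.frame(omega = spectrum$omega, residual = res))
}
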