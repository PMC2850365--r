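#' Calibrate the motor-model slope map gamma(x)
#'
#' Brute-force simulation of the step-force model over a grid of duration
#' exponents x: for each x the averaged spectrum is computed at a reference
#' mean force and fitted over the simulator's power-law range (2e-2 to 2e2
#' Hz), yielding the spectral decay exponent gamma(x) and the reference
#' amplitude A_ref(x) at omega = 1 rad/s. [fit_motor_model()] interpolates
#' this table, so fitting never nests stochastic simulation inside an
#' optimizer. The table shipped as [motor_calibration] was generated with
#' `calibrate_motor_slopes(seed = 20260921)` at the defaults below.
#'
#' @param x_grid grid of duration exponents.
#' @param F_ref reference mean force (N), default 20 pN.
#' @param duration,n_realizations per-x simulation effort.
#' @param seed integer seed.
#' @return data.frame with columns `x`, `gamma`, `log10_A_ref`, `F_ref`.
#' @export
calibrate_motor_slopes <- function(x_grid = seq(1.1, 2.3, by = 0.1),
                                   F_ref = 20e-12,
                                   duration = 200, n_realizations = 16,
                                   seed = 1) {
  band <- 2 * pi * c(2e-2, 2e2)
  rows <- lapply(seq_along(x_grid), function(i) {
    p <- motor_params(F_mean = F_ref, x = x_grid[i])
    sp <- motor_spectrum(p, duration = duration,
                         n_realizations = n_realizations,
                         seed = seed + 1000L * i)
    fit <- fit_force_powerlaw(sp, band = band)
    data.frame(x = x_grid[i], gamma = fit$gamma,
               log10_A_ref = log10(fit$A), F_ref = F_ref)
  })
  do.call(rbind, rows)
}

#' Motor-model slope calibration table
#'
#' Mapping from the on-time duration exponent x to the spectral decay
#' exponent gamma and reference amplitude of the step-force simulator
#' (F_ref = 20 pN, tau_off = 30 ms, t_on in [0.1 ms, 100 s], dt = 0.1 ms;
#' 48 realizations of 200 s per grid point, fitted over 2e-2 to 2e2 Hz).
#' gamma decreases monotonically with x, close to the renewal-theory
#' power-counting gamma = 3 - x for 1 < x < 2. The grid stops at x = 2.1
#' (gamma = 0.91): beyond it rare long pulses dominate single spectra and
#' the slope estimate is no longer stable at this averaging effort, and
#' motor fitting targets spectra of microtubule-bearing cells, whose decay
#' exponents lie at or above 1.
#'
#' @format data.frame with columns `x`, `gamma`, `log10_A_ref` (log10 of the
#'   spectral amplitude in N^2 s at omega = 1 rad/s), `F_ref` (N).
#' @seealso [calibrate_motor_slopes()], [fit_motor_model()]
#' @export
motor_calibration <- data.frame(
  x = c(1.1, 1.2, 1.3, 1.4, 1.5, 1.6, 1.7, 1.8, 1.9, 2.0, 2.1),
  gamma = c(1.80315, 1.73220, 1.64820, 1.57165, 1.47265, 1.38749,
            1.29105, 1.16577, 1.08680, 0.99536, 0.91445),
  log10_A_ref = c(-21.917, -21.884, -21.781, -21.744, -21.785, -21.874,
                  -22.063, -22.407, -22.693, -23.038, -23.359),
  F_ref = 2e-11)
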