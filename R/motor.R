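#' Step-force motor model parameters
#'
#' Renewal model of the active force exerted by molecular motors on an
#' endosome: square force pulses of random sign (probability 1/2 each) and
#' amplitude n F0, with n the number of engaged motors drawn per pulse from
#' Normal(n_mot, sigma_n) rounded to an integer >= 1. Pulse durations t_on
#' follow a truncated power law P(t_on) ~ t_on^-x on [t_on_min, t_on_max];
#' dwell times between pulses are exponential with mean tau_off. The mean
#' force over a trajectory is F_mean = n_mot F0.
#'
#' @param F_mean mean force over a trajectory (N); sets n_mot = F_mean / F0.
#'   Either `F_mean` or `n_mot` must be given.
#' @param x duration exponent of the on-time distribution (> 0).
#' @param n_mot mean motor number; overrides `F_mean` when supplied.
#' @param sigma_n s.d. of the motor number; default 0.3 * n_mot.
#' @param F0 single-motor stall force (N), default 7 pN.
#' @param tau_off mean dwell time (s), default 0.030.
#' @param t_on_min,t_on_max truncation of the on-time distribution (s),
#'   defaults 1e-4 and 100.
#' @param dt simulation time step (s), default 1e-4; must not exceed
#'   t_on_min.
#' @return object of class `motor_params`.
#' @examples
#' motor_params(F_mean = 22e-12, x = 1.5)
#' @export
motor_params <- function(F_mean = NULL, x, n_mot = NULL, sigma_n = NULL,
                         F0 = 7e-12, tau_off = 0.030,
                         t_on_min = 1e-4, t_on_max = 100, dt = 1e-4) {
  if (is.null(n_mot)) {
    if (is.null(F_mean)) stop_invalid("supply F_mean or n_mot")
    n_mot <- F_mean / F0
  }
  if (is.null(sigma_n)) sigma_n <- 0.3 * n_mot
  if (x <= 0) stop_invalid("x must be positive")
  if (F0 <= 0 || n_mot <= 0 || sigma_n < 0 || tau_off <= 0)
    stop_invalid("F0, n_mot, tau_off must be positive; sigma_n >= 0")
  if (t_on_min <= 0 || t_on_min >= t_on_max)
    stop_invalid("need 0 < t_on_min < t_on_max")
  if (dt <= 0 || dt > t_on_min)
    stop_invalid("dt must satisfy 0 < dt <= t_on_min")
  structure(list(F0 = F0, n_mot = n_mot, sigma_n = sigma_n, x = x,
                 tau_off = tau_off, t_on_min = t_on_min,
                 t_on_max = t_on_max, dt = dt,
                 F_mean = n_mot * F0),
            class = "motor_params")
}

#' @export
print.motor_params <- function(x, ...) {
  cat(sprintf(
    "Motor model: F_mean = %.3g pN (n_mot = %.2f x F0 = %.3g pN), x = %.3g, tau_off = %.3g s\n",
    x$F_mean * 1e12, x$n_mot, x$F0 * 1e12, x$x, x$tau_off))
  invisible(x)
}

#' Sample pulse durations from the truncated power law
#'
#' Inverse-CDF draws from P(t) ~ t^-x on [t_min, t_max]; the x = 1 case is
#' handled by its log-uniform limit.
#'
#' @param x exponent (> 0).
#' @param t_min,t_max truncation bounds (s).
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return numeric vector of on-times in [t_min, t_max].
#' @export
sample_on_times <- function(x, t_min, t_max, n, seed = NULL) {
  if (t_min >= t_max) stop_invalid("t_min must be < t_max")
  if (x <= 0) stop_invalid("x must be positive")
  if (n < 1) stop_invalid("n must be >= 1")
  with_seed(seed, {
    u <- stats::runif(n)
    if (abs(x - 1) < 1e-12) {
      t_min * (t_max / t_min)^u
    } else {
      a <- 1 - x
      (t_min^a + u * (t_max^a - t_min^a))^(1 / a)
    }
  })
}

#' Cumulative distribution of the truncated power law
#'
#' Closed-form CDF of P(t) ~ t^-x on [t_min, t_max]; the analytic oracle for
#' [sample_on_times()].
#'
#' @inheritParams sample_on_times
#' @param q quantiles at which to evaluate.
#' @return CDF values in [0, 1].
#' @export
ptrunc_powerlaw <- function(q, x, t_min, t_max) {
  q <- pmin(pmax(q, t_min), t_max)
  if (abs(x - 1) < 1e-12) {
    log(q / t_min) / log(t_max / t_min)
  } else {
    a <- 1 - x
    (q^a - t_min^a) / (t_max^a - t_min^a)
  }
}

#' Sample dwell times
#'
#' Exponential off-times with mean `tau_off` (detachment independent of how
#' long the motors have been engaged).
#'
#' @param tau_off mean dwell (s).
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return numeric vector of positive dwell times.
#' @export
sample_dwell_times <- function(tau_off, n, seed = NULL) {
  if (tau_off <= 0) stop_invalid("tau_off must be positive")
  with_seed(seed, stats::rexp(n, rate = 1 / tau_off))
}

#' Simulated force time series
#'
#' @param times uniform sample times (s).
#' @param values force values (N), piecewise constant with zero dwells.
#' @return object of class `force_series`.
#' @export
force_series <- function(times, values) {
  if (length(times) != length(values)) stop_invalid("length mismatch")
  dts <- diff(times)
  if (any(dts <= 0) || max(dts) - min(dts) > 1e-12)
    stop_invalid("times must be uniform and increasing")
  structure(list(times = times, values = values, dt = mean(dts)),
            class = "force_series")
}

#' @export
print.force_series <- function(x, ...) {
  on <- x$values != 0
  cat(sprintf(
    "Force series: %d samples, dt = %.3g s, duty %.2f, mean |F| (on) = %.3g pN, max |F| = %.3g pN\n",
    length(x$values), x$dt, mean(on),
    if (any(on)) mean(abs(x$values[on])) * 1e12 else 0,
    max(abs(x$values)) * 1e12))
  invisible(x)
}

#' @export
plot.force_series <- function(x, ...) {
  graphics::plot(x$times, x$values * 1e12, type = "s",
                 xlab = "time (s)", ylab = "F (pN)", ...)
  invisible(x)
}

#' Simulate the motor step-force process
#'
#' Alternating pulse/dwell renewal sequence sampled on a uniform grid of step
#' `params$dt`: each pulse lasts a power-law distributed on-time, carries a
#' random sign and amplitude n F0 (n ~ Normal(n_mot, sigma_n), rounded,
#' clipped at 1), and is separated from the next by an exponential dwell at
#' zero force.
#'
#' @param params a [motor_params()].
#' @param duration trajectory length (s); must be at least 100 time steps.
#' @param seed optional integer seed.
#' @return a [force_series()].
#' @examples
#' f <- simulate_force(motor_params(F_mean = 22e-12, x = 1.5, dt = 1e-3,
#'                                  t_on_min = 1e-3), duration = 5, seed = 1)
#' @export
simulate_force <- function(params, duration, seed = NULL) {
  stopifnot(inherits(params, "motor_params"))
  if (duration < 100 * params$dt)
    stop_invalid("duration must be >= 100 dt")
  with_seed(seed, {
    ## draw renewal intervals in batches until the trajectory is covered
    on <- numeric(0); off <- numeric(0); amp <- numeric(0)
    total <- 0
    while (total < duration) {
      batch <- max(64L, ceiling((duration - total) /
                                  (params$tau_off + 5 * params$t_on_min)))
      on_b <- sample_on_times(params$x, params$t_on_min, params$t_on_max,
                              batch)
      off_b <- stats::rexp(batch, rate = 1 / params$tau_off)
      n_b <- pmax(1, round(stats::rnorm(batch, params$n_mot,
                                        params$sigma_n)))
      s_b <- sample(c(-1, 1), batch, replace = TRUE)
      on <- c(on, on_b); off <- c(off, off_b)
      amp <- c(amp, s_b * n_b * params$F0)
      total <- sum(on) + sum(off)
    }
    n_steps <- floor(duration / params$dt)
    tgrid <- seq(0, by = params$dt, length.out = n_steps)
    f <- numeric(n_steps)
    t0 <- 0
    for (k in seq_along(on)) {
      i0 <- floor(t0 / params$dt) + 1L
      i1 <- min(n_steps, ceiling((t0 + on[k]) / params$dt))
      if (i0 > n_steps) break
      f[i0:i1] <- amp[k]
      t0 <- t0 + on[k] + off[k]
    }
    force_series(tgrid, f)
  })
}

#' Averaged power spectrum of the motor force model
#'
#' One-sided periodogram of simulated force realizations, averaged over
#' realizations and binned on a logarithmic frequency grid (equal weight per
#' log bin, appropriate for power-law fitting). Units N^2 s over rad/s, same
#' convention as [force_spectrum()].
#'
#' @param params a [motor_params()].
#' @param duration length of each realization (s), default 200.
#' @param n_realizations number of realizations averaged, default 20.
#' @param seed integer seed (each realization uses seed + i - 1, or
#'   consecutive RNG draws when NULL).
#' @param bins_per_decade log-binning density, default 24.
#' @return an `endo_spectrum` (units N^2 s).
#' @export
motor_spectrum <- function(params, duration = 200, n_realizations = 20,
                           seed = NULL, bins_per_decade = 24) {
  stopifnot(inherits(params, "motor_params"))
  if (n_realizations < 1) stop_invalid("n_realizations must be >= 1")
  n_steps <- floor(duration / params$dt)
  nf <- floor(n_steps / 2)
  freqs <- (1:nf) / (n_steps * params$dt)
  omega <- 2 * pi * freqs
  acc <- numeric(nf)
  for (i in seq_len(n_realizations)) {
    fs <- simulate_force(params, duration,
                         seed = if (is.null(seed)) NULL else seed + i - 1L)
    X <- stats::fft(fs$values - mean(fs$values))
    P <- 2 * params$dt * Mod(X[2:(nf + 1)])^2 / n_steps
    if (n_steps %% 2 == 0) P[nf] <- P[nf] / 2
    acc <- acc + P
  }
  S <- acc / n_realizations
  ## log-frequency binning
  lw <- log10(omega)
  bin <- floor((lw - lw[1]) * bins_per_decade)
  wb <- tapply(omega, bin, mean)
  sb <- tapply(S, bin, mean)
  keep <- sb > 0
  endo_spectrum(as.numeric(wb[keep]), as.numeric(sb[keep]), units = "N^2 s",
                meta = list(duration = duration,
                            n_realizations = n_realizations,
                            dt = params$dt,
                            bins_per_decade = bins_per_decade))
}

#' Fit the motor model to a measured force spectrum
#'
#' Two-stage deterministic fit against the precomputed simulator calibration
#' (see [motor_slope_calibration()]): the duration exponent x is read off the
#' fitted spectral slope gamma by inverse interpolation of the calibration's
#' monotone gamma(x) curve; F_mean then follows from the amplitude, using
#' the exact scaling S ~ F_mean^2 at fixed x:
#' F_mean = F_ref sqrt(A_target / A_ref(x)).
#'
#' @param target a `spectrum_fit` from [fit_force_powerlaw()], or an
#'   `endo_spectrum` (then fitted first over `band`).
#' @param band fitting band (rad/s) when `target` is a spectrum; default the
#'   simulator's calibrated range 2e-2 to 2e2 Hz in rad/s.
#' @param calibration calibration table, default the shipped
#'   [motor_calibration] table.
#' @return object of class `motor_fit`: list with `F_mean` (N), `x`,
#'   `gamma`, `A`, `params` (a [motor_params()] at the fitted values) and
#'   `target_fit`.
#' @examples
#' fit <- fit_motor_model(structure(list(A = 1e-22, gamma = 1.5),
#'                                  class = "spectrum_fit"))
#' @export
fit_motor_model <- function(target,
                            band = 2 * pi * c(2e-2, 2e2),
                            calibration = motor_calibration) {
  if (inherits(target, "endo_spectrum"))
    target <- fit_force_powerlaw(target, band = band)
  if (!inherits(target, "spectrum_fit"))
    stop_invalid("target must be an endo_spectrum or spectrum_fit")
  cal <- calibration[order(calibration$x), ]
  g <- target$gamma
  if (g > max(cal$gamma) || g < min(cal$gamma))
    stop_invalid(
      "target gamma = %.3g outside calibrated range [%.3g, %.3g] (x in [%g, %g])",
      g, min(cal$gamma), max(cal$gamma), min(cal$x), max(cal$x))
  ## gamma(x) is monotone decreasing: invert by interpolation
  o <- order(cal$gamma)
  x_hat <- stats::approx(cal$gamma[o], cal$x[o], xout = g)$y
  logA_ref <- stats::approx(cal$x, cal$log10_A_ref, xout = x_hat)$y
  F_mean <- cal$F_ref[1] * sqrt(target$A / 10^logA_ref)
  structure(list(F_mean = F_mean, x = x_hat, gamma = g, A = target$A,
                 params = motor_params(F_mean = F_mean, x = x_hat),
                 target_fit = target),
            class = "motor_fit")
}

#' @export
print.motor_fit <- function(x, ...) {
  cat(sprintf(
    "Motor fit: F_mean = %.3g pN, x = %.3g  (from A = %.3g N^2 s, gamma = %.3g)\n",
    x$F_mean * 1e12, x$x, x$A, x$gamma))
  invisible(x)
}

#' @export
coef.motor_fit <- function(object, ...) {
  c(F_mean = object$F_mean, x = object$x)
}

#' @export
#' @rdname fit_motor_model
#' @param object a `motor_fit`.
#' @param nsim number of force realizations to simulate.
#' @param duration realization length (s).
#' @param ... unused.
simulate.motor_fit <- function(object, nsim = 1, seed = NULL,
                               duration = 100, ...) {
  out <- lapply(seq_len(nsim), function(i)
    simulate_force(object$params, duration,
                   seed = if (is.null(seed)) NULL else seed + i - 1L))
  if (nsim == 1) out[[1]] else out
}

#' @export
#' @rdname fit_motor_model
predict.motor_fit <- function(object, omega = NULL, ...) {
  if (is.null(omega)) omega <- 2 * pi * 10^seq(-2, 2, length.out = 60)
  endo_spectrum(omega, object$A * omega^(-object$gamma), units = "N^2 s")
}
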