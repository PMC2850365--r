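## Synthetic track generators.
##
## All generators take an explicit `seed`; identical seeds and parameters give
## bit-identical tracks. Randomness is drawn inside a local RNG scope so the
## caller's RNG state is left untouched.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(
        rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

#' Fractional Gaussian noise by circulant embedding
#'
#' Davies-Harte exact synthesis of n unit-variance fractional Gaussian noise
#' samples with Hurst exponent H in (0, 1). The circulant eigenvalues of the
#' fGn autocovariance are non-negative for all H in (0,1), making the method
#' exact.
#'
#' @param n number of samples.
#' @param H Hurst exponent in (0, 1). Cumulated samples form fractional
#'   Brownian motion with MSD ~ t^(2H).
#' @return numeric vector of length n (unit variance, zero mean process).
#' @noRd
fgn_davies_harte <- function(n, H) {
  if (H <= 0 || H >= 1) stop_invalid("Hurst exponent must be in (0,1)")
  acov <- function(k) 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                               abs(k - 1)^(2 * H))
  r <- acov(0:n)
  circ <- c(r, rev(r[2:n]))          # length 2n
  lam <- Re(stats::fft(circ))
  lam[lam < 0 & lam > -1e-8] <- 0
  if (any(lam < 0))
    stop_invalid("circulant embedding failed (negative eigenvalue)")
  m <- 2L * n
  z <- complex(m)
  z[1] <- sqrt(lam[1] / m) * stats::rnorm(1)
  z[n + 1] <- sqrt(lam[n + 1] / m) * stats::rnorm(1)
  u <- stats::rnorm(n - 1)
  v <- stats::rnorm(n - 1)
  z[2:n] <- sqrt(lam[2:n] / (2 * m)) * complex(real = u, imaginary = v)
  z[m:(n + 2)] <- Conj(z[2:n])
  Re(stats::fft(z))[1:n]
}

#' Simulate a stationary-increment Gaussian track with power-law MSD
#'
#' Generates a 2-D fractional-Brownian track whose per-axis time-averaged MSD
#' follows `msd_prefactor * lag^msd_exponent` (each axis independently, equal
#' prefactors unless `msd_prefactor` has length 2: parallel, perpendicular).
#' This is the generic engine behind the thermal power-law generator and is
#' also used directly to emulate superdiffusive (exponent > 1) driven motion
#' with Gaussian statistics.
#'
#' @param msd_prefactor per-axis MSD prefactor(s), m^2 / s^exponent.
#' @param msd_exponent MSD exponent in (0, 2).
#' @param duration track length in seconds.
#' @param dt sampling interval in seconds.
#' @param seed integer seed.
#' @param axis chain-axis unit vector, default c(1, 0).
#' @return an [endo_track()].
#' @export
simulate_fbm_track <- function(msd_prefactor, msd_exponent, duration, dt,
                               seed = NULL, axis = c(1, 0)) {
  if (any(msd_prefactor <= 0)) stop_invalid("msd_prefactor must be positive")
  if (msd_exponent <= 0 || msd_exponent >= 2)
    stop_invalid("msd_exponent must be in (0, 2), got %s",
                 format(msd_exponent))
  if (dt <= 0 || duration <= 0) stop_invalid("duration and dt must be positive")
  n <- floor(duration / dt)
  if (n < 2) stop_invalid("duration/dt must be >= 2")
  H <- msd_exponent / 2
  pref <- rep_len(msd_prefactor, 2L)
  ## increment over dt has variance C * dt^exponent for MSD = C t^exponent
  with_seed(seed, {
    sx <- sqrt(pref[1]) * dt^H
    sy <- sqrt(pref[2]) * dt^H
    xin <- fgn_davies_harte(n, H) * sx
    yin <- fgn_davies_harte(n, H) * sy
    endo_track(times = seq(0, by = dt, length.out = n + 1),
               x = c(0, cumsum(xin)), y = c(0, cumsum(yin)), axis = axis)
  })
}

#' Simulate a Brownian track in a Newtonian fluid
#'
#' Independent Gaussian increments per axis with diffusion coefficient
#' D_axis = kB T / (K_axis * viscosity), K from [drag_factors()], so the
#' per-axis MSD is 2 D_axis t. The x axis is the chain (parallel) axis.
#'
#' @param probe a [chain_probe()]; its `temperature` sets kB T.
#' @param viscosity fluid viscosity in Pa s.
#' @param duration,dt track length and sampling interval (s); duration/dt
#'   must be at least 100.
#' @param seed integer seed.
#' @param drags optional [drag_factors()] override.
#' @return an [endo_track()].
#' @examples
#' tr <- simulate_newtonian_track(chain_probe(1, d_endo = 1e-6,
#'                                            temperature = 298),
#'                                viscosity = 0.619, duration = 10,
#'                                dt = 0.01, seed = 1)
#' @export
simulate_newtonian_track <- function(probe, viscosity, duration, dt,
                                     seed = NULL, drags = NULL) {
  stopifnot(inherits(probe, "chain_probe"))
  if (!is.numeric(viscosity) || viscosity <= 0)
    stop_invalid("viscosity must be positive (Pa s)")
  if (dt <= 0) stop_invalid("dt must be positive")
  n <- floor(duration / dt)
  if (n < 100) stop_invalid("duration/dt must be >= 100 (got %d)", n)
  K <- if (is.null(drags)) drag_factors(probe) else drags
  kT <- thermal_energy(probe$temperature)
  Dpar <- kT / (K$K_parallel * viscosity)
  Dperp <- kT / (K$K_perpendicular * viscosity)
  with_seed(seed, {
    xin <- stats::rnorm(n, sd = sqrt(2 * Dpar * dt))
    yin <- stats::rnorm(n, sd = sqrt(2 * Dperp * dt))
    endo_track(times = seq(0, by = dt, length.out = n + 1),
               x = c(0, cumsum(xin)), y = c(0, cumsum(yin)))
  })
}

#' Simulate thermal motion in a power-law medium
#'
#' Equilibrium (FDT-obeying) track of a probe embedded in a medium
#' G*(omega) = G0 (i omega)^alpha: per-axis MSD is
#' 2 kB T / (K_axis G0 Gamma(1 + alpha)) * t^alpha, realised as fractional
#' Brownian motion via circulant embedding. The target exponent holds over
#' lags roughly in [10 dt, duration / 10].
#'
#' @param probe a [chain_probe()].
#' @param medium a [power_law_medium()] with alpha strictly inside (0, 1).
#' @param duration,dt track length and sampling interval (s).
#' @param seed integer seed.
#' @param drags optional [drag_factors()] override.
#' @return an [endo_track()].
#' @export
simulate_thermal_powerlaw_track <- function(probe, medium, duration, dt,
                                            seed = NULL, drags = NULL) {
  stopifnot(inherits(probe, "chain_probe"),
            inherits(medium, "power_law_medium"))
  if (medium$alpha <= 0 || medium$alpha >= 1)
    stop_invalid("thermal power-law tracks need alpha in (0,1), got %s",
                 format(medium$alpha))
  K <- if (is.null(drags)) drag_factors(probe) else drags
  C <- equilibrium_msd_prefactor(medium,
                                 c(K$K_parallel, K$K_perpendicular),
                                 probe$temperature)
  simulate_fbm_track(C, medium$alpha, duration, dt, seed = seed)
}

## MSD prefactor of the equilibrium (FDT) response: C in <dx^2> = C t^alpha.
equilibrium_msd_prefactor <- function(medium, K, temperature) {
  2 * thermal_energy(temperature) /
    (K * medium$G0 * gamma(1 + medium$alpha))
}

#' Simulate an actively driven track
#'
#' Linear response of the probe to an imposed force along the chain axis in a
#' power-law medium, computed exactly as the creep superposition of the force
#' steps: x(t) = (1/K_par) sum_j dF_j J(t - t_j), with
#' J(t) = t^alpha / (G0 Gamma(1+alpha)) the medium's creep compliance and
#' dF_j the force jumps. A constant force therefore produces steady Stokes
#' drift in the Newtonian limit. Optionally a thermal equilibrium track is
#' superposed on both axes.
#'
#' @param probe a [chain_probe()].
#' @param medium a [power_law_medium()] with alpha in (0, 1].
#' @param force a [force_series()] sampled at the desired track dt.
#' @param seed integer seed (used only for the thermal component).
#' @param thermal logical; superpose equilibrium thermal motion. Default TRUE.
#' @param drags optional [drag_factors()] override.
#' @return an [endo_track()] sampled at the force series' dt.
#' @export
simulate_active_track <- function(probe, medium, force, seed = NULL,
                                  thermal = TRUE, drags = NULL) {
  stopifnot(inherits(probe, "chain_probe"),
            inherits(medium, "power_law_medium"),
            inherits(force, "force_series"))
  K <- if (is.null(drags)) drag_factors(probe) else drags
  dt <- force$dt
  times <- force$times
  n <- length(times)
  if (n < 2) stop_invalid("force series too short")
  f <- force$values
  ## force jumps and their onset times (f is piecewise constant)
  jumps <- c(f[1], diff(f))
  idx <- which(jumps != 0)
  xact <- numeric(n)
  if (length(idx)) {
    a <- medium$alpha
    ga <- medium$G0 * gamma(1 + a)
    for (j in idx) {
      tl <- times[j:n] - times[j]
      xact[j:n] <- xact[j:n] + jumps[j] * tl^a / (ga * K$K_parallel)
    }
  }
  if (thermal) {
    if (medium$alpha >= 1) {
      ## Newtonian medium: plain Brownian thermal component
      th <- simulate_newtonian_track(probe, medium$G0, (n - 1) * dt, dt,
                                     seed = seed, drags = K)
    } else {
      th <- simulate_thermal_powerlaw_track(probe, medium, (n - 1) * dt, dt,
                                            seed = seed, drags = K)
    }
    m <- length(th$x)
    endo_track(times = times[seq_len(min(n, m))],
               x = xact[seq_len(min(n, m))] + th$x[seq_len(min(n, m))],
               y = th$y[seq_len(min(n, m))])
  } else {
    endo_track(times = times, x = xact, y = numeric(n))
  }
}
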