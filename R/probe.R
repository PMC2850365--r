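#' Chain-of-endosomes probe
#'
#' Describes a chain of `n_endosomes` magnetic endosomes used as an
#' intracellular microrheology probe: geometry (endosome diameter), magnetics
#' (magnetic moment per endosome) and bath temperature. All quantities are SI.
#'
#' @param n_endosomes integer number of endosomes in the chain (N >= 1).
#' @param d_endo endosome diameter in meters. Default 0.6 micrometers.
#' @param moment magnetic moment of one endosome in A m^2. Default 3.7e-15.
#' @param temperature bath temperature in kelvin. Default 310 K (cell interior);
#'   use 298 K for room-temperature calibration fluids.
#'
#' @return An object of class `chain_probe`.
#' @examples
#' p <- chain_probe(3)
#' chain_volume(p)
#' @export
chain_probe <- function(n_endosomes, d_endo = 0.6e-6, moment = 3.7e-15,
                        temperature = 310) {
  if (length(n_endosomes) != 1L || is.na(n_endosomes) ||
      n_endosomes < 1 || n_endosomes != round(n_endosomes))
    stop_invalid("n_endosomes must be a single integer >= 1 (got %s)",
                 format(n_endosomes))
  if (!is.numeric(d_endo) || d_endo <= 0)
    stop_invalid("d_endo must be a positive length in meters")
  if (!is.numeric(moment) || moment < 0)
    stop_invalid("moment must be a non-negative magnetic moment in A m^2")
  if (!is.numeric(temperature) || temperature <= 0)
    stop_invalid("temperature must be positive (kelvin)")
  structure(
    list(n_endosomes = as.integer(n_endosomes), d_endo = d_endo,
         moment = moment, temperature = temperature),
    class = "chain_probe")
}

#' @export
print.chain_probe <- function(x, ...) {
  cat(sprintf(
    "Chain probe: N = %d endosome(s), d = %.3g um, m = %.3g A m^2, T = %.1f K\n",
    x$n_endosomes, x$d_endo * 1e6, x$moment, x$temperature))
  invisible(x)
}

#' Volume of the chain probe
#'
#' Total volume of the N spheres making up the chain, V = N (pi/6) d^3.
#'
#' @param probe a [chain_probe()].
#' @return volume in m^3.
#' @export
chain_volume <- function(probe) {
  stopifnot(inherits(probe, "chain_probe"))
  probe$n_endosomes * (pi / 6) * probe$d_endo^3
}

#' Magnetic torque prefactor of a chain
#'
#' The restoring torque scale of a chain of magnetic endosomes in a rotating
#' field arises from dipole-dipole interaction of each endosome with its
#' neighbours: Gamma_0 = (3 mu_0 m^2 / 4 pi) N^2 / d_endo^3. Calibrated for
#' chains, so N >= 2 is required.
#'
#' @param probe a [chain_probe()] with `n_endosomes >= 2` and `moment > 0`.
#' @return torque prefactor Gamma_0 in N m.
#' @examples
#' magnetic_prefactor(chain_probe(2))
#' @export
magnetic_prefactor <- function(probe) {
  stopifnot(inherits(probe, "chain_probe"))
  if (probe$n_endosomes < 2)
    stop_invalid("magnetic_prefactor requires a chain (N >= 2), got N = %d",
                 probe$n_endosomes)
  if (probe$moment <= 0)
    stop_invalid("magnetic_prefactor requires a positive magnetic moment")
  (3 * .mu0 * probe$moment^2 / (4 * pi)) *
    probe$n_endosomes^2 / probe$d_endo^3
}

#' Rotational geometry factor of a chain
#'
#' Dimensionless rotational drag factor of an N-endosome chain,
#' kappa = 2 N^2 / (ln(N/2) + 2.4/N), calibrated against Newtonian fluids.
#'
#' @param n_endosomes integer N >= 2.
#' @return dimensionless kappa.
#' @examples
#' kappa_factor(2)  # 8 / 1.2
#' @export
kappa_factor <- function(n_endosomes) {
  if (any(n_endosomes < 2) || any(n_endosomes != round(n_endosomes)))
    stop_invalid("kappa_factor requires integer N >= 2")
  2 * n_endosomes^2 / (log(n_endosomes / 2) + 2.4 / n_endosomes)
}

#' Translational drag factors of the probe
#'
#' Geometric drag factors K (in meters) such that the friction coefficient
#' along an axis is K * viscosity. For a single sphere K = 3 pi d on both
#' axes (Stokes). For a chain of N touching spheres the chain is treated as a
#' rod of length L = N d and diameter d with the Tirado-Garcia de la Torre
#' short-rod end corrections:
#'   K_par  = 2 pi L / (ln p - 0.207 + 0.980/p - 0.133/p^2)
#'   K_perp = 4 pi L / (ln p + 0.839 + 0.185/p + 0.233/p^2),  p = L/d,
#' which keep K_perp > K_par down to p = 2. If a correction ever drives a
#' denominator non-positive the sphere of equal volume is used instead, with
#' a warning.
#'
#' @param probe a [chain_probe()].
#' @param override optional list with elements `K_parallel`, `K_perpendicular`
#'   (meters) returned verbatim, e.g. experimentally calibrated values.
#' @return object of class `drag_factors`: list with `K_parallel`,
#'   `K_perpendicular` (m) and `source`.
#' @examples
#' drag_factors(chain_probe(1, d_endo = 1e-6))  # 3 pi 1e-6 on both axes
#' @export
drag_factors <- function(probe, override = NULL) {
  stopifnot(inherits(probe, "chain_probe"))
  if (!is.null(override)) {
    if (!all(c("K_parallel", "K_perpendicular") %in% names(override)))
      stop_invalid("override must contain K_parallel and K_perpendicular")
    if (override$K_parallel <= 0 || override$K_perpendicular <= 0)
      stop_invalid("override drag factors must be positive")
    return(structure(list(K_parallel = override$K_parallel,
                          K_perpendicular = override$K_perpendicular,
                          source = "user"),
                     class = "drag_factors"))
  }
  N <- probe$n_endosomes
  d <- probe$d_endo
  if (N == 1L) {
    K <- 3 * pi * d
    return(structure(list(K_parallel = K, K_perpendicular = K,
                          source = "sphere"),
                     class = "drag_factors"))
  }
  L <- N * d
  p <- L / d   # = N
  den_par <- log(p) - 0.207 + 0.980 / p - 0.133 / p^2
  den_perp <- log(p) + 0.839 + 0.185 / p + 0.233 / p^2
  if (den_par <= 0 || den_perp <= 0) {
    warning("short-rod log regime: falling back to equal-volume sphere")
    d_eq <- d * N^(1 / 3)
    K <- 3 * pi * d_eq
    return(structure(list(K_parallel = K, K_perpendicular = K,
                          source = "sphere"),
                     class = "drag_factors"))
  }
  structure(list(K_parallel = 2 * pi * L / den_par,
                 K_perpendicular = 4 * pi * L / den_perp,
                 source = "chain-formula"),
            class = "drag_factors")
}

#' @export
print.drag_factors <- function(x, ...) {
  cat(sprintf("Drag factors (%s): K_par = %.4g m, K_perp = %.4g m\n",
              x$source, x$K_parallel, x$K_perpendicular))
  invisible(x)
}

#' Dipolar cohesion force between two touching endosomes
#'
#' Contact force between two coaxial point dipoles of moment m at
#' centre-to-centre distance d: F_d = 3 mu_0 m^2 / (2 pi d^4). This is the
#' force an instantaneous motor pull must exceed to detach an endosome from
#' its chain.
#'
#' @param probe a [chain_probe()].
#' @return force in newtons.
#' @export
dipolar_cohesion_force <- function(probe) {
  stopifnot(inherits(probe, "chain_probe"))
  3 * .mu0 * probe$moment^2 / (2 * pi * probe$d_endo^4)
}
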