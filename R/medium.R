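#' Power-law viscoelastic medium
#'
#' Complex shear modulus of the form G*(omega) = G0 (i omega)^alpha, so that
#' G' = G0 omega^alpha cos(alpha pi/2), G'' = G0 omega^alpha sin(alpha pi/2)
#' and the loss angle is phi = alpha pi/2 at every frequency. alpha = 1 is a
#' Newtonian fluid of viscosity G0; alpha = 0 an elastic solid of modulus G0.
#'
#' @param G0 modulus prefactor in Pa at omega = 1 rad/s (for alpha = 1 this is
#'   the viscosity in Pa s).
#' @param alpha dimensionless power-law exponent in [0, 1].
#' @return object of class `power_law_medium`.
#' @examples
#' m <- power_law_medium(8.6, 0.40)
#' modulus(m, 2 * pi * 1)   # complex G* at 1 Hz
#' @export
power_law_medium <- function(G0, alpha) {
  if (!is.numeric(G0) || G0 <= 0) stop_invalid("G0 must be positive (Pa)")
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    stop_invalid("alpha must lie in [0, 1], got %s", format(alpha))
  structure(list(G0 = G0, alpha = alpha), class = "power_law_medium")
}

#' @export
print.power_law_medium <- function(x, ...) {
  cat(sprintf(
    "Power-law medium: |G(omega)| = %.3g Pa x omega^%.3g, phase %.3g rad\n",
    x$G0, x$alpha, x$alpha * pi / 2))
  invisible(x)
}

#' Complex shear modulus of a medium
#'
#' @param medium a [power_law_medium()].
#' @param omega angular frequency (rad/s), vectorized.
#' @return complex vector G*(omega).
#' @export
modulus <- function(medium, omega) {
  stopifnot(inherits(medium, "power_law_medium"))
  medium$G0 * complex(modulus = abs(omega)^medium$alpha,
                      argument = medium$alpha * pi / 2 * sign(omega))
}

#' Creep compliance of a power-law medium
#'
#' Displacement response per unit step force applied through a drag factor K:
#' x(t) = F J(t) / K with J(t) = t^alpha / (G0 Gamma(1 + alpha)).
#' In the Newtonian limit (alpha = 1, G0 = eta) this is x = F t / (K eta),
#' i.e. steady Stokes drift.
#'
#' @param medium a [power_law_medium()] with alpha in (0, 1].
#' @param t time since force onset (s), vectorized; negative times return 0.
#' @return compliance J(t) in 1/Pa (multiply by F/K for displacement).
#' @export
creep_compliance <- function(medium, t) {
  stopifnot(inherits(medium, "power_law_medium"))
  a <- medium$alpha
  if (a <= 0) stop_invalid("creep_compliance requires alpha > 0")
  ifelse(t > 0, t^a / (medium$G0 * gamma(1 + a)), 0)
}
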