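## Literature parameter presets for the three cytoskeleton conditions.
## G0 (Pa at omega = 1 rad/s) and alpha describe the modulus power law,
## beta the measured MSD exponent, gamma the force-spectrum decay, and
## teff_1s the effective temperature (bath units) at lag 1 s used to scale
## synthetic active tracks. "microtubules_only" means actin disrupted
## (latrunculin A); "actin_only" means microtubules disrupted (nocodazole).
.condition_table <- data.frame(
  label = c("intact", "microtubules_only", "actin_only"),
  G0 = c(8.6, 3.5, 5.7),
  alpha = c(0.40, 0.56, 0.49),
  beta = c(1.3, 1.2, 0.8),
  gamma = c(1.5, 1.1, 0.8),
  teff_1s = c(1000, 300, 10),
  stringsAsFactors = FALSE)

#' Cytoskeleton condition preset
#'
#' Literature values of the modulus power law (G0, alpha), MSD exponent beta
#' and force-spectrum exponent gamma for the three experimental conditions:
#' intact cytoskeleton, microtubules only (actin disrupted) and actin only
#' (microtubules disrupted). `teff_1s` is the effective-temperature scale at
#' lag 1 s used by the synthetic generator to set active-track amplitudes
#' (roughly 1000 bath temperatures for the intact condition, barely 10 once
#' microtubules are disrupted; the intermediate condition is not constrained
#' by a printed value and is set to 300).
#'
#' @param label one of "intact", "microtubules_only", "actin_only".
#' @return list with `label`, `G0`, `alpha`, `beta`, `gamma`, `teff_1s` and
#'   `medium` (a [power_law_medium()]).
#' @examples
#' condition_preset("intact")$alpha
#' @export
condition_preset <- function(label = c("intact", "microtubules_only",
                                       "actin_only")) {
  label <- match.arg(label)
  row <- .condition_table[.condition_table$label == label, ]
  list(label = label, G0 = row$G0, alpha = row$alpha, beta = row$beta,
       gamma = row$gamma, teff_1s = row$teff_1s,
       medium = power_law_medium(row$G0, row$alpha))
}

#' Synthetic active track at a condition preset
#'
#' Stationary-increment Gaussian (fractional-Brownian) track whose per-axis
#' MSD exponent is the preset's beta and whose amplitude at lag 1 s is
#' `teff_1s` times the equilibrium FDT prediction for the preset medium.
#'
#' @param preset a [condition_preset()].
#' @param probe a [chain_probe()].
#' @param duration,dt track length and sampling (s), defaults 60 s, 0.01 s.
#' @param seed integer seed.
#' @return an [endo_track()].
#' @export
simulate_condition_track <- function(preset, probe, duration = 60,
                                     dt = 0.01, seed = NULL) {
  stopifnot(inherits(probe, "chain_probe"))
  K <- drag_factors(probe)
  eq1s <- equilibrium_msd_prefactor(preset$medium,
                                    c(K$K_parallel, K$K_perpendicular),
                                    probe$temperature)
  simulate_fbm_track(msd_prefactor = preset$teff_1s * eq1s,
                     msd_exponent = preset$beta,
                     duration = duration, dt = dt, seed = seed)
}
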