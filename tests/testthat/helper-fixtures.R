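## Shared fixtures: the glycerol-validation probe (chains of 1-um beads in a
## 0.619 Pa s fluid at 25 C) and the standard intracellular probe.

kB <- 1.380649e-23

glycerol_probe <- function(N = 2) {
  chain_probe(N, d_endo = 1e-6, moment = 1e-14, temperature = 298)
}

cell_probe <- function(N = 3) chain_probe(N)

glycerol_eta <- 0.619

## Band-averaged ratio of the Langevin-inferred to the thermal force
## spectrum for one Newtonian track (the in-silico counterpart of the
## calibration-fluid check).
newtonian_spectrum_ratio <- function(probe, eta, seed, duration = 60,
                                     dt = 0.01, band = c(2, 50)) {
  K <- drag_factors(probe)
  ctx <- langevin_context(power_law_medium(eta, 1), K, probe$temperature,
                          axis = "parallel")
  tr <- simulate_newtonian_track(probe, eta, duration, dt, seed = seed)
  sff <- force_spectrum(tr, ctx, n_segments = 8)
  eq <- thermal_force_spectrum(ctx, sff$omega)
  keep <- sff$omega >= band[1] & sff$omega <= band[2]
  mean(sff$value[keep] / eq$value[keep])
}

## Mean fitted force-spectrum decay exponent for fractional-Gaussian tracks
## of MSD exponent beta pushed through the Langevin inversion in a medium
## (G0, alpha); one full-length Hann periodogram per track.
condition_gamma <- function(G0, alpha, beta, n_tracks, seed0,
                            duration = 60, dt = 0.01, band = c(0.2, 20)) {
  probe <- cell_probe()
  ctx <- langevin_context(power_law_medium(G0, alpha), drag_factors(probe),
                          probe$temperature, axis = "parallel")
  gams <- vapply(seq_len(n_tracks), function(i) {
    tr <- simulate_fbm_track(1e-13, beta, duration, dt, seed = seed0 + i)
    sff <- force_spectrum(tr, ctx, n_segments = 1, method = "differenced")
    fit_force_powerlaw(sff, band = band)$gamma
  }, numeric(1))
  mean(gams)
}
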