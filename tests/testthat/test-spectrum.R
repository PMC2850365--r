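test_that("position spectrum: sinusoid mass, white-noise Parseval, Brownian 1/w^2", {
  dt <- 0.01
  t <- seq(0, 60 - dt, by = dt)
  n <- length(t)
  ## pure sinusoid of amplitude a: spectral mass a^2/2 near omega0
  a <- 1e-7; w0 <- 2 * pi * 2
  tr <- endo_track(t, a * sin(w0 * t), numeric(n))
  sp <- position_spectrum(tr, "x", n_segments = 4)
  near <- abs(sp$omega - w0) < 2
  expect_equal(spectrum_integral(sp, band = range(sp$omega[near])), a^2 / 2,
               tolerance = 0.05)
  ## white-noise positions: flat spectrum integrating to the variance
  set.seed(5)
  z <- stats::rnorm(n, sd = 1e-8)
  trw <- endo_track(t, z, numeric(n))
  spw <- position_spectrum(trw, "x", n_segments = 8)
  expect_equal(spectrum_integral(spw), stats::var(z), tolerance = 0.1)
  fitw <- fit_powerlaw(spw$omega, spw$value)
  expect_lt(abs(fitw$exponent), 0.1)
  ## Brownian track: S_xx ~ 4 D / omega^2 in the mid-band
  p <- glycerol_probe(1)
  D <- kB * 298 / (drag_factors(p)$K_parallel * glycerol_eta)
  trb <- simulate_newtonian_track(p, glycerol_eta, 60, dt, seed = 41)
  spb <- position_spectrum(trb, "parallel", n_segments = 8)
  keep <- spb$omega > 2 & spb$omega < 50
  expect_equal(mean(spb$value[keep] * spb$omega[keep]^2 / (4 * D)), 1,
               tolerance = 0.25)
})

test_that("differenced estimator is leakage-free on steep power-law spectra", {
  ## fractional tracks: fitted S_xx slope should be -(beta + 1)
  for (beta in c(0.8, 1.3)) {
    slopes <- vapply(1:10, function(i) {
      tr <- simulate_fbm_track(1e-13, beta, 60, 0.01, seed = 900 + i)
      sp <- position_spectrum(tr, "parallel", n_segments = 1,
                              method = "differenced")
      keep <- sp$omega >= 0.2 & sp$omega <= 20
      fit_powerlaw(sp$omega[keep], sp$value[keep])$exponent
    }, numeric(1))
    expect_equal(mean(slopes), -(beta + 1), tolerance = 0.05)
  }
  ## normalization agrees with the Welch estimator on Brownian tracks
  p <- glycerol_probe(1)
  D <- kB * 298 / (drag_factors(p)$K_parallel * glycerol_eta)
  lv <- vapply(1:4, function(i) {
    tr <- simulate_newtonian_track(p, glycerol_eta, 60, 0.01,
                                   seed = 950 + i)
    sp <- position_spectrum(tr, "parallel", n_segments = 1,
                            method = "differenced")
    keep <- sp$omega > 2 & sp$omega < 50
    mean(sp$value[keep] * sp$omega[keep]^2 / (4 * D))
  }, numeric(1))
  expect_equal(mean(lv), 1, tolerance = 0.15)
})

test_that("Parseval bound: band integral of S_xx below the position variance", {
  p <- cell_probe()
  tr <- simulate_thermal_powerlaw_track(p, power_law_medium(8.6, 0.4),
                                        60, 0.01, seed = 43)
  sp <- position_spectrum(tr, "parallel", n_segments = 8)
  z <- tr$x * tr$axis[1] + tr$y * tr$axis[2]
  expect_lte(spectrum_integral(sp), stats::var(z) * 1.05)
})

test_that("force inversion: Newtonian white-force level and zero track", {
  p <- glycerol_probe(2)
  K <- drag_factors(p)
  ctx <- langevin_context(power_law_medium(glycerol_eta, 1), K, 298,
                          axis = "parallel")
  tr <- simulate_newtonian_track(p, glycerol_eta, 60, 0.01, seed = 44)
  sff <- force_spectrum(tr, ctx, n_segments = 8)
  level <- 4 * kB * 298 * K$K_parallel * glycerol_eta
  keep <- sff$omega > 2 & sff$omega < 50
  expect_equal(mean(sff$value[keep]) / level, 1, tolerance = 0.25)
  ## zero track maps to zero force spectrum
  t <- seq(0, 10, by = 0.01)
  tr0 <- endo_track(t, numeric(length(t)), numeric(length(t)))
  sff0 <- force_spectrum(tr0, ctx)
  expect_true(all(sff0$value == 0))
})

test_that("force-spectrum round trip recovers a known input force spectrum", {
  ## drive a probe with a simulated motor force, invert the track back
  p <- cell_probe()
  med <- power_law_medium(8.6, 0.40)
  K <- drag_factors(p)
  ctx <- langevin_context(med, K, p$temperature, axis = "parallel")
  mp <- motor_params(F_mean = 22e-12, x = 1.5, dt = 0.01, t_on_min = 0.01)
  nrep <- 6
  acc_in <- NULL; acc_out <- NULL
  for (i in seq_len(nrep)) {
    f <- simulate_force(mp, 60, seed = 500 + i)
    tr <- simulate_active_track(p, med, f, thermal = FALSE)
    est <- welch_psd(f$values, f$dt, n_segments = 1)
    sout <- force_spectrum(tr, ctx, n_segments = 1)
    acc_in <- if (is.null(acc_in)) est$S else acc_in + est$S
    acc_out <- if (is.null(acc_out)) sout$value else acc_out + sout$value
    omega <- sout$omega
  }
  keep <- omega > 1 & omega < 30
  ratio <- mean(acc_out[keep] / acc_in[keep])
  expect_equal(ratio, 1, tolerance = 0.25)
})

test_that("thermal force spectrum: Newtonian constant, power-law decay, T-linear", {
  K <- drag_factors(glycerol_probe(2))
  ctx <- langevin_context(power_law_medium(glycerol_eta, 1), K, 298)
  w <- 10^seq(-1, 2, by = 0.1)
  eq <- thermal_force_spectrum(ctx, w)
  expect_equal(eq$value,
               rep(4 * kB * 298 * K$K_parallel * glycerol_eta, length(w)),
               tolerance = 1e-12)
  ## power-law medium: decay exponent 1 - alpha
  ctxa <- langevin_context(power_law_medium(8.6, 0.40), K, 310)
  eqa <- thermal_force_spectrum(ctxa, w)
  fita <- fit_force_powerlaw(eqa, band = range(w))
  expect_equal(fita$gamma, 0.60, tolerance = 1e-10)
  ## doubling temperature doubles the spectrum
  ctx2 <- langevin_context(power_law_medium(8.6, 0.40), K, 620)
  expect_equal(thermal_force_spectrum(ctx2, w)$value, 2 * eqa$value,
               tolerance = 1e-12)
})

test_that("spectrum power-law fit is exact and validates its band", {
  w <- 10^seq(-1, 2, by = 0.1)
  sp <- endo_spectrum(w, 1e-22 * w^-1.5, units = "N^2 s")
  fit <- fit_force_powerlaw(sp, band = range(w))
  expect_equal(fit$A, 1e-22, tolerance = 1e-10)
  expect_equal(fit$gamma, 1.5, tolerance = 1e-12)
  expect_error(fit_force_powerlaw(sp, band = c(1e4, 1e5)), "points in band")
})
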