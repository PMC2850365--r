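test_that("MSD closed forms: ballistic drift and alternating steps", {
  ## linear drift x = v t: MSD = v^2 tau^2 exactly
  v <- 2e-8
  t <- seq(0, 10, by = 0.1)
  tr <- endo_track(t, v * t, numeric(length(t)))
  msd <- compute_msd(tr, axis = "parallel", max_lag_fraction = 0.2)
  expect_equal(msd$value, v^2 * msd$lag^2, tolerance = 1e-12)
  fit <- fit_msd_exponent(msd, band = c(0.1, 2))
  expect_equal(fit$exponent, 2, tolerance = 1e-10)
  ## alternating +h/-h positions: MSD = h^2 at odd lags, 0 at even lags
  h <- 1e-7
  x <- h * rep(c(0, 1), 10)
  tra <- endo_track(seq(0, by = 0.1, length.out = 20), x, numeric(20))
  msda <- compute_msd(tra, axis = "parallel", max_lag_fraction = 0.3)
  expect_equal(msda$value[1], h^2)
  expect_equal(msda$value[2], 0)
  expect_equal(msda$value[3], h^2)
})

test_that("MSD estimator recovers the diffusion coefficient of Brownian tracks", {
  p <- glycerol_probe(1)
  K <- drag_factors(p)
  D <- kB * 298 / (K$K_parallel * glycerol_eta)
  tr <- simulate_newtonian_track(p, glycerol_eta, 60, 0.01, seed = 21)
  for (ax in c("parallel", "perpendicular")) {
    msd <- compute_msd(tr, axis = ax)
    fit <- fit_powerlaw(msd$lag, msd$value, band = c(0.02, 1))
    expect_equal(predict(fit, 1) / 2, D, tolerance = 0.15)
  }
  ## "both" sums the two axes
  m2 <- compute_msd(tr, axis = "both")
  mp <- compute_msd(tr, axis = "parallel")
  mq <- compute_msd(tr, axis = "perpendicular")
  expect_equal(m2$value, mp$value + mq$value, tolerance = 1e-12)
  expect_error(compute_msd(endo_track(c(0, 1), c(0, 0), c(0, 0))),
               "10 samples")
})

test_that("FDT prediction: viscous limit, exponent identity, linearity in T", {
  p <- glycerol_probe(1)
  K <- drag_factors(p)
  lags <- 10^seq(-2, 1, by = 0.25)
  ## alpha = 1, G0 = eta: equilibrium MSD is 2 D tau (Stokes-Einstein)
  eq <- fdt_msd_prediction(power_law_medium(glycerol_eta, 1), K, 298, lags,
                           axis = "parallel")
  D <- kB * 298 / (K$K_parallel * glycerol_eta)
  expect_equal(eq$value, 2 * D * lags, tolerance = 1e-12)
  ## exponent equals alpha for generic media
  for (alpha in c(0.3, 0.56)) {
    eqa <- fdt_msd_prediction(power_law_medium(4, alpha), K, 310, lags)
    fit <- fit_powerlaw(eqa$lag, eqa$value)
    expect_equal(fit$exponent, alpha, tolerance = 1e-12)
  }
  ## doubling temperature doubles the prediction
  e1 <- fdt_msd_prediction(power_law_medium(4, 0.4), K, 300, lags)
  e2 <- fdt_msd_prediction(power_law_medium(4, 0.4), K, 600, lags)
  expect_equal(e2$value, 2 * e1$value, tolerance = 1e-12)
  expect_error(fdt_msd_prediction(power_law_medium(4, 0), K, 300, lags),
               "alpha")
})

test_that("effective temperature flags driven motion and not thermal motion", {
  p <- cell_probe()
  K <- drag_factors(p)
  med <- power_law_medium(8.6, 0.40)
  ## measured == equilibrium: ratio identically one
  lags <- 10^seq(-1.5, 0.5, by = 0.1)
  eq <- fdt_msd_prediction(med, K, p$temperature, lags)
  expect_equal(effective_temperature(eq, eq)$T_eff,
               rep(1, length(lags)), tolerance = 1e-12)
  ## thermal synthetic: ratio near one across the band
  tr <- simulate_thermal_powerlaw_track(p, med, 60, 0.01, seed = 31)
  msd <- compute_msd(tr, axis = "both")
  keep <- msd$lag >= 0.05 & msd$lag <= 2
  eqm <- fdt_msd_prediction(med, K, p$temperature, msd$lag[keep])
  ratio <- effective_temperature(
    structure(msd[keep, ], class = class(msd), axis = "both"), eqm)
  expect_true(all(ratio$T_eff > 0.7 & ratio$T_eff < 1.3))
  ## superdiffusive synthetic: ratio >> 1 and increasing with lag
  pre <- condition_preset("intact")
  tra <- simulate_condition_track(pre, p, 60, 0.01, seed = 32)
  msda <- compute_msd(tra, axis = "both")
  keepa <- msda$lag >= 0.05 & msda$lag <= 5
  eqa <- fdt_msd_prediction(med, K, p$temperature, msda$lag[keepa])
  ra <- effective_temperature(
    structure(msda[keepa, ], class = class(msda), axis = "both"), eqa)
  expect_gt(min(ra$T_eff), 10)
  expect_gt(stats::cor(log(ra$lag), log(ra$T_eff)), 0.9)
  expect_error(effective_temperature(eq, fdt_msd_prediction(
    med, K, p$temperature, lags + 1000)), "common lag")
})

test_that("FDT consistency: thermal tracks match the equilibrium prediction", {
  p <- cell_probe()
  med <- power_law_medium(5.7, 0.49)
  msds <- lapply(1:6, function(i)
    compute_msd(simulate_thermal_powerlaw_track(p, med, 60, 0.01,
                                                seed = 600 + i),
                axis = "both"))
  avg <- average_msd(msds)
  keep <- avg$lag >= 0.05 & avg$lag <= 5
  eq <- fdt_msd_prediction(med, drag_factors(p), p$temperature,
                           avg$lag[keep])
  rel <- avg$value[keep] / eq$value
  expect_true(all(rel > 0.8 & rel < 1.2))
})
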