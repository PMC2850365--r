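test_that("Newtonian tracks are deterministic, diffusive and Gaussian", {
  p <- chain_probe(1, d_endo = 1e-6, temperature = 298)
  a <- simulate_newtonian_track(p, glycerol_eta, 30, 0.01, seed = 42)
  b <- simulate_newtonian_track(p, glycerol_eta, 30, 0.01, seed = 42)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  ## fitted diffusion coefficient close to kB T / (3 pi d eta)
  tr <- simulate_newtonian_track(p, glycerol_eta, 60, 0.01, seed = 7)
  msd <- compute_msd(tr, axis = "parallel")
  fit <- fit_powerlaw(msd$lag, msd$value, band = c(0.02, 1))
  D_true <- kB * 298 / (3 * pi * 1e-6 * glycerol_eta)
  D_hat <- predict(fit, 1) / 2   # MSD = 2 D tau
  expect_equal(D_hat, D_true, tolerance = 0.15)
  ## increments: normal and uncorrelated
  inc <- diff(tr$x)
  n <- length(inc)
  expect_gt(stats::shapiro.test(inc[1:3000])$p.value, 1e-3)
  rho1 <- stats::cor(inc[-1], inc[-n])
  expect_lt(abs(rho1), 3 / sqrt(n))
})

test_that("vanishing mobility: near-infinite viscosity freezes the track", {
  p <- chain_probe(1, d_endo = 1e-6, temperature = 298)
  tr <- simulate_newtonian_track(p, 1e6, 1, 0.005, seed = 1)
  expect_lt(max(abs(tr$x), abs(tr$y)), 1e-10)
  expect_error(simulate_newtonian_track(p, -1, 10, 0.01), "viscosity")
  expect_error(simulate_newtonian_track(p, 1, 10, -0.01), "dt")
})

test_that("thermal power-law tracks recover the target MSD exponent", {
  p <- cell_probe()
  med <- power_law_medium(5, 0.5)
  tr <- simulate_thermal_powerlaw_track(p, med, 60, 0.01, seed = 3)
  expect_length(tr$x, 6001)
  expect_true(all(is.finite(tr$x)))
  expect_lt(abs(mean(diff(tr$x))), 3 * stats::sd(diff(tr$x)) / sqrt(6000))
  ## exponent recovered on a track-averaged MSD (single-track anomalous
  ## exponents carry large correlated errors at long lags)
  msds <- lapply(1:8, function(i)
    compute_msd(simulate_thermal_powerlaw_track(p, med, 60, 0.01, seed = i),
                "parallel"))
  fit <- fit_msd_exponent(average_msd(msds), band = c(0.05, 5))
  expect_equal(fit$exponent, 0.5, tolerance = 0.1)  # 0.5 +/- 0.05
  expect_error(
    simulate_thermal_powerlaw_track(p, power_law_medium(5, 1), 10, 0.01),
    "alpha")
})

test_that("thermal generator matches Brownian statistics in viscous limit", {
  p <- chain_probe(1, d_endo = 1e-6, temperature = 298)
  med <- power_law_medium(glycerol_eta, 0.995)
  m1 <- average_msd(lapply(1:6, function(i)
    compute_msd(simulate_thermal_powerlaw_track(p, med, 60, 0.01,
                                                seed = 100 + i),
                "parallel")))
  m2 <- average_msd(lapply(1:6, function(i)
    compute_msd(simulate_newtonian_track(p, glycerol_eta, 60, 0.01,
                                         seed = 200 + i), "parallel")))
  f1 <- fit_msd_exponent(m1, band = c(0.02, 1))
  f2 <- fit_msd_exponent(m2, band = c(0.02, 1))
  expect_equal(f1$exponent, f2$exponent, tolerance = 0.08)
  expect_equal(log(predict(f1, 0.1)), log(predict(f2, 0.1)),
               tolerance = 0.01)
})

test_that("active tracks follow the creep response of the medium", {
  p <- cell_probe()
  K <- drag_factors(p)
  ## zero force, no thermal component: identically zero
  f0 <- force_series(seq(0, 1, by = 0.01), numeric(101))
  tr0 <- simulate_active_track(p, power_law_medium(8.6, 0.4), f0,
                               thermal = FALSE)
  expect_true(all(tr0$x == 0) && all(tr0$y == 0))
  ## constant force on a Newtonian medium: linear drift at F / (K eta)
  eta <- 0.619
  F <- 1e-12
  fc <- force_series(seq(0, 10, by = 0.01), rep(F, 1001))
  trc <- simulate_active_track(p, power_law_medium(eta, 1), fc,
                               thermal = FALSE)
  v_expect <- F / (K$K_parallel * eta)
  v_fit <- stats::coef(stats::lm(trc$x ~ trc$times))[2]
  expect_equal(unname(v_fit), v_expect, tolerance = 1e-6)
  expect_true(all(abs(trc$y) == 0))
})

test_that("motor-driven tracks are superdiffusive at literature parameters", {
  p <- cell_probe()
  med <- power_law_medium(8.6, 0.40)
  mp <- motor_params(F_mean = 22e-12, x = 1.5, dt = 0.01, t_on_min = 0.01)
  betas <- vapply(1:8, function(i) {
    f <- simulate_force(mp, 60, seed = 100 + i)
    tr <- simulate_active_track(p, med, f, seed = 200 + i, thermal = TRUE)
    fit_msd_exponent(compute_msd(tr, "parallel"), band = c(0.05, 5))$exponent
  }, numeric(1))
  expect_gte(mean(betas), 1.1)
  expect_lte(mean(betas), 1.5)
})

test_that("power counting: MSD exponent of driven tracks is gamma - 1 + 2 alpha", {
  ## step forces with spectral decay gamma filtered through G ~ omega^alpha
  p <- cell_probe()
  for (cond in list(c(x = 1.5, alpha = 0.40), c(x = 1.9, alpha = 0.56))) {
    gamma_f <- 3 - cond[["x"]]   # renewal power counting for 1 < x < 2
    med <- power_law_medium(5, cond[["alpha"]])
    mp <- motor_params(F_mean = 22e-12, x = cond[["x"]], dt = 0.01,
                       t_on_min = 0.01)
    betas <- vapply(1:4, function(i) {
      f <- simulate_force(mp, 60, seed = 300 + i)
      tr <- simulate_active_track(p, med, f, thermal = FALSE)
      fit_msd_exponent(compute_msd(tr, "parallel"),
                       band = c(0.05, 5))$exponent
    }, numeric(1))
    expect_equal(mean(betas), gamma_f - 1 + 2 * cond[["alpha"]],
                 tolerance = 0.2)
  }
})

test_that("fBm generator self-consistency across exponents", {
  for (beta in c(0.5, 1.3)) {
    avg <- average_msd(lapply(1:6, function(i)
      compute_msd(simulate_fbm_track(1e-13, beta, 60, 0.01, seed = 300 + i),
                  "parallel")))
    fit <- fit_msd_exponent(avg, band = c(0.05, 5))
    expect_equal(fit$exponent, beta, tolerance = 0.12)
  }
  expect_error(simulate_fbm_track(1e-13, 2.1, 10, 0.01), "msd_exponent")
  a <- simulate_fbm_track(1e-13, 1.3, 10, 0.01, seed = 9)
  b <- simulate_fbm_track(1e-13, 1.3, 10, 0.01, seed = 9)
  expect_identical(a$x, b$x)
})
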