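#' Run the combined active/passive analysis pipeline
#'
#' Ties the stages together the way the dual experiment combines them:
#' (1) active: torque-balance inversion of oscillation records and power-law
#' fit of |G|; (2) passive: per-track MSD, averaged, anomalous-exponent fit;
#' (3) FDT comparison: equilibrium prediction from the fitted modulus and
#' the lag-dependent effective temperature; (4) force inversion: Welch
#' position spectra (parallel axis), generalized-Langevin inversion, power-law
#' fit of S_FF; (5) motor-model fit of (F_mean, x). Stages whose inputs are
#' missing or that fail are recorded as skipped and downstream stages that
#' depend on them are skipped too.
#'
#' @param probe a [chain_probe()].
#' @param tracks list of [endo_track()] (or NULL to skip passive stages).
#' @param records an `oscillation_records` data.frame (or NULL to skip the
#'   active stage; then `medium` must be given for the force inversion).
#' @param medium optional [power_law_medium()] used instead of the fitted
#'   modulus (e.g. known synthetic truth).
#' @param active_band modulus fit band in Hz, default c(0.2, 20).
#' @param passive_band MSD fit band in s, default c(0.05, 5).
#' @param spectrum_band force-spectrum fit band in rad/s, default c(0.2, 20).
#' @param average_moduli "geometric" (default) or "arithmetic" averaging of
#'   per-chain modulus magnitudes across probes before fitting.
#' @param n_segments Welch segments for position spectra, default 1
#'   (a single full-length windowed periodogram per track; tracks are
#'   averaged instead of segments).
#' @param spectrum_method position-spectrum estimator for the force stage,
#'   default "differenced" (leakage-free for steep exponent fits, see
#'   [position_spectrum()]).
#' @param seed integer seed recorded in the report (the pipeline itself is
#'   deterministic given its inputs).
#' @param out optional path; when given the report is written there as JSON.
#' @return list of class `endoforce_report` with per-stage results, fitted
#'   parameters `(alpha, G0, beta, gamma, A, F_mean, x)`, bands, warnings
#'   and status flags.
#' @export
run_pipeline <- function(probe, tracks = NULL, records = NULL,
                         medium = NULL,
                         active_band = c(0.2, 20),
                         passive_band = c(0.05, 5),
                         spectrum_band = c(0.2, 20),
                         average_moduli = c("geometric", "arithmetic"),
                         n_segments = 1, spectrum_method = "differenced",
                         seed = NULL, out = NULL) {
  stopifnot(inherits(probe, "chain_probe"))
  average_moduli <- match.arg(average_moduli)
  if (is.null(tracks) && is.null(records))
    stop_invalid("need at least one of tracks or records")
  report <- list(seed = seed,
                 probe = unclass(probe),
                 bands = list(active_hz = active_band,
                              passive_s = passive_band,
                              spectrum_rad_s = spectrum_band),
                 status = list(), warnings = character(0))
  ## --- active stage -------------------------------------------------------
  modulus_fit <- NULL
  if (!is.null(records)) {
    res <- try({
      spec <- active_modulus(records, probe)
      keep <- spec$omega >= 2 * pi * active_band[1] &
              spec$omega <= 2 * pi * active_band[2]
      spec_fit <- spec[keep, , drop = FALSE]
      mag <- if (average_moduli == "geometric") {
        exp(tapply(log(spec_fit$magnitude), spec_fit$omega, mean))
      } else tapply(spec_fit$magnitude, spec_fit$omega, mean)
      wuniq <- as.numeric(names(mag))
      fit <- fit_powerlaw(wuniq, as.numeric(mag))
      phase <- check_phase_consistency(spec, fit)
      list(spectrum = spec, fit = fit, phase = phase)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      report$status$active <- paste("failed:", attr(res, "condition")$message)
    } else {
      report$status$active <- "ok"
      report$active <- list(G0 = res$fit$prefactor,
                            alpha = res$fit$exponent,
                            r_squared = res$fit$r_squared,
                            mean_phase = res$phase$mean_phase,
                            phase_expected = res$phase$expected)
      modulus_fit <- res$fit
      if (any(res$spectrum$negative_Gp))
        report$warnings <- c(report$warnings, sprintf(
          "%d negative G' point(s) flagged", sum(res$spectrum$negative_Gp)))
    }
  } else report$status$active <- "skipped: no records"
  if (!is.null(medium)) {
    modulus_medium <- medium
  } else if (!is.null(modulus_fit)) {
    modulus_medium <- power_law_medium(modulus_fit$prefactor,
                                       min(1, max(1e-6,
                                                  modulus_fit$exponent)))
  } else modulus_medium <- NULL
  ## --- passive stage ------------------------------------------------------
  msd_avg <- NULL
  if (!is.null(tracks)) {
    res <- try({
      msds <- lapply(tracks, compute_msd, axis = "both")
      avg <- average_msd(msds)
      fit <- fit_msd_exponent(avg, band = passive_band)
      list(msd = avg, fit = fit)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      report$status$passive <- paste("failed:",
                                     attr(res, "condition")$message)
    } else {
      report$status$passive <- "ok"
      report$passive <- list(beta = res$fit$exponent,
                             msd_prefactor = res$fit$prefactor,
                             r_squared = res$fit$r_squared)
      msd_avg <- res$msd
    }
  } else report$status$passive <- "skipped: no tracks"
  ## --- FDT stage ----------------------------------------------------------
  if (!is.null(msd_avg) && !is.null(modulus_medium) &&
      modulus_medium$alpha < 1) {
    res <- try({
      drags <- drag_factors(probe)
      eq <- fdt_msd_prediction(modulus_medium, drags, probe$temperature,
                               lags = msd_avg$lag, axis = "both")
      teff <- effective_temperature(msd_avg, eq)
      i1 <- which.min(abs(teff$lag - 1))
      list(teff = teff, teff_1s = teff$T_eff[i1])
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      report$status$fdt <- paste("failed:", attr(res, "condition")$message)
    } else {
      report$status$fdt <- "ok"
      report$fdt <- list(teff_1s = res$teff_1s,
                         violated = res$teff_1s > 3)
    }
  } else report$status$fdt <- "skipped: needs tracks and a modulus"
  ## --- force-spectrum stage ----------------------------------------------
  sff_fit <- NULL
  if (!is.null(tracks) && !is.null(modulus_medium)) {
    res <- try({
      drags <- drag_factors(probe)
      ctx <- langevin_context(modulus_medium, drags, probe$temperature,
                              axis = "parallel")
      specs <- lapply(tracks, function(tr)
        force_spectrum(tr, ctx, n_segments = n_segments,
                       method = spectrum_method))
      w <- specs[[1]]$omega
      sbar <- Reduce(`+`, lapply(specs, `[[`, "value")) / length(specs)
      sp <- endo_spectrum(w, sbar, units = "N^2 s")
      fit_force_powerlaw(sp, band = spectrum_band)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      report$status$force <- paste("failed:", attr(res, "condition")$message)
    } else {
      report$status$force <- "ok"
      report$force <- list(A = res$A, gamma = res$gamma,
                           r_squared = res$r_squared)
      sff_fit <- res
    }
  } else report$status$force <- "skipped: needs tracks and a modulus"
  ## --- motor stage --------------------------------------------------------
  if (!is.null(sff_fit)) {
    res <- try(fit_motor_model(sff_fit), silent = TRUE)
    if (inherits(res, "try-error")) {
      report$status$motor <- paste("failed:", attr(res, "condition")$message)
    } else {
      report$status$motor <- "ok"
      report$motor <- list(F_mean = res$F_mean, x = res$x)
    }
  } else report$status$motor <- "skipped: needs a force-spectrum fit"
  class(report) <- "endoforce_report"
  if (!is.null(out)) {
    jsonlite::write_json(unclass(report), out, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  }
  report
}

#' @export
print.endoforce_report <- function(x, ...) {
  cat("Combined active/passive microrheology report\n")
  for (st in names(x$status)) cat(sprintf("  %-8s %s\n", st, x$status[[st]]))
  if (!is.null(x$active))
    cat(sprintf("  |G| = %.3g Pa x omega^%.3g\n", x$active$G0,
                x$active$alpha))
  if (!is.null(x$passive))
    cat(sprintf("  MSD exponent beta = %.3g\n", x$passive$beta))
  if (!is.null(x$fdt))
    cat(sprintf("  T_eff(1 s) = %.3g bath temperatures\n", x$fdt$teff_1s))
  if (!is.null(x$force))
    cat(sprintf("  S_FF = %.3g omega^-%.3g N^2 s\n", x$force$A,
                x$force$gamma))
  if (!is.null(x$motor))
    cat(sprintf("  Motor model: F_mean = %.3g pN, x = %.3g\n",
                x$motor$F_mean * 1e12, x$motor$x))
  invisible(x)
}

#' Generate a demonstration dataset on disk
#'
#' Writes, for each cytoskeleton condition preset, synthetic tracks and
#' oscillation records (with the preset's medium as ground truth), plus a
#' Newtonian glycerol-like calibration set (chains of N = 1..5 one-micron
#' beads in a 0.619 Pa s fluid at 298 K), and a `ground_truth.json` sidecar
#' echoing every generator parameter and seed.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed; file contents are reproducible byte-for-byte.
#' @param n_tracks tracks per condition, default 5.
#' @param duration,dt track length and sampling (s), defaults 60, 0.01.
#' @return invisibly, the list of files written.
#' @export
make_demo_dataset <- function(out_dir, seed = 1, n_tracks = 5,
                              duration = 60, dt = 0.01) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  truth <- list(seed = seed, duration = duration, dt = dt)
  probe <- chain_probe(3)
  for (lab in .condition_table$label) {
    preset <- condition_preset(lab)
    trs <- lapply(seq_len(n_tracks), function(i)
      simulate_condition_track(preset, probe, duration, dt,
                               seed = seed + 7919L * i +
                                 match(lab, .condition_table$label)))
    f1 <- file.path(out_dir, paste0("tracks_", lab, ".tsv"))
    write_tracks(trs, f1)
    rec <- simulate_oscillation_records(probe, preset$medium,
                                        field_protocol(),
                                        noise_sd = 0.002,
                                        seed = seed +
                                          match(lab, .condition_table$label))
    f2 <- file.path(out_dir, paste0("records_", lab, ".tsv"))
    write_oscillation_records(rec, f2)
    files <- c(files, f1, f2)
    truth[[lab]] <- preset[c("G0", "alpha", "beta", "gamma", "teff_1s")]
  }
  glyc <- list()
  for (N in 1:5) {
    pg <- chain_probe(N, d_endo = 1e-6, moment = 1e-14, temperature = 298)
    glyc[[N]] <- simulate_newtonian_track(pg, 0.619, duration, dt,
                                          seed = seed + 31L * N)
  }
  f3 <- file.path(out_dir, "tracks_glycerol.tsv")
  write_tracks(glyc, f3)
  files <- c(files, f3)
  truth$glycerol <- list(viscosity = 0.619, temperature = 298,
                         d_bead = 1e-6, n_beads = 1:5)
  f4 <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(truth, f4, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, f4)
  invisible(files)
}
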