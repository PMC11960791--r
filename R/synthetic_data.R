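# Synthetic cohort generator. No raw spectra are distributed with the
# measurement campaign this package models, so every pipeline stage is
# exercised against generated data with the statistical structure the
# analysis assumes: absorption spectra from the chromophore model,
# reduced scattering from the standard tissue power law
# musp(lambda) = a * (lambda/500)^(-b) (monotone decreasing), lognormal
# inter-sample variability at the reported per-tissue coefficients of
# variation, and multiplicative measurement noise. Each generator stores
# its per-sample ground truth so downstream recovery tests can consume it.

#' Solve the dry-background amplitude that reproduces a target absorption
#'
#' Given blood and water content and the background rate `B`, returns the
#' amplitude `A` such that the chromophore model evaluates to `target_mua`
#' at `wavelength`. Used to calibrate tissue presets against measured mean
#' absorption values.
#'
#' @param target_mua Target absorption coefficient (mm^-1).
#' @param fb,SO2,B,fw Remaining model parameters.
#' @param wavelength Calibration wavelength (nm, default 664).
#' @return Amplitude `A` (mm^-1).
#' @export
calibrate_dry_amplitude <- function(target_mua, fb, SO2, B, fw = 0.75,
                                    wavelength = 664) {
  lib <- chromophore_library(wavelength)
  blood <- fb * (SO2 * lib$mua_oxy + (1 - SO2) * lib$mua_deoxy)
  dry <- target_mua - blood - fw * lib$mua_water
  if (dry <= 0)
    stop("blood and water absorption already exceed the target mua")
  dry / exp(-B * wavelength)
}

#' Specification of a synthetic tissue group
#'
#' @param tissue_type Label.
#' @param fb,SO2,A,B,fw Chromophore truth (see [model_mua()]).
#' @param scatter_a Reduced scattering at the 500 nm reference (mm^-1).
#' @param scatter_b Scattering power (> 0, so musp decreases with
#'   wavelength).
#' @param cv_mua,cv_musp Inter-sample coefficients of variation applied
#'   (lognormally) to the absorption amplitudes (`fb`, `A`) and to
#'   `scatter_a`.
#' @param so2_sd Inter-sample standard deviation of SO2 (absolute,
#'   truncated to `[0, 1]`).
#' @param noise_cv Multiplicative measurement-noise coefficient of
#'   variation applied per wavelength.
#' @param n_samples Number of samples.
#' @return Object of class `tissue_generator_spec`.
#' @export
tissue_generator_spec <- function(tissue_type, fb, SO2, A, B, fw = 0.75,
                                  scatter_a, scatter_b, cv_mua = 0,
                                  cv_musp = 0, so2_sd = 0, noise_cv = 0,
                                  n_samples = 10) {
  .check_chromo_params(fb, SO2, A, B, fw)
  if (scatter_a <= 0 || scatter_b <= 0)
    stop("scattering power law needs a > 0 and b > 0")
  if (cv_mua < 0 || cv_musp < 0 || so2_sd < 0 || noise_cv < 0)
    stop("variability parameters must be >= 0")
  if (n_samples < 1) stop("n_samples must be >= 1")
  structure(
    list(tissue_type = tissue_type, fb = fb, SO2 = SO2, A = A, B = B,
         fw = fw, scatter_a = scatter_a, scatter_b = scatter_b,
         cv_mua = cv_mua, cv_musp = cv_musp, so2_sd = so2_sd,
         noise_cv = noise_cv, n_samples = n_samples),
    class = "tissue_generator_spec")
}

#' Tissue presets calibrated to the measured group means
#'
#' Generator specifications for the four tissue groups. Chromophore
#' parameters use the mean fitted values per tissue (normal: fb 3.9
#' percent, SO2 65 percent; tumor: fb 2.0 percent, SO2 46 percent); the
#' dry-background amplitude is calibrated with
#' [calibrate_dry_amplitude()] so the mean absorption at 664 nm matches the
#' measured group mean (normal 0.37, carbon 0.83, tumor 0.27, porcine 0.26
#' mm^-1), and the scattering power law is calibrated so musp at 664 nm
#' matches the measured mean (2.71, 1.97, 1.99, 2.60 mm^-1) with the power
#' implied by the 630-690 nm trend. Inter-sample CVs are the reported
#' per-tissue variations (normal 40/37, carbon 21/7, tumor 30/21 percent
#' for mua/musp); sample sizes are the measured cohort sizes (23, 3, 15,
#' 12).
#'
#' @param n_samples Optional named vector overriding per-tissue sample
#'   sizes.
#' @return Named list of [tissue_generator_spec()] objects
#'   (`normal`, `carbon`, `tumor`, `porcine`).
#' @export
tissue_presets <- function(n_samples = NULL) {
  musp_at <- function(a, b, wl) a * (wl / 500)^(-b)
  mk <- function(type, fb, SO2, B, mua664, musp664, b, cv_mua, cv_musp,
                 so2_sd, n) {
    a <- musp664 / (664 / 500)^(-b)
    tissue_generator_spec(
      tissue_type = type, fb = fb, SO2 = SO2,
      A = calibrate_dry_amplitude(mua664, fb, SO2, B),
      B = B, scatter_a = a, scatter_b = b, cv_mua = cv_mua,
      cv_musp = cv_musp, so2_sd = so2_sd, n_samples = n)
  }
  out <- list(
    normal = mk("normal", fb = 0.039, SO2 = 0.65, B = 0.004,
                mua664 = 0.37, musp664 = 2.71, b = 0.73,
                cv_mua = 0.40, cv_musp = 0.37, so2_sd = 0.18, n = 23),
    carbon = mk("carbon", fb = 0.039, SO2 = 0.30, B = 0.0005,
                mua664 = 0.83, musp664 = 1.97, b = 1.00,
                cv_mua = 0.21, cv_musp = 0.07, so2_sd = 0.10, n = 3),
    tumor = mk("tumor", fb = 0.020, SO2 = 0.46, B = 0.004,
               mua664 = 0.27, musp664 = 1.99, b = 1.10,
               cv_mua = 0.30, cv_musp = 0.21, so2_sd = 0.06, n = 15),
    porcine = mk("porcine", fb = 0.030, SO2 = 0.30, B = 0.004,
                 mua664 = 0.26, musp664 = 2.60, b = 0.55,
                 cv_mua = 0.19, cv_musp = 0.30, so2_sd = 0.10, n = 12))
  if (!is.null(n_samples)) {
    for (nm in names(n_samples)) out[[nm]]$n_samples <- n_samples[[nm]]
  }
  out
}

.with_seed <- function(seed, expr) {
  restore <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restore())
  force(expr)
}

.rlnorm_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic tissue group
#'
#' Draws per-sample chromophore and scattering parameters around the
#' specification truth (lognormal for the positive amplitudes `fb`, `A`,
#' `scatter_a`, `scatter_b`; truncated normal for SO2), evaluates the
#' absorption model and the scattering power law on `wavelength`, applies
#' multiplicative lognormal measurement noise at `noise_cv`, and returns a
#' [spectrum_group()] whose `truth` field holds the per-sample parameters.
#' Fixed seed implies byte-identical output.
#'
#' @param spec A [tissue_generator_spec()].
#' @param wavelength Wavelength grid (nm).
#' @param seed Integer seed.
#' @return A `spectrum_group` with per-sample `truth` data frame.
#' @export
generate_group <- function(spec, wavelength = seq(450, 800, by = 5), seed) {
  stopifnot(inherits(spec, "tissue_generator_spec"))
  if (missing(seed)) stop("seed is mandatory")
  lib <- chromophore_library(wavelength)
  n <- spec$n_samples
  .with_seed(seed, {
    fb_i <- .rlnorm_cv(n, spec$fb, spec$cv_mua)
    A_i <- .rlnorm_cv(n, spec$A, spec$cv_mua)
    B_i <- rep(spec$B, n)
    so2_i <- pmin(pmax(rnorm(n, spec$SO2, spec$so2_sd), 0), 1)
    a_i <- .rlnorm_cv(n, spec$scatter_a, spec$cv_musp)
    # mild jitter of the scattering power, only for variable cohorts so
    # that zero-CV specifications reproduce the truth exactly
    b_i <- .rlnorm_cv(n, spec$scatter_b,
                      if (spec$cv_musp > 0) 0.05 else 0)
    fb_i <- pmin(fb_i, 1)

    mua <- matrix(NA_real_, length(wavelength), n)
    musp <- matrix(NA_real_, length(wavelength), n)
    for (j in seq_len(n)) {
      m <- model_mua(lib, fb = fb_i[j], SO2 = so2_i[j], A = A_i[j],
                     B = B_i[j], fw = spec$fw)
      s <- a_i[j] * (wavelength / 500)^(-b_i[j])
      if (spec$noise_cv > 0) {
        m <- m * .rlnorm_cv(length(m), 1, spec$noise_cv)
        s <- s * .rlnorm_cv(length(s), 1, spec$noise_cv)
      }
      mua[, j] <- m
      musp[, j] <- s
    }
    truth <- data.frame(sample = seq_len(n), fb = fb_i, SO2 = so2_i,
                        A = A_i, B = B_i, fw = spec$fw, scatter_a = a_i,
                        scatter_b = b_i)
    spectrum_group(wavelength, mua, musp, tissue_type = spec$tissue_type,
                   truth = truth)
  })
}

#' Forward-simulate double-integrating-sphere measurements for a group
#'
#' Pushes every sample spectrum of a group through the forward slab Monte
#' Carlo model to produce per-wavelength (Rd, Tt) pairs, optionally
#' perturbed by multiplicative noise at the stated accuracy of the
#' measurement system (0.8 percent).
#'
#' @param group A `spectrum_group`.
#' @param thickness Slab thickness (mm), > 0.
#' @param g,n Anisotropy and refractive index of the forward model.
#' @param n_packets Packets per forward simulation.
#' @param seed Integer seed.
#' @param noise_cv Relative measurement noise on Rd and Tt (0 = noiseless;
#'   0.008 emulates the stated instrument accuracy).
#' @param samples Subset of sample indices (default all).
#' @return Data frame with columns `sample_id`, `tissue_type`,
#'   `wavelength`, `Rd`, `Tt`, `thickness`.
#' @export
generate_dis_measurements <- function(group, thickness, g = 0.9, n = 1.38,
                                      n_packets = 1e5, seed, noise_cv = 0,
                                      samples = seq_len(group$n)) {
  stopifnot(inherits(group, "spectrum_group"))
  if (missing(seed)) stop("seed is mandatory")
  if (!is.finite(thickness) || thickness <= 0)
    stop("thickness must be > 0")
  rows <- list()
  for (j in samples) {
    for (i in seq_along(group$wavelength)) {
      s <- layered_sample(thickness, mua = group$mua[i, j],
                          musp = group$musp[i, j], g = g, n = n)
      r <- simulate_slab(s, n_packets = n_packets,
                         seed = seed + 7919 * j + i)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = j, tissue_type = group$tissue_type,
        wavelength = group$wavelength[i], Rd = r$Rd, Tt = r$Tt,
        thickness = thickness)
    }
  }
  out <- do.call(rbind, rows)
  if (noise_cv > 0) {
    out <- .with_seed(seed + 1, {
      out$Rd <- out$Rd * (1 + rnorm(nrow(out), sd = noise_cv))
      out$Tt <- out$Tt * (1 + rnorm(nrow(out), sd = noise_cv))
      out
    })
  }
  out
}

#' Generate repeated-measurement series with declining oxygen saturation
#'
#' Emulates the ex vivo drift in which hemoglobin saturation falls between
#' repeated measurements of the same sample: per-sample parameters are
#' drawn once, then SO2 is reduced by `decline_per_step` at each subsequent
#' time point with everything else fixed.
#'
#' @param spec A [tissue_generator_spec()].
#' @param decline_per_step Absolute SO2 decrease per step (e.g. 0.08).
#' @param n_steps Number of time points (>= 2).
#' @param wavelength Wavelength grid (nm).
#' @param seed Integer seed.
#' @return List with `series` (list of samples, each a list of
#'   `data.frame(wavelength, mua)` per time point, suitable for
#'   [saturation_drift()]) and `truth` (per-sample starting parameters).
#' @export
generate_drift_series <- function(spec, decline_per_step = 0.08, n_steps = 3,
                                  wavelength = seq(450, 800, by = 5), seed) {
  stopifnot(inherits(spec, "tissue_generator_spec"))
  if (missing(seed)) stop("seed is mandatory")
  if (n_steps < 2) stop("need at least 2 time points")
  if (decline_per_step < 0) stop("decline_per_step must be >= 0")
  if (spec$SO2 - (n_steps - 1) * decline_per_step < 0)
    stop("SO2 would fall below 0 over the series")
  lib <- chromophore_library(wavelength)
  n <- spec$n_samples
  .with_seed(seed, {
    fb_i <- .rlnorm_cv(n, spec$fb, spec$cv_mua)
    A_i <- .rlnorm_cv(n, spec$A, spec$cv_mua)
    so2_i <- pmin(pmax(rnorm(n, spec$SO2, spec$so2_sd),
                       (n_steps - 1) * decline_per_step), 1)
    series <- lapply(seq_len(n), function(j) {
      lapply(seq_len(n_steps), function(k) {
        so2 <- so2_i[j] - (k - 1) * decline_per_step
        m <- model_mua(lib, fb = fb_i[j], SO2 = so2, A = A_i[j],
                       B = spec$B, fw = spec$fw)
        if (spec$noise_cv > 0)
          m <- m * .rlnorm_cv(length(m), 1, spec$noise_cv)
        data.frame(wavelength = wavelength, mua = m)
      })
    })
    list(series = series,
         truth = data.frame(sample = seq_len(n), fb = fb_i, A = A_i,
                            SO2_start = so2_i,
                            decline_per_step = decline_per_step))
  })
}
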