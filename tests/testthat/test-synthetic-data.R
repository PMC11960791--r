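test_that("zero variability reproduces the truth spectra exactly", {
  spec <- tissue_generator_spec("normal", fb = 0.039, SO2 = 0.65, A = 5,
                                B = 0.004, scatter_a = 3.3,
                                scatter_b = 0.73, n_samples = 4)
  g <- generate_group(spec, wavelength = lambda_vis, seed = 1)
  lib <- ref_lib()
  truth <- model_mua(lib, fb = 0.039, SO2 = 0.65, A = 5, B = 0.004)
  for (j in 1:4) expect_equal(g$mua[, j], truth)
  expect_equal(g$musp[, 1], 3.3 * (lambda_vis / 500)^(-0.73))
  expect_true(all(diff(g$musp[, 1]) < 0)) # monotone decreasing
})

test_that("generation is seed-reproducible and truth is stored", {
  spec <- tissue_presets()$tumor
  a <- generate_group(spec, wavelength = lambda_vis, seed = 7)
  b <- generate_group(spec, wavelength = lambda_vis, seed = 7)
  d <- generate_group(spec, wavelength = lambda_vis, seed = 8)
  expect_identical(a$mua, b$mua)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$mua, d$mua))
  expect_s3_class(a$truth, "data.frame")
  expect_equal(nrow(a$truth), spec$n_samples)
  expect_true(all(c("fb", "SO2", "A", "scatter_a") %in% names(a$truth)))
})

test_that("presets are calibrated to the measured group means at 664 nm", {
  presets <- tissue_presets(n_samples = c(normal = 400, carbon = 400,
                                          tumor = 400, porcine = 400))
  anchors <- c(normal = 0.37, carbon = 0.83, tumor = 0.27, porcine = 0.26)
  musp_anchors <- c(normal = 2.71, carbon = 1.97, tumor = 1.99,
                    porcine = 2.60)
  wl <- c(550, 664, 800)
  for (nm in names(anchors)) {
    g <- generate_group(presets[[nm]], wavelength = wl, seed = 11)
    i <- which(wl == 664)
    # lognormal amplitude draws around the truth preserve the mean; at
    # n = 400 the sample mean sits within ~3 standard errors
    se_mua <- sd(g$mua[i, ]) / sqrt(400)
    se_musp <- sd(g$musp[i, ]) / sqrt(400)
    expect_lt(abs(mean(g$mua[i, ]) - anchors[[nm]]), 3.5 * se_mua)
    expect_lt(abs(mean(g$musp[i, ]) - musp_anchors[[nm]]), 3.5 * se_musp)
  }
})

test_that("tumor preset absorbs less than normal in the hemoglobin bands", {
  presets <- tissue_presets()
  wl <- seq(500, 600, by = 10)
  gn <- generate_group(presets$normal, wavelength = wl, seed = 3)
  gt <- generate_group(presets$tumor, wavelength = wl, seed = 4)
  expect_true(all(rowMeans(gt$mua) < rowMeans(gn$mua)))
})

test_that("forward-simulated DIS measurements stay physical and invert back", {
  spec <- tissue_generator_spec("tumor", fb = 0.02, SO2 = 0.46, A = 3.5,
                                B = 0.004, scatter_a = 2.7, scatter_b = 1.1,
                                n_samples = 1)
  g <- generate_group(spec, wavelength = c(630, 664, 690), seed = 5)
  meas <- generate_dis_measurements(g, thickness = 0.7, n_packets = 1e5,
                                    seed = 6)
  expect_equal(nrow(meas), 3)
  expect_true(all(meas$Rd + meas$Tt <= 1))
  expect_true(all(meas$Rd > 0 & meas$Tt > 0))
  sp <- invert_spectrum(meas, thickness = 0.7, seed = 9)
  expect_true(all(sp$converged))
  expect_true(all(abs(sp$mua - g$mua[, 1]) / g$mua[, 1] < 0.05))
  expect_true(all(abs(sp$musp - g$musp[, 1]) / g$musp[, 1] < 0.05))
})

test_that("generator guards reject impossible settings", {
  spec <- tissue_presets()$normal
  expect_error(generate_dis_measurements(
    generate_group(spec, wavelength = c(664), seed = 1), thickness = 0,
    seed = 1), "thickness")
  expect_error(generate_drift_series(spec, decline_per_step = 0.5,
                                     n_steps = 3, seed = 1), "below 0")
  expect_error(tissue_generator_spec("x", fb = 0.02, SO2 = 0.5, A = 1,
                                     B = 0.004, scatter_a = 2,
                                     scatter_b = -1), "b > 0")
})

test_that("zero decline gives a constant drift series", {
  spec <- tissue_generator_spec("normal", fb = 0.039, SO2 = 0.65, A = 5,
                                B = 0.004, scatter_a = 3.3, scatter_b = 0.73,
                                n_samples = 2)
  ser <- generate_drift_series(spec, decline_per_step = 0, n_steps = 3,
                               wavelength = lambda_vis, seed = 2)
  expect_identical(ser$series[[1]][[1]], ser$series[[1]][[3]])
})
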