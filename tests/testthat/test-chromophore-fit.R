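test_that("the absorption model obeys its linearity identities", {
  lib <- ref_lib()
  # only water remains when blood and dry background vanish
  expect_equal(model_mua(lib, fb = 0, SO2 = 0.5, A = 0, B = 0.004),
               0.75 * lib$mua_water)
  # affine in SO2: the endpoint difference is fb * (oxy - deoxy)
  fb <- 0.04
  d <- model_mua(lib, fb = fb, SO2 = 1, A = 2, B = 0.004) -
    model_mua(lib, fb = fb, SO2 = 0, A = 2, B = 0.004)
  expect_equal(d, fb * (lib$mua_oxy - lib$mua_deoxy))
  # additive (linear) in fb at fixed SO2 (water and background off)
  m1 <- model_mua(lib, fb = 0.02, SO2 = 0.6, A = 0, B = 0, fw = 0)
  m2 <- model_mua(lib, fb = 0.04, SO2 = 0.6, A = 0, B = 0, fw = 0)
  expect_equal(2 * m1, m2)
})

test_that("the dry-background term is the stated exponential", {
  lib <- chromophore_library(500)
  m <- model_mua(lib, fb = 0, SO2 = 0, A = 7, B = 0.004, fw = 0)
  expect_equal(m, 7 * exp(-2))
})

test_that("parameters outside their physical bounds are rejected", {
  lib <- ref_lib()
  expect_error(model_mua(lib, fb = -0.1, SO2 = 0.5, A = 1, B = 0.004), "fb")
  expect_error(model_mua(lib, fb = 0.1, SO2 = 1.5, A = 1, B = 0.004), "SO2")
  expect_error(model_mua(lib, fb = 0.1, SO2 = 0.5, A = -1, B = 0.004), "A")
  expect_error(correct_saturation(664, 0.37, list(fb = 0.04, SO2 = 0.6), 1.2),
               "so2_target")
})

test_that("noiseless model spectra are recovered to optimizer precision", {
  lib <- ref_lib()
  truth <- list(fb = 0.039, SO2 = 0.65, A = 7, B = 0.004)
  y <- model_mua(lib, fb = truth$fb, SO2 = truth$SO2, A = truth$A,
                 B = truth$B)
  fit <- fit_mua(lib$wavelength, y, library = lib)
  expect_lt(abs(fit$fb - truth$fb) / truth$fb, 0.01)
  expect_lt(abs(fit$SO2 - truth$SO2) / truth$SO2, 0.01)
  expect_lt(abs(fit$A - truth$A) / truth$A, 0.01)
  expect_lt(abs(fit$B - truth$B) / truth$B, 0.01)
  expect_true(fit$so2_identifiable)
})

test_that("saturation is flagged unidentifiable when there is no blood", {
  lib <- ref_lib()
  y <- model_mua(lib, fb = 0, SO2 = 0.5, A = 5, B = 0.004)
  fit <- fit_mua(lib$wavelength, y, library = lib)
  expect_lt(fit$fb, 1e-4)
  expect_false(fit$so2_identifiable)
})

test_that("degenerate spectra and short grids are rejected", {
  expect_error(fit_mua(lambda_vis, rep(0, length(lambda_vis))), "degenerate")
  expect_error(fit_mua(c(500, 600, 700), c(1, 1, 1)), "at least 20")
})

test_that("saturation correction is an exact shift and involution", {
  lib <- ref_lib()
  truth <- list(fb = 0.039, SO2 = 0.65)
  y <- model_mua(lib, fb = truth$fb, SO2 = truth$SO2, A = 5, B = 0.004)
  # identity when the target equals the fitted saturation
  expect_equal(correct_saturation(lib$wavelength, y, truth, 0.65, lib), y)
  # there and back again restores the original to machine precision
  up <- correct_saturation(lib$wavelength, y, truth, 0.97, lib)
  back <- correct_saturation(lib$wavelength, up,
                             list(fb = truth$fb, SO2 = 0.97), 0.65, lib)
  expect_equal(back, y, tolerance = 1e-12)
  # shifting to full oxygenation reproduces the model at SO2 = 1
  expect_equal(correct_saturation(lib$wavelength, y, truth, 1, lib),
               model_mua(lib, fb = truth$fb, SO2 = 1, A = 5, B = 0.004))
  # raising SO2 lowers absorption near 664 nm (deoxy > oxy there)
  i <- which.min(abs(lib$wavelength - 664))
  expect_lt(up[i], y[i])
})

test_that("saturation drift recovers a linear decline and handles guards", {
  spec <- tissue_generator_spec("normal", fb = 0.039, SO2 = 0.70, A = 5,
                                B = 0.004, scatter_a = 3, scatter_b = 0.7,
                                n_samples = 4)
  ser <- generate_drift_series(spec, decline_per_step = 0.08, n_steps = 3,
                               wavelength = lambda_vis, seed = 2)
  dr <- saturation_drift(ser$series)
  expect_equal(dr$mean[1], 0)
  expect_equal(dr$mean[2], -0.08, tolerance = 0.015)
  expect_equal(dr$mean[3], -0.16, tolerance = 0.02)
  # identical spectra at all times: zero drift
  sp1 <- ser$series[[1]][[1]]
  same <- list(list(sp1, sp1, sp1))
  expect_equal(saturation_drift(same)$delta, matrix(0, 1, 3),
               ignore_attr = TRUE)
  # single time point violates the precondition
  expect_error(saturation_drift(list(list(sp1))), "2 time points")
})
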