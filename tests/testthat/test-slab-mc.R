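test_that("identical seed and packet count give bit-identical results", {
  s <- layered_sample(0.7, mua = 0.1, mus = 10, g = 0.9)
  a <- simulate_slab(s, n_packets = 1e4, seed = 5)
  b <- simulate_slab(s, n_packets = 1e4, seed = 5)
  d <- simulate_slab(s, n_packets = 1e4, seed = 6)
  expect_identical(a$Rd, b$Rd)
  expect_identical(a$Tt, b$Tt)
  expect_false(identical(a$Rd, d$Rd))
})

test_that("packet-weight bookkeeping closes exactly", {
  for (mua in c(0.05, 0.5)) {
    r <- simulate_slab(layered_sample(0.7, mua = mua, mus = 15, g = 0.9),
                       n_packets = 2e4, seed = 3)
    expect_lt(abs(r$balance), 1e-9)
  }
})

test_that("a non-absorbing slab returns all light", {
  r <- simulate_slab(layered_sample(1, mua = 0, mus = 10, g = 0.9,
                                    glass = FALSE, n = 1.0),
                     n_packets = 2e4, seed = 11)
  expect_equal(r$Rd + r$Tt, 1, tolerance = 1e-12)
})

test_that("transmittance follows Beer-Lambert without scattering", {
  for (case in list(c(0.5, 0.5), c(1, 0.7), c(3, 0.7))) {
    mua <- case[1]
    d <- case[2]
    r <- simulate_slab(layered_sample(d, mua = mua, mus = 0, g = 0, n = 1,
                                      glass = FALSE),
                       n_packets = 5e4, seed = 13)
    expect_lt(abs(r$Tt - exp(-mua * d)),
              3 * r$mc_stderr[["Tt"]] + 1e-4)
    expect_lt(r$Rd, 1e-12)
  }
})

test_that("absorption monotonically trades transmittance for deposition", {
  res <- lapply(c(0.1, 0.4, 1.2), function(mua) {
    simulate_slab(layered_sample(0.7, mua = mua, mus = 10, g = 0.9),
                  n_packets = 5e4, seed = 17)
  })
  tts <- vapply(res, `[[`, numeric(1), "Tt")
  abs_ <- vapply(res, `[[`, numeric(1), "absorbed_fraction")
  expect_true(all(diff(tts) < 0))
  expect_true(all(diff(abs_) > 0))
})

test_that("standard error shrinks like 1/sqrt(n_packets)", {
  s <- layered_sample(0.7, mua = 0.1, mus = 10, g = 0.9)
  se1 <- simulate_slab(s, n_packets = 1e4, seed = 19)$mc_stderr[["Rd"]]
  se2 <- simulate_slab(s, n_packets = 4e4, seed = 19)$mc_stderr[["Rd"]]
  expect_equal(se1 / se2, 2, tolerance = 0.3)
})

test_that("reduced scattering is converted exactly", {
  s <- layered_sample(0.7, mua = 0.1, musp = 2.71, g = 0.9)
  expect_equal(s$mus, 27.1)
  expect_error(layered_sample(0.7, mua = 0.1, mus = 1, musp = 1), "exactly one")
  expect_error(layered_sample(0.7, mua = -1, mus = 1), "mua")
  expect_error(layered_sample(0, mua = 0.1, mus = 1), "thickness")
})

test_that("glass-mounted slab matches the independent analog oracle", {
  # frozen values from an independent analog (unweighted) Monte Carlo
  # implementation with a different RNG (scratch oracle, 4e6 photons);
  # that implementation reproduces the published semi-infinite anchor
  # below to 0.2 percent
  r <- simulate_slab(layered_sample(0.7, mua = 0.1, mus = 10, g = 0.9,
                                    n = 1.38, glass = TRUE, n_glass = 1.52),
                     n_packets = 2e5, seed = 23)
  expect_equal(r$Rd, 0.21029, tolerance = 0.01)
  expect_equal(r$Tt, 0.55158, tolerance = 0.01)
  expect_equal(r$absorbed_fraction, 0.19342, tolerance = 0.015)
  expect_equal(r$specular, 0.04471, tolerance = 0.001)
})

test_that("semi-infinite mismatched medium reproduces the published anchor", {
  # total reflectance 0.2600 for albedo 0.9, isotropic scattering,
  # relative refractive index 1.5 (classic radiative-transfer benchmark)
  r <- simulate_slab(layered_sample(30, mua = 1, mus = 9, g = 0, n = 1.5,
                                    glass = FALSE),
                     n_packets = 2e5, seed = 29, include_specular = TRUE)
  expect_equal(r$Rd, 0.2600, tolerance = 0.01)
  expect_lt(r$Tt, 1e-10)
})
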