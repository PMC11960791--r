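make_group <- function(n, wl = c(500, 600, 700), mua_mean = 0.4,
                       musp_mean = 2.5, sdev = 0.05, seed = 1,
                       type = "normal") {
  set.seed(seed)
  mua <- matrix(rnorm(length(wl) * n, mua_mean, sdev), length(wl), n)
  musp <- matrix(rnorm(length(wl) * n, musp_mean, sdev), length(wl), n)
  spectrum_group(wl, mua, musp, tissue_type = type)
}

test_that("identical groups give p = 1 everywhere", {
  g <- make_group(5)
  p <- compare_groups(g, g)
  expect_true(all(p$p_mua == 1))
  expect_true(all(p$p_musp == 1))
  expect_false(any(p$sig_mua))
})

test_that("p-values are invariant under group-label exchange", {
  a <- make_group(6, seed = 2)
  b <- make_group(8, seed = 3, mua_mean = 0.5)
  expect_equal(compare_groups(a, b)$p_mua, compare_groups(b, a)$p_mua)
})

test_that("the per-wavelength test matches stats::t.test directly", {
  a <- make_group(6, seed = 4)
  b <- make_group(9, seed = 5, mua_mean = 0.45)
  p <- compare_groups(a, b)
  i <- 2
  expect_equal(p$p_mua[i],
               t.test(a$mua[i, ], b$mua[i, ], var.equal = TRUE)$p.value)
})

test_that("grid mismatch and undersized groups are rejected", {
  a <- make_group(4)
  b <- make_group(4, wl = c(500, 600, 720))
  expect_error(compare_groups(a, b), "grid")
  one <- spectrum_group(c(500, 600, 700), matrix(1, 3, 1), matrix(2, 3, 1))
  expect_error(compare_groups(a, one), "n >= 2")
})

test_that("an absorption offset above 600 nm is localised by the masks", {
  wl <- seq(450, 800, by = 25)
  set.seed(6)
  n1 <- 12
  n2 <- 12
  base <- matrix(rnorm(length(wl) * n1, 0.4, 0.04), length(wl), n1)
  off <- matrix(rnorm(length(wl) * n2, 0.4, 0.04), length(wl), n2) +
    0.4 * (wl > 600)
  musp1 <- matrix(rnorm(length(wl) * n1, 2.2, 0.2), length(wl), n1)
  musp2 <- matrix(rnorm(length(wl) * n2, 2.2, 0.2), length(wl), n2)
  normal <- spectrum_group(wl, base, musp1, "normal")
  carbon <- spectrum_group(wl, off, musp2, "carbon")
  p <- compare_groups(normal, carbon)
  expect_true(all(p$sig_mua[p$wavelength > 600]))
  expect_true(mean(p$sig_mua[p$wavelength <= 600]) < 0.2)
})

test_that("summary table reproduces closed-form mean and sd", {
  wl <- c(630, 635, 664, 690)
  mua <- cbind(c(0.5, 0.5, 0.3, 0.5), c(0.7, 0.7, 0.5, 0.7))
  musp <- cbind(rep(2, 4), rep(3, 4))
  g <- spectrum_group(wl, mua, musp, "normal")
  s <- summarize_groups(list(normal = g))
  r664 <- s[s$wavelength == 664, ]
  expect_equal(r664$mua_mean, 0.4)
  expect_equal(r664$mua_sd, sd(c(0.3, 0.5)))
  expect_equal(r664$mua_sd, 0.1414214, tolerance = 1e-6)
  expect_equal(r664$musp_mean, 2.5)
  # identical spectra give zero sd
  g0 <- spectrum_group(wl, cbind(mua[, 1], mua[, 1]), musp, "x")
  expect_true(all(summarize_groups(list(x = g0))$mua_sd == 0))
})

test_that("off-grid report wavelengths snap with a warning", {
  g <- make_group(3, wl = c(500, 600, 700))
  expect_warning(s <- summarize_groups(list(g = g), wavelengths = 664),
                 "snapped")
  expect_equal(s$wavelength, 700)
})

test_that("cv_report returns sd/mean at the reference wavelength", {
  g <- make_group(50, wl = c(600, 664), mua_mean = 0.4, sdev = 0.08,
                  seed = 9)
  cv <- cv_report(g)
  expect_equal(cv[["cv_mua"]],
               sd(g$mua[2, ]) / mean(g$mua[2, ]))
})
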