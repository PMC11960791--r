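test_that("side-firing launch positions and directions match the probe model", {
  src <- cylindrical_source(center = c(15, 15, 15))
  s <- launch_source(src, 1e4, seed = 3)
  rad <- sqrt((s[, "x"] - 15)^2 + (s[, "y"] - 15)^2)
  # all launch positions on the 0.5 mm outer radius (up to the tiny nudge)
  expect_true(all(abs(rad - 0.5) < 1e-6))
  # axial coordinate uniform over the 11 mm emission window
  z <- s[, "z"] - 15
  expect_true(all(abs(z) <= 5.5))
  ks <- suppressWarnings(ks.test(z, "punif", -5.5, 5.5))
  expect_gt(ks$p.value, 0.01)
  # emission is outward: positive radial direction component everywhere
  rdir <- ((s[, "x"] - 15) * s[, "ux"] + (s[, "y"] - 15) * s[, "uy"]) / rad
  expect_true(all(rdir > 0))
  # symmetry: no net axial or transverse direction
  expect_lt(abs(mean(s[, "uz"])), 0.02)
  expect_lt(abs(mean(s[, "ux"])), 0.02)
  expect_lt(abs(mean(s[, "uy"])), 0.02)
  # unit directions
  expect_equal(rowSums(s[, 4:6]^2), rep(1, nrow(s)), tolerance = 1e-9)
})

test_that("transport conserves energy and closes its weight bookkeeping", {
  ph <- build_phantom(domain_mm = 30, voxel_mm = 0.5)
  ph <- assign_properties(ph, "human")
  src <- cylindrical_source(center = ph$center) # 150 mW x 667 s = 100.05 J
  df <- run_transport(ph, src, n_packets = 1e5, seed = 5)
  expect_lt(abs(df$balance), 1e-9)
  expect_equal(df$delivered_J, 100.05)
  expect_lt(abs(df$deposited_J + df$escaped_J - 100.05),
            5 * (df$se_deposited_J + df$se_escaped_J))
  expect_true(all(df$fluence >= 0))
})

test_that("energy deposition equals mua times fluence voxel-wise", {
  ph <- build_phantom(domain_mm = 12, voxel_mm = 0.3, tumor_diam_mm = 6)
  ph <- assign_properties(ph, "human")
  df <- run_transport(ph, cylindrical_source(center = ph$center,
                                             emission_length_mm = 5),
                      n_packets = 2e4, seed = 7)
  mua_vox <- ph$prop_map$mua[as.integer(ph$labels) + 1L]
  expect_equal(as.numeric(df$energy),
               mua_vox * as.numeric(df$fluence) * 10, tolerance = 1e-12)
})

test_that("fields scale exactly linearly with delivered power", {
  ph <- homogeneous_phantom(domain = 10, h = 0.5, mua = 0.1, musp = 1)
  s1 <- point_source(c(5, 5, 5), power_W = 1)
  s2 <- point_source(c(5, 5, 5), power_W = 2)
  f1 <- run_transport(ph, s1, n_packets = 1e4, seed = 9)
  f2 <- run_transport(ph, s2, n_packets = 1e4, seed = 9)
  expect_equal(2 * as.numeric(f1$fluence), as.numeric(f2$fluence),
               tolerance = 1e-12)
})

test_that("fluence is statistically mirror-symmetric about the source plane", {
  ph <- build_phantom(domain_mm = 21, voxel_mm = 0.3)
  ph <- assign_properties(ph, "human")
  df <- run_transport(ph, cylindrical_source(center = ph$center),
                      n_packets = 2e5, seed = 11)
  n <- dim(df$fluence)[3]
  lo <- sum(df$fluence[, , 1:(n / 2)])
  hi <- sum(df$fluence[, , (n / 2 + 1):n])
  expect_lt(abs(lo - hi) / (lo + hi), 0.01)
  # and about the bronchus axis in x
  lo_x <- sum(df$fluence[1:(n / 2), , ])
  hi_x <- sum(df$fluence[(n / 2 + 1):n, , ])
  expect_lt(abs(lo_x - hi_x) / (lo_x + hi_x), 0.01)
})

test_that("on-axis fluence of a pencil beam decays as Beer-Lambert", {
  mua <- 0.5
  h <- 0.25
  ph <- homogeneous_phantom(domain = 15, h = h, mua = mua, musp = 0, g = 0)
  src <- pencil_source(c(7.5 + h / 2, 7.5 + h / 2, 1e-4))
  df <- run_transport(ph, src, n_packets = 5e4, seed = 13)
  ic <- as.integer(7.5 / h) + 1L
  prof <- df$fluence[ic, ic, ]
  zc <- (seq_len(dim(df$fluence)[3]) - 0.5) * h
  sel <- 3:30
  slope <- coef(lm(log(prof[sel]) ~ zc[sel]))[[2]]
  expect_equal(-slope, mua, tolerance = 0.02)
})

test_that("identical seeds reproduce fields bit-for-bit", {
  ph <- homogeneous_phantom(domain = 8, h = 0.5, mua = 0.1, musp = 1)
  a <- run_transport(ph, point_source(c(4, 4, 4)), n_packets = 1e4, seed = 21)
  b <- run_transport(ph, point_source(c(4, 4, 4)), n_packets = 1e4, seed = 21)
  expect_identical(a$fluence, b$fluence)
})

test_that("invalid transport setups are rejected before sampling", {
  ph <- build_phantom(domain_mm = 8, voxel_mm = 0.5, tumor_diam_mm = 4)
  expect_error(run_transport(ph, point_source(c(4, 4, 4)), 1e4, seed = 1),
               "properties")
  ph <- assign_properties(ph, "human")
  expect_error(run_transport(ph, cylindrical_source(center = c(4, 4, 4)),
                             1e4, seed = 1),
               "outside")
  expect_error(run_transport(ph, point_source(c(4, 4, 4)), 1e3, seed = 1),
               "n_packets")
})
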