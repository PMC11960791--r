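test_that("tumor voxel count matches the analytic sphere at default resolution", {
  ph <- build_phantom() # 30 mm cube, 0.05 mm voxels, 10 mm tumor, 1 mm bronchus
  counts <- label_counts(ph)
  # analytic: sphere minus the coaxial bronchus core; the cylinder-sphere
  # intersection is (4 pi / 3) (rt^3 - (rt^2 - rb^2)^{3/2}), so the tumor
  # volume reduces to (4 pi / 3) (rt^2 - rb^2)^{3/2}
  h <- 0.05
  rt <- 5
  rb <- 0.5
  expected <- (4 * pi / 3) * (rt^2 - rb^2)^1.5 / h^3
  expect_lt(abs(counts[["tumor"]] - expected) / expected, 0.01)
  rm(ph)
  gc(verbose = FALSE)
})

test_that("labels are mirror-symmetric and obey precedence air > tumor", {
  ph <- build_phantom(domain_mm = 12, voxel_mm = 0.3, tumor_diam_mm = 8,
                      bronchus_diam_mm = 2)
  lab <- array(as.integer(ph$labels), dim = ph$dims)
  n <- ph$dims[1]
  expect_identical(lab, lab[n:1, , ])
  expect_identical(lab, lab[, n:1, ])
  expect_identical(lab, lab[, , n:1])
  # the bronchus column through the tumor center stays air
  mid <- n / 2
  expect_true(all(lab[mid, mid, ] == 2))
  # bronchus traverses the whole domain
  expect_true(all(lab[mid, mid, c(1, n)] == 2))
})

test_that("degenerate geometries behave as specified", {
  ph <- build_phantom(domain_mm = 6, voxel_mm = 0.3, tumor_diam_mm = 0,
                      bronchus_diam_mm = 0)
  expect_equal(unname(label_counts(ph)[c("tumor", "air")]), c(0, 0))
  expect_error(build_phantom(domain_mm = 10, voxel_mm = 0.3), "divide")
  expect_error(build_phantom(domain_mm = 10, voxel_mm = 0.5,
                             tumor_diam_mm = 20), "fit")
})

test_that("tumor volume estimate is resolution-convergent", {
  vol <- vapply(c(0.1, 0.05), function(h) {
    ph <- build_phantom(domain_mm = 16, voxel_mm = h, tumor_diam_mm = 10,
                        bronchus_diam_mm = 1)
    (label_counts(ph)[["tumor"]]) * h^3
  }, numeric(1))
  expect_lt(abs(vol[2] - vol[1]) / vol[2], 0.005)
})

test_that("property assignment fills the map without touching labels", {
  ph <- build_phantom(domain_mm = 6, voxel_mm = 0.3, tumor_diam_mm = 4,
                      bronchus_diam_mm = 1)
  before <- ph$labels
  ph2 <- assign_properties(ph, "human")
  expect_identical(ph2$labels, before)
  pm <- ph2$prop_map
  expect_equal(pm$mua, c(0.37, 0.27, 1e-5))
  expect_equal(pm$musp, c(2.71, 1.99, 0.1))
  # mus = musp / (1 - g) applied exactly for g < 1; air keeps its value
  expect_equal(pm$mus[1:2], c(2.71, 1.99) / 0.1)
  expect_equal(pm$mus[3], 0.1)
})

test_that("scenario property tables encode the study conditions", {
  carbon <- scenario_properties("human_carbon")
  expect_equal(carbon$mua[1:2], c(0.83, 0.27))
  expect_equal(carbon$musp[1:2], c(1.97, 1.99))
  porcine <- scenario_properties("porcine")
  # porcine tumor assumed optically identical to normal tissue
  expect_equal(porcine$mua[1], porcine$mua[2])
  expect_equal(porcine$mua[1], 0.26)
  expect_equal(porcine$musp[1], porcine$musp[2])
  corr <- scenario_properties("human_SO2_97")
  # saturation correction lowers absorption, leaves scattering untouched
  expect_lt(corr$mua[1], 0.37)
  expect_lt(corr$mua[2], 0.27)
  expect_equal(corr$musp[1:2], c(2.71, 1.99))
  # air compartment constants
  human <- scenario_properties("human")
  expect_equal(human$mua[3], 1e-5)
  expect_equal(human$g[3], 1.0)
  expect_equal(human$n[3], 1.0)
})

test_that("missing properties for a populated label are rejected", {
  ph <- build_phantom(domain_mm = 6, voxel_mm = 0.3, tumor_diam_mm = 4,
                      bronchus_diam_mm = 1)
  expect_error(
    assign_properties(ph, data.frame(label = 0:1, mua = 0.3, musp = 2,
                                     g = 0.9, n = 1.38)),
    "label")
})
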