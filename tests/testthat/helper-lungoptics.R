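# Shared fixtures: small wavelength grids and a cached reference library.

lambda_vis <- seq(450, 800, by = 5)

ref_lib <- local({
  cache <- new.env(parent = emptyenv())
  function(wl = lambda_vis) {
    key <- paste0("g", paste(range(wl), collapse = "_"), length(wl))
    if (is.null(cache[[key]])) cache[[key]] <- chromophore_library(wl)
    cache[[key]]
  }
})

# homogeneous cube phantom with uniform properties (no tumor, no bronchus)
homogeneous_phantom <- function(domain = 20, h = 0.5, mua = 0.02, musp = 2,
                                g = 0.9, n = 1.0) {
  ph <- build_phantom(domain_mm = domain, voxel_mm = h, tumor_diam_mm = 0,
                      bronchus_diam_mm = 0)
  assign_properties(ph, data.frame(label = 0:2, mua = mua, musp = musp,
                                   g = g, n = n))
}

# strict interior local maxima of y, returned as x positions
local_maxima <- function(x, y) {
  i <- which(diff(sign(diff(y))) == -2) + 1
  x[i]
}
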