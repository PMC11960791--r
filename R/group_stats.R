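# Per-wavelength two-group comparison of optical-property spectra and
# summary tables, following standard ex vivo reporting practice: classical
# equal-variance unpaired two-tailed t-tests per wavelength with raw
# p-values plotted against wavelength (no multiplicity adjustment), and
# mean +/- sample standard deviation summaries at PDT wavelengths.

#' Bundle sample spectra into a group
#'
#' @param wavelength Shared wavelength grid (nm).
#' @param mua Matrix of absorption coefficients, wavelengths x samples
#'   (mm^-1).
#' @param musp Matrix of reduced scattering coefficients, wavelengths x
#'   samples (mm^-1).
#' @param tissue_type Label, e.g. `"normal"`, `"carbon"`, `"tumor"`.
#' @param truth Optional per-sample generator truth (kept for recovery
#'   tests).
#' @return Object of class `spectrum_group`.
#' @export
spectrum_group <- function(wavelength, mua, musp, tissue_type = "unknown",
                           truth = NULL) {
  mua <- as.matrix(mua)
  musp <- as.matrix(musp)
  stopifnot(nrow(mua) == length(wavelength),
            identical(dim(mua), dim(musp)))
  structure(
    list(wavelength = as.numeric(wavelength), mua = mua, musp = musp,
         tissue_type = tissue_type, n = ncol(mua), truth = truth),
    class = "spectrum_group")
}

#' @export
print.spectrum_group <- function(x, ...) {
  cat(sprintf("<spectrum_group> %s: %d samples, %d wavelengths (%g-%g nm)\n",
              x$tissue_type, x$n, length(x$wavelength), min(x$wavelength),
              max(x$wavelength)))
  invisible(x)
}

#' Per-wavelength two-group comparison of optical properties
#'
#' Classical (equal-variance) Student unpaired two-tailed t-test of mua and
#' musp at every wavelength of the shared grid. Raw p-values are returned
#' without multiple-testing adjustment - the intended use is a p-value
#' versus wavelength plot read against the significance level - so masks of
#' "significant" wavelengths should be interpreted accordingly.
#'
#' @param a,b `spectrum_group` objects on an identical wavelength grid,
#'   each with at least 2 samples.
#' @param alpha Significance level for the masks (default 0.01).
#' @return Object of class `p_value_spectrum`: data frame with columns
#'   `wavelength`, `p_mua`, `p_musp`, `sig_mua`, `sig_musp`; attribute
#'   `alpha`.
#' @export
compare_groups <- function(a, b, alpha = 0.01) {
  stopifnot(inherits(a, "spectrum_group"), inherits(b, "spectrum_group"))
  if (!isTRUE(all.equal(a$wavelength, b$wavelength)))
    stop("wavelength grids differ between groups")
  if (a$n < 2 || b$n < 2) stop("both groups need n >= 2")
  pw <- function(ma, mb) {
    vapply(seq_along(a$wavelength), function(i) {
      xa <- ma[i, ]
      xb <- mb[i, ]
      if (sd(xa) == 0 && sd(xb) == 0) return(1)
      t.test(xa, xb, var.equal = TRUE)$p.value
    }, numeric(1))
  }
  p_mua <- pw(a$mua, b$mua)
  p_musp <- pw(a$musp, b$musp)
  out <- data.frame(wavelength = a$wavelength, p_mua = p_mua,
                    p_musp = p_musp, sig_mua = p_mua < alpha,
                    sig_musp = p_musp < alpha)
  attr(out, "alpha") <- alpha
  class(out) <- c("p_value_spectrum", "data.frame")
  out
}

#' Summary table of optical properties at selected wavelengths
#'
#' Mean and sample standard deviation (n - 1 denominator) of mua and musp
#' per group at the requested wavelengths; wavelengths not on the grid are
#' snapped to the nearest grid point with a warning.
#'
#' @param groups Named list of `spectrum_group` objects.
#' @param wavelengths Wavelengths to report (nm); defaults to the
#'   PDT-relevant 630, 635, 664 and 690 nm.
#' @return Data frame with columns `tissue`, `wavelength`, `mua_mean`,
#'   `mua_sd`, `musp_mean`, `musp_sd`, `n`.
#' @export
summarize_groups <- function(groups, wavelengths = c(630, 635, 664, 690)) {
  stopifnot(length(groups) > 0)
  rows <- list()
  for (gname in names(groups)) {
    g <- groups[[gname]]
    stopifnot(inherits(g, "spectrum_group"))
    if (g$n < 1) stop("empty group: ", gname)
    for (wl in wavelengths) {
      i <- which.min(abs(g$wavelength - wl))
      if (abs(g$wavelength[i] - wl) > 1e-9)
        warning(sprintf("wavelength %g nm snapped to %g nm", wl,
                        g$wavelength[i]))
      rows[[length(rows) + 1]] <- data.frame(
        tissue = if (is.null(gname) || gname == "") g$tissue_type else gname,
        wavelength = g$wavelength[i],
        mua_mean = mean(g$mua[i, ]), mua_sd = sd(g$mua[i, ]),
        musp_mean = mean(g$musp[i, ]), musp_sd = sd(g$musp[i, ]),
        n = g$n)
    }
  }
  do.call(rbind, rows)
}

#' Coefficient-of-variation report for a group
#'
#' Inter-sample variation (sd/mean) of mua and musp, reported at a
#' reference wavelength (default 664 nm, the treatment wavelength).
#'
#' @param group A `spectrum_group`.
#' @param wavelength Reference wavelength (nm), snapped to the grid.
#' @return Named numeric vector `c(cv_mua, cv_musp)`.
#' @export
cv_report <- function(group, wavelength = 664) {
  stopifnot(inherits(group, "spectrum_group"))
  i <- which.min(abs(group$wavelength - wavelength))
  c(cv_mua = sd(group$mua[i, ]) / mean(group$mua[i, ]),
    cv_musp = sd(group$musp[i, ]) / mean(group$musp[i, ]))
}
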