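# Reduction of dose fields to region-restricted summaries: cumulative
# volume histograms (the PDT analogue of dose-volume histograms) and
# threshold-coverage fractions.

#' Logical mask of a phantom region
#'
#' @param x A `voxel_phantom` or `dose_fields` object (both carry labels).
#' @param region `"surrounding"`, `"tumor"` or `"air"`.
#' @return Logical array over the voxel grid.
#' @export
region_mask <- function(x, region = c("tumor", "surrounding", "air")) {
  region <- match.arg(region)
  labs <- if (inherits(x, "voxel_phantom")) x$labels else x$labels
  m <- as.integer(labs) == PHANTOM_LABELS[[region]]
  dim(m) <- dim(labs)
  m
}

#' Cumulative volume histogram of a dose field
#'
#' For each threshold, the fraction of the region's voxels whose dose is at
#' least that threshold (closed comparison, `dose >= t`). The curve is
#' non-increasing in the threshold, equals 1 at threshold 0 and lies in
#' `[0, 1]` throughout.
#'
#' @param field 3D dose array (fluence in J/cm^2 or energy deposition in
#'   J/cm^3).
#' @param mask Logical array selecting the region (non-empty).
#' @param thresholds Ascending dose thresholds. Defaults to log-spaced
#'   values covering the 0.1-100 decades used for dose contours.
#' @return Object of class `cvh`: data frame with columns `threshold` and
#'   `volume_fraction`.
#' @examples
#' f <- array(1, c(4, 4, 4))
#' cvh(f, array(TRUE, dim(f)), thresholds = c(0.5, 1, 2))
#' @export
cvh <- function(field, mask, thresholds = 10^seq(-1, 2, by = 0.25)) {
  stopifnot(identical(dim(field), dim(mask)))
  if (!any(mask)) stop("empty region mask")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly ascending")
  dose <- field[mask]
  n <- length(dose)
  vf <- vapply(thresholds, function(t) sum(dose >= t) / n, numeric(1))
  structure(data.frame(threshold = thresholds, volume_fraction = vf),
            class = c("cvh", "data.frame"))
}

#' Fraction of a region covered by at least a threshold dose
#'
#' @inheritParams cvh
#' @param threshold Single dose threshold.
#' @return Fraction in `[0, 1]`.
#' @examples
#' f <- array(seq_len(8), c(2, 2, 2))
#' coverage(f, array(TRUE, dim(f)), threshold = 5)
#' @export
coverage <- function(field, mask, threshold) {
  stopifnot(identical(dim(field), dim(mask)), length(threshold) == 1)
  if (!any(mask)) stop("empty region mask")
  sum(field[mask] >= threshold) / sum(mask)
}
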