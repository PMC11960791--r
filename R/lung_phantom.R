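# 3D voxel model of peripheral lung tissue: homogeneous surrounding tissue
# (label 0), a spherical tumor (label 1) centered on a 1-mm air-filled
# bronchus (label 2) that traverses the whole domain along z. Coordinates
# are cell-centered with the origin at the domain corner; the default
# domain is a 30 mm cube at 0.05 mm isotropic voxels.

PHANTOM_LABELS <- c(surrounding = 0L, tumor = 1L, air = 2L)

#' Build the voxelized lung phantom
#'
#' Voxelizes a cube of surrounding tissue containing a spherical tumor
#' centered on an axis-aligned cylindrical bronchus (along z, through the
#' domain center). Labels are assigned by a center-in-shape test with
#' precedence air > tumor > surrounding.
#'
#' @param domain_mm Edge length of the cubic domain (mm).
#' @param voxel_mm Isotropic voxel size (mm); must divide `domain_mm`.
#' @param tumor_diam_mm Tumor diameter (mm); 0 for no tumor.
#' @param bronchus_diam_mm Bronchus diameter (mm); 0 for no bronchus.
#' @return Object of class `voxel_phantom`: list with `labels` (raw 3D
#'   array, values 0/1/2), `dims`, `voxel_mm`, `origin` (mm, domain corner),
#'   `center` (mm) and `prop_map` (NULL until [assign_properties()]).
#' @examples
#' ph <- build_phantom(domain_mm = 10, voxel_mm = 0.5, tumor_diam_mm = 6,
#'                     bronchus_diam_mm = 1)
#' table(as.integer(ph$labels))
#' @export
build_phantom <- function(domain_mm = 30, voxel_mm = 0.05,
                          tumor_diam_mm = 10, bronchus_diam_mm = 1) {
  nvox <- domain_mm / voxel_mm
  if (abs(nvox - round(nvox)) > 1e-9)
    stop("voxel_mm must divide domain_mm")
  nvox <- as.integer(round(nvox))
  if (tumor_diam_mm < 0 || bronchus_diam_mm < 0)
    stop("diameters must be >= 0")
  if (tumor_diam_mm > domain_mm)
    stop("tumor does not fit inside the domain")
  center <- rep(domain_mm / 2, 3)
  labels <- build_phantom_cpp(rep(nvox, 3L), voxel_mm, c(0, 0, 0), center,
                              tumor_diam_mm / 2, bronchus_diam_mm / 2)
  dim(labels) <- rep(nvox, 3L)
  structure(
    list(labels = labels, dims = rep(nvox, 3L), voxel_mm = voxel_mm,
         origin = c(0, 0, 0), center = center, prop_map = NULL),
    class = "voxel_phantom")
}

#' Count voxels per tissue label
#'
#' @param phantom A [build_phantom()] result.
#' @return Named numeric vector of voxel counts (surrounding, tumor, air).
#' @export
label_counts <- function(phantom) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  n <- count_labels_cpp(phantom$labels, 3L)
  names(n) <- names(PHANTOM_LABELS)
  n
}

#' Optical properties of the simulation scenarios at 664 nm
#'
#' Returns the per-tissue absorption and reduced scattering coefficients
#' (mm^-1) used by the light-transport scenarios, at the talaporfin
#' activation wavelength of 664 nm:
#' \describe{
#'   \item{human}{surrounding = measured mean normal tissue, tumor =
#'     measured mean tumor tissue.}
#'   \item{human_carbon}{surrounding = carbon-deposited tissue, tumor
#'     unchanged.}
#'   \item{human_SO2_97}{both tissues with the hemoglobin component shifted
#'     to 97 percent saturation via [correct_saturation()] from the mean
#'     fitted blood volume fraction and saturation (computed at call time,
#'     not hard-coded).}
#'   \item{porcine}{surrounding = measured mean porcine normal tissue;
#'     tumor optical properties assumed identical to normal tissue.}
#' }
#' The air/bronchus compartment always uses mua = 1e-5 mm^-1, musp = 0.1
#' mm^-1, g = 1 (forward delta) and n = 1.
#'
#' @param scenario One of `"human"`, `"human_carbon"`, `"human_SO2_97"`,
#'   `"porcine"`.
#' @param g,n Anisotropy and refractive index assigned to both tissues.
#' @return Data frame with one row per label: `label`, `tissue`, `mua`,
#'   `musp`, `g`, `n`.
#' @export
scenario_properties <- function(scenario = c("human", "human_carbon",
                                             "human_SO2_97", "porcine"),
                                g = 0.9, n = 1.38) {
  scenario <- match.arg(scenario)
  # measured mean (mua, musp) at 664 nm per tissue type
  normal <- c(mua = 0.37, musp = 2.71)
  carbon <- c(mua = 0.83, musp = 1.97)
  tumor <- c(mua = 0.27, musp = 1.99)
  porcine <- c(mua = 0.26, musp = 2.60)
  # mean chromophore-fit parameters per tissue type
  fit_normal <- list(fb = 0.039, SO2 = 0.65)
  fit_tumor <- list(fb = 0.020, SO2 = 0.46)

  if (scenario == "human") {
    surr <- normal; tum <- tumor
  } else if (scenario == "human_carbon") {
    surr <- carbon; tum <- tumor
  } else if (scenario == "human_SO2_97") {
    lib <- chromophore_library(664)
    surr <- c(mua = correct_saturation(664, normal[["mua"]], fit_normal,
                                       0.97, lib),
              musp = normal[["musp"]])
    tum <- c(mua = correct_saturation(664, tumor[["mua"]], fit_tumor,
                                      0.97, lib),
             musp = tumor[["musp"]])
  } else {
    surr <- porcine; tum <- porcine
  }

  data.frame(
    label = unname(PHANTOM_LABELS),
    tissue = names(PHANTOM_LABELS),
    mua = c(surr[["mua"]], tum[["mua"]], 1e-5),
    musp = c(surr[["musp"]], tum[["musp"]], 0.1),
    g = c(g, g, 1.0),
    n = c(n, n, 1.0))
}

#' Assign optical properties to a phantom
#'
#' Fills the label-to-properties map of a phantom, either from a scenario
#' name (see [scenario_properties()]) or from an explicit data frame with
#' columns `label`, `mua`, `musp` (or `mus`), `g`, `n`. The scattering
#' coefficient is derived as `mus = musp / (1 - g)` for `g < 1`; for the
#' forward-delta air convention (`g = 1`) the tabulated `musp` value is
#' used as `mus` unchanged (a forward delta has no transport effect, so any
#' finite value is equivalent). Labels are never mutated.
#'
#' @param phantom A [build_phantom()] result.
#' @param props Scenario name or data frame.
#' @return The phantom with `prop_map` set (data frame with columns `label`,
#'   `mua`, `mus`, `musp`, `g`, `n`).
#' @export
assign_properties <- function(phantom, props = "human") {
  stopifnot(inherits(phantom, "voxel_phantom"))
  if (is.character(props)) props <- scenario_properties(props)
  req <- c("label", "mua", "g", "n")
  if (!all(req %in% names(props)))
    stop("props needs columns label, mua, g, n and one of musp/mus")
  used <- which(count_labels_cpp(phantom$labels, 3L) > 0) - 1L
  if (!all(used %in% props$label))
    stop(sprintf("missing optical properties for label(s) %s",
                 paste(setdiff(used, props$label), collapse = ", ")))
  if (any(props$mua < 0)) stop("mua must be >= 0")
  # exact [[-indexing: $ would partially match "mus" to a "musp" column
  if (is.null(props[["mus"]])) {
    if (is.null(props[["musp"]])) stop("give musp or mus")
    props[["mus"]] <- ifelse(props$g < 1, props[["musp"]] / (1 - props$g),
                             props[["musp"]])
  }
  if (is.null(props[["musp"]]))
    props[["musp"]] <- props[["mus"]] * (1 - pmin(props$g, 1))
  props <- props[order(props$label), , drop = FALSE]
  if (!identical(as.integer(props$label), seq_len(nrow(props)) - 1L))
    stop("labels must be consecutive integers starting at 0")
  phantom$prop_map <- props
  phantom
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat(sprintf(
    "<voxel_phantom> %d x %d x %d voxels at %.3g mm (%g mm cube)\n",
    x$dims[1], x$dims[2], x$dims[3], x$voxel_mm, x$dims[1] * x$voxel_mm))
  n <- label_counts(x)
  cat(sprintf("  %s: %g voxels\n", names(n), n), sep = "")
  cat(if (is.null(x$prop_map)) "  properties: unassigned\n"
      else "  properties: assigned\n")
  invisible(x)
}
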