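# Light sources and voxel Monte Carlo transport over a voxel_phantom.

#' Cylindrical side-firing source
#'
#' The clinical side-firing probe is modelled as a cylindrical surface of
#' given outer diameter and emission length, axis along z, emitting uniformly
#' over the surface with a cosine-weighted angular profile about the outward
#' radial normal. Defaults follow the bronchoscopic PDT irradiation
#' protocol: 1 mm outer diameter, 11 mm emission length, 150 mW for 667 s
#' (100.05 J delivered).
#'
#' @param center Center of the emission region (mm), typically the tumor
#'   center.
#' @param outer_diameter_mm Probe outer diameter (mm).
#' @param emission_length_mm Emission length (mm).
#' @param power_W Irradiation power (W).
#' @param duration_s Irradiation time (s).
#' @return Object of class `light_source`.
#' @export
cylindrical_source <- function(center, outer_diameter_mm = 1,
                               emission_length_mm = 11, power_W = 0.150,
                               duration_s = 667) {
  stopifnot(length(center) == 3, outer_diameter_mm > 0,
            emission_length_mm > 0, power_W > 0, duration_s > 0)
  structure(
    list(type = 0L, center = as.numeric(center),
         radius = outer_diameter_mm / 2,
         emission_length = emission_length_mm,
         power_W = power_W, duration_s = duration_s),
    class = "light_source")
}

#' Isotropic point source (physics-oracle harness)
#'
#' @inheritParams cylindrical_source
#' @export
point_source <- function(center, power_W = 1, duration_s = 1) {
  stopifnot(length(center) == 3)
  structure(
    list(type = 1L, center = as.numeric(center), power_W = power_W,
         duration_s = duration_s),
    class = "light_source")
}

#' Collimated pencil source (physics-oracle harness)
#'
#' @inheritParams cylindrical_source
#' @param direction Unit propagation direction.
#' @export
pencil_source <- function(center, direction = c(0, 0, 1), power_W = 1,
                          duration_s = 1) {
  stopifnot(length(center) == 3, length(direction) == 3)
  structure(
    list(type = 2L, center = as.numeric(center),
         direction = as.numeric(direction), power_W = power_W,
         duration_s = duration_s),
    class = "light_source")
}

#' Sample initial photon packets from a source
#'
#' Draws launch positions and directions, mainly for verifying the source
#' model (uniformity over the emission window, radial launch positions,
#' angular symmetry). Weight is 1 for every packet.
#'
#' @param source A `light_source`.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return Matrix with columns x, y, z, ux, uy, uz.
#' @export
launch_source <- function(source, n, seed) {
  stopifnot(inherits(source, "light_source"))
  sample_source_cpp(unclass(source), as.double(n), as.double(seed))
}

#' Run voxel Monte Carlo light transport
#'
#' Transports photon packets through the labeled voxel grid: free paths
#' sampled in optical depth against the local total attenuation,
#' Henyey-Greenstein scattering (forward delta where g = 1, the air
#' convention), Fresnel reflection/refraction at voxel faces where the
#' refractive index changes, absorbing domain boundary. Per-voxel fluence is
#' scored with the track-length estimator and scaled by the delivered energy
#' `power_W * duration_s`; the energy-deposition field is derived voxel-wise
#' as `mua * fluence`, making that identity exact by construction. Results
#' are bit-reproducible for a given seed.
#'
#' @param phantom A [build_phantom()] result with properties assigned
#'   ([assign_properties()]).
#' @param source A `light_source` whose emission region lies inside the
#'   domain.
#' @param n_packets Number of photon packets (>= 1e4 for meaningful fields).
#' @param seed Integer seed.
#' @return Object of class `dose_fields`: list with `fluence` (3D array,
#'   J/cm^2), `energy` (3D array, J/cm^3), `escaped_fraction`,
#'   `deposited_J`, `escaped_J`, `delivered_J`, `se_deposited_J`,
#'   `balance` (exact packet-weight bookkeeping residual), `n_packets`,
#'   `voxel_mm`, `labels` (reference to the phantom labels).
#' @export
run_transport <- function(phantom, source, n_packets = 1e6, seed) {
  stopifnot(inherits(phantom, "voxel_phantom"),
            inherits(source, "light_source"))
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(phantom$prop_map))
    stop("phantom has no optical properties assigned")
  if (n_packets < 1e4) stop("n_packets must be >= 1e4")
  if (n_packets > 2^53) stop("n_packets overflows the scoring accumulators")
  ext_lo <- phantom$origin
  ext_hi <- phantom$origin + phantom$dims * phantom$voxel_mm
  emission_halfz <- if (source$type == 0L) source$emission_length / 2 else 0
  if (any(source$center - c(0, 0, emission_halfz) < ext_lo) ||
      any(source$center + c(0, 0, emission_halfz) > ext_hi))
    stop("source emission region lies outside the domain")

  pm <- phantom$prop_map
  raw <- voxel_mc_cpp(phantom$labels, as.integer(phantom$dims),
                      phantom$voxel_mm, phantom$origin,
                      pm$mua, pm[["mus"]], pm$g, pm$n,
                      unclass(source), as.double(n_packets), as.double(seed))

  Q <- source$power_W * source$duration_s          # delivered energy, J
  vvox <- phantom$voxel_mm^3                       # mm^3
  # track_sum is sum(w * path[mm]); fluence in J/cm^2 =
  #   track_sum * (Q / N) / V[mm^3] * 100
  scale <- Q / raw$n_packets / vvox * 100
  fluence <- raw$track_sum * scale
  dim(fluence) <- phantom$dims
  mua_vox <- pm$mua[as.integer(phantom$labels) + 1L]
  energy <- mua_vox * as.numeric(fluence) * 10     # J/cm^3
  dim(energy) <- phantom$dims

  structure(
    list(fluence = fluence, energy = energy,
         escaped_fraction = raw$escaped,
         deposited_J = raw$absorbed_track * Q,
         escaped_J = raw$escaped * Q,
         delivered_J = Q,
         se_deposited_J = raw$se_absorbed * Q,
         se_escaped_J = raw$se_escaped * Q,
         balance = 1 - (raw$escaped + raw$absorbed_collision +
                          raw$roulette_net + raw$lost),
         n_packets = raw$n_packets, voxel_mm = phantom$voxel_mm,
         labels = phantom$labels),
    class = "dose_fields")
}

#' @export
print.dose_fields <- function(x, ...) {
  cat(sprintf(
    "<dose_fields> %d x %d x %d voxels at %.3g mm, %g packets\n",
    dim(x$fluence)[1], dim(x$fluence)[2], dim(x$fluence)[3], x$voxel_mm,
    x$n_packets))
  cat(sprintf("  delivered %.4g J: deposited %.4g J, escaped %.4g J\n",
              x$delivered_J, x$deposited_J, x$escaped_J))
  invisible(x)
}
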