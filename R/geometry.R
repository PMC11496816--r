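#' Acquisition geometry for propagation-based phase-contrast CT
#'
#' Describes a parallel-beam synchrotron free-space-propagation setup: beam
#' energy, propagation (sample-to-detector) distance, detector pixel pitch,
#' and the angular sampling scheme. Defaults follow the ID17-style
#' configuration used throughout the package: 35 keV, 3.45 m propagation and
#' an effective 3.5 um pixel at the sample.
#'
#' In 360-degree mode the rotation axis is offset towards the edge of the
#' field of view (`rotation_axis_offset`, in pixels from the detector centre)
#' so that opposing projections can be mirrored and stitched into a single
#' 180-degree data set of roughly double width (see [halfacq_stitch()]).
#'
#' @param energy_kev Beam energy in keV (> 0). The wavelength is derived as
#'   12.398 / E Angstrom.
#' @param prop_distance_m Sample-to-detector distance in metres (>= 0; 0 gives
#'   a pure-attenuation contact image).
#' @param pixel_pitch_um Detector pixel pitch at the sample, in micrometres.
#' @param n_angles Number of equally spaced projections (>= 1).
#' @param angular_range Either 180 or 360 degrees; angles are
#'   endpoint-exclusive.
#' @param photon_count Expected photons per pixel for Poisson noise;
#'   `Inf` (default) means noiseless.
#' @param rotation_axis_offset Rotation-axis offset from the detector centre,
#'   in pixels. Required (non-zero) in 360-degree mode.
#' @return An object of class `ct_geometry`.
#' @examples
#' g <- ct_geometry(n_angles = 4, angular_range = 180)
#' projection_angles(g)  # 0, 45, 90, 135
#' @export
ct_geometry <- function(energy_kev = 35,
                        prop_distance_m = 3.45,
                        pixel_pitch_um = 3.5,
                        n_angles = 2000,
                        angular_range = 180,
                        photon_count = Inf,
                        rotation_axis_offset = 0) {
  assert_scalar_num(energy_kev, "energy_kev", min = 1e-9)
  assert_scalar_num(prop_distance_m, "prop_distance_m", min = 0)
  assert_scalar_num(pixel_pitch_um, "pixel_pitch_um", min = 1e-12)
  assert_scalar_num(n_angles, "n_angles", min = 1)
  if (!angular_range %in% c(180, 360))
    abort("`angular_range` must be 180 or 360 degrees")
  if (!(is.numeric(photon_count) && length(photon_count) == 1L &&
        (is.infinite(photon_count) || photon_count > 0)))
    abort("`photon_count` must be a positive number or Inf")
  assert_scalar_num(rotation_axis_offset, "rotation_axis_offset")
  structure(
    list(energy_kev = energy_kev,
         prop_distance_m = prop_distance_m,
         pixel_pitch_um = pixel_pitch_um,
         n_angles = as.integer(n_angles),
         angular_range = angular_range,
         photon_count = photon_count,
         rotation_axis_offset = rotation_axis_offset),
    class = "ct_geometry")
}

#' X-ray wavelength of a geometry
#'
#' @param geometry A [ct_geometry()].
#' @return Wavelength in micrometres (lambda = 12.398 / E Angstrom).
#' @export
wavelength_um <- function(geometry) {
  12.398 / geometry$energy_kev * 1e-4
}

#' Projection angles of a geometry
#'
#' Equally spaced angles over the angular range, endpoint-exclusive.
#'
#' @param geometry A [ct_geometry()].
#' @return Numeric vector of angles in degrees.
#' @export
projection_angles <- function(geometry) {
  seq(0, geometry$angular_range, length.out = geometry$n_angles + 1L)[
    seq_len(geometry$n_angles)]
}

#' @export
print.ct_geometry <- function(x, ...) {
  cat(sprintf(
    "<ct_geometry> %g keV, z = %g m, pitch = %g um, %d angles over %g deg%s\n",
    x$energy_kev, x$prop_distance_m, x$pixel_pitch_um, x$n_angles,
    x$angular_range,
    if (is.finite(x$photon_count))
      sprintf(", %g photons/px", x$photon_count) else " (noiseless)"))
  if (x$rotation_axis_offset != 0)
    cat(sprintf("  rotation axis offset: %g px\n", x$rotation_axis_offset))
  invisible(x)
}
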