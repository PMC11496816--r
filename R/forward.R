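# Forward model: parallel-beam line integrals of the complex refractive
# index followed by Fresnel free-space propagation to the detector plane.
# Projections are built per slice row (2D slice x 1D detector row, stacked),
# which is the declared parallel-beam contract of the simulator.

default_detector <- function(width, pixel_pitch, axis_offset = 0) {
  ((seq_len(width)) - (width + 1) / 2 - axis_offset) * pixel_pitch
}

radon_volume <- function(vol, angles_deg, pixel_pitch, det) {
  dm <- dim(vol)
  out <- array(0, dim = c(length(angles_deg), dm[1], length(det)))
  ang <- angles_deg * pi / 180
  for (z in seq_len(dm[1])) {
    out[, z, ] <- cpp_radon(vol[z, , , drop = TRUE], ang, det, pixel_pitch,
                            pixel_pitch / 2)
  }
  out
}

#' Parallel-beam line integrals of a refractive volume
#'
#' Path-integrates the per-voxel delta and beta maps along parallel rays at
#' one view angle, slice by slice. Integrals are in micrometre-weighted
#' units (value x path length in um) and the operation is linear in the
#' input maps.
#'
#' @param volume A `refractive_volume` from [assign_materials()].
#' @param angle View angle in degrees (0 projects along the +y axis).
#' @param det Optional detector coordinates in um relative to the rotation
#'   axis; defaults to `nx` pixels centred on the axis.
#' @param axis_offset Rotation-axis offset in pixels from the detector
#'   centre (used when `det` is NULL).
#' @return A list with matrices `delta` and `beta`, each (nz x n_det).
#' @export
line_integrals <- function(volume, angle, det = NULL, axis_offset = 0) {
  if (!inherits(volume, "refractive_volume"))
    abort("`volume` must be a refractive_volume")
  dm <- dim(volume$delta)
  if (is.null(det))
    det <- default_detector(dm[3], volume$voxel_pitch, axis_offset)
  list(delta = radon_volume(volume$delta, angle, volume$voxel_pitch,
                            det)[1, , , drop = TRUE],
       beta = radon_volume(volume$beta, angle, volume$voxel_pitch,
                           det)[1, , , drop = TRUE])
}

#' Fresnel free-space propagation of one projection
#'
#' Forms the complex transmission function from the projected delta and
#' beta maps (phase phi = -(2 pi / lambda) * int delta, amplitude
#' attenuation exp(-(2 pi / lambda) * int beta)) and propagates it over the
#' sample-to-detector distance with the Fourier-domain Fresnel transfer
#' function on a reflect-padded grid (padding >= half the image extent per
#' axis). At `prop_distance_m = 0` the contact image
#' exp(-(4 pi / lambda) * int beta) is returned exactly (Beer-Lambert).
#'
#' @param delta_proj,beta_proj Matrices of path-integrated delta and beta
#'   (um-weighted), rows = slice rows, cols = detector columns.
#' @param geometry A [ct_geometry()]; supplies wavelength, distance and
#'   pixel pitch.
#' @param fresnel_floor Sampling guard: error if the per-pixel Fresnel
#'   number `pitch^2 / (lambda z)` falls below this floor (aliasing of the
#'   propagator's chirp).
#' @return Matrix of flat-field-normalised intensities (unit background).
#' @export
propagate <- function(delta_proj, beta_proj, geometry,
                      fresnel_floor = 0.01) {
  delta_proj <- rbind(delta_proj); beta_proj <- rbind(beta_proj)
  if (!identical(dim(delta_proj), dim(beta_proj)))
    abort("delta and beta projections must have identical shape")
  lam <- wavelength_um(geometry)
  z <- geometry$prop_distance_m * 1e6
  if (z == 0) return(exp(-(4 * pi / lam) * beta_proj))
  pitch <- geometry$pixel_pitch_um
  nf <- pitch^2 / (lam * z)
  if (nf < fresnel_floor)
    abort(sprintf(
      "per-pixel Fresnel number %.3g below floor %.3g: propagation grid undersampled",
      nf, fresnel_floor))
  ny <- nrow(delta_proj); nx <- ncol(delta_proj)
  nyp <- next_pow2(ceiling(1.5 * ny)); nxp <- next_pow2(ceiling(1.5 * nx))
  phi <- -(2 * pi / lam) * pad_reflect(delta_proj, nyp, nxp)
  att <- (2 * pi / lam) * pad_reflect(beta_proj, nyp, nxp)
  U <- exp(-att + 1i * phi)  # complex transmission on the padded grid
  fy <- fft_freq(nyp, pitch); fx <- fft_freq(nxp, pitch)
  H <- exp(-1i * pi * lam * z * outer(fy^2, fx^2, `+`))
  Uz <- ifft2(fft2(U) * H)
  Mod(Uz[seq_len(ny), seq_len(nx), drop = FALSE])^2
}

#' Simulate a phase-contrast CT acquisition
#'
#' Generates flat-field-normalised intensity projections of a refractive
#' volume at equally spaced angles (endpoint-exclusive) over 180 or 360
#' degrees, propagating each projection to the detector plane. In
#' 360-degree (extended field-of-view) mode the rotation axis must be
#' offset towards the detector edge (`rotation_axis_offset` in the
#' geometry); see [halfacq_stitch()]. Optional Poisson noise is applied at
#' the geometry's `photon_count`.
#'
#' @param volume A `refractive_volume`.
#' @param geometry A [ct_geometry()].
#' @param det_width Detector width in pixels (defaults to the volume's x
#'   extent).
#' @param seed Seed for the Poisson noise (ignored when noiseless).
#' @return A `projection_set`: list with `data` (array angle x rows x
#'   cols), `angles` (degrees), `det` (detector s-coordinates, um),
#'   `geometry` and `kind = "intensity"`.
#' @export
acquire <- function(volume, geometry, det_width = NULL, seed = 1) {
  if (!inherits(volume, "refractive_volume"))
    abort("`volume` must be a refractive_volume")
  if (geometry$angular_range == 360 && geometry$rotation_axis_offset == 0)
    abort(paste("360-degree (half-acquisition) mode requires a non-zero",
                "rotation_axis_offset placing the axis near the detector edge"))
  dm <- dim(volume$delta)
  det_width <- det_width %||% dm[3]
  pitch <- geometry$pixel_pitch_um
  det <- default_detector(det_width, pitch, geometry$rotation_axis_offset)
  angles <- projection_angles(geometry)
  # Propagation happens in free space over the whole wavefield; the
  # detector only windows it. Simulate on a symmetric extended grid
  # aligned with the detector lattice (so opposing views stay exact
  # mirrors), then crop to the detector window.
  half_diag <- 0.5 * sqrt(sum((dm[2:3] * volume$voxel_pitch)^2))
  reach <- max(abs(det), half_diag + 16 * pitch)
  kmax <- ceiling(reach / pitch) + 1L
  phase <- det[1] / pitch - floor(det[1] / pitch)
  s_ext <- if (phase < 0.25 || phase > 0.75) {
    seq(-kmax, kmax) * pitch            # integer lattice, mirror-closed
  } else {
    (seq(-kmax, kmax - 1L) + 0.5) * pitch  # half-integer, mirror-closed
  }
  idx <- round((det - s_ext[1]) / pitch) + 1L
  if (any(idx < 1 | idx > length(s_ext)) ||
      max(abs(s_ext[idx] - det)) > 1e-6 * pitch) {
    s_ext <- det  # off-lattice detector: propagate on the window itself
    idx <- seq_along(det)
  }
  dsino <- radon_volume(volume$delta, angles, volume$voxel_pitch, s_ext)
  bsino <- radon_volume(volume$beta, angles, volume$voxel_pitch, s_ext)
  data <- array(0, dim = c(length(angles), dm[1], det_width))
  for (a in seq_along(angles)) {
    I_ext <- propagate(dsino[a, , , drop = TRUE],
                       bsino[a, , , drop = TRUE], geometry)
    data[a, , ] <- I_ext[, idx, drop = FALSE]
  }
  if (is.finite(geometry$photon_count)) {
    N <- geometry$photon_count
    with_seed(seed, {
      data <- array(rpois(length(data), pmax(data, 0) * N) / N,
                    dim = dim(data))
    })
  }
  projection_set(data, angles, geometry, det = det, kind = "intensity")
}

#' Construct a projection set
#'
#' @param data Array (n_angles x rows x detector columns).
#' @param angles Angles in degrees, strictly increasing, equally spaced.
#' @param geometry A [ct_geometry()].
#' @param det Detector s-coordinates in um relative to the rotation axis.
#' @param kind `"intensity"` (flat-field normalised) or `"thickness"`
#'   (phase-retrieved).
#' @return A `projection_set` object.
#' @export
projection_set <- function(data, angles, geometry, det = NULL,
                           kind = c("intensity", "thickness")) {
  kind <- match.arg(kind)
  if (length(dim(data)) != 3L) abort("`data` must be a 3D array")
  if (dim(data)[1] != length(angles))
    abort("first dim of `data` must match length(angles)")
  det <- det %||% default_detector(dim(data)[3], geometry$pixel_pitch_um,
                                   geometry$rotation_axis_offset)
  structure(list(data = data, angles = angles, det = det,
                 geometry = geometry, kind = kind),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  cat(sprintf("<projection_set:%s> %d angles x %d rows x %d detector px\n",
              x$kind, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3]))
  invisible(x)
}

#' Write / read a projection set as float32 TIFF + YAML sidecar
#'
#' One TIFF page per projection angle; the sidecar stores the geometry,
#' angle list, detector coordinates and kind.
#' @param pset A `projection_set`.
#' @param path TIFF path.
#' @return `write_projection_set()` returns `path` invisibly;
#'   `read_projection_set()` the reconstructed `projection_set`.
#' @export
write_projection_set <- function(pset, path) {
  write_tiff_stack(pset$data, path, type = "float32")
  update_sidecar(path, "projection_set",
                 list(angles = pset$angles, det = pset$det, kind = pset$kind,
                      geometry = unclass(pset$geometry)))
  invisible(path)
}

#' @rdname write_projection_set
#' @export
read_projection_set <- function(path) {
  data <- read_tiff_stack(path, type = "float32")
  side <- read_sidecar(path)$projection_set
  if (is.null(side)) abort("missing projection_set sidecar metadata")
  geom <- do.call(ct_geometry, side$geometry[
    c("energy_kev", "prop_distance_m", "pixel_pitch_um", "n_angles",
      "angular_range", "photon_count", "rotation_axis_offset")])
  projection_set(data, unlist(side$angles), geom, det = unlist(side$det),
                 kind = side$kind)
}
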