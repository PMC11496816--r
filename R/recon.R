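# Filtered backprojection (parallel beam) plus the two stitching schemes
# used for large samples: half-acquisition (360 degrees, axis at the edge
# of the field of view, opposing projections mirrored and joined) and
# vertical stitching of overlapping sub-volumes.

# Frequency response of the discrete band-limited ramp: the DFT of the
# sampled spatial kernel (Ram-Lak h[0] = 1/(4 d^2), h[m] = -1/(pi m d)^2
# for odd m; Shepp-Logan h[m] = -2 / (pi^2 d^2 (4 m^2 - 1))), which avoids
# the low-frequency bias of sampling |f| directly.
ramp_filter <- function(np, pitch, filter_name, apodization) {
  m <- c(seq(0, np / 2), seq(-np / 2 + 1, -1))  # signed sample offsets
  h <- numeric(np)
  if (filter_name == "ram-lak") {
    h[1] <- 1 / (4 * pitch^2)
    odd <- m %% 2 != 0
    h[odd] <- -1 / (pi * m[odd] * pitch)^2
  } else {  # shepp-logan
    h <- -2 / (pi^2 * pitch^2 * (4 * m^2 - 1))
  }
  H <- Re(stats::fft(h)) * pitch  # per-sample convolution weight
  freq <- fft_freq(np, pitch)
  fnyq <- 1 / (2 * pitch)
  if (apodization == "hann") H <- H * 0.5 * (1 + cos(pi * freq / fnyq))
  if (apodization == "hamming")
    H <- H * (0.54 + 0.46 * cos(pi * freq / fnyq))
  H
}

#' Filtered backprojection of one sinogram
#'
#' Standard parallel-beam FBP: each detector row is ramp-filtered in the
#' Fourier domain (Ram-Lak by default, Shepp-Logan or apodised variants
#' optional) on a zero-padded grid, then backprojected with linear
#' interpolation. The operator is linear in the sinogram. Angles must be
#' equally spaced and span at least 180 degrees effectively
#' (limited-angle reconstruction is not supported).
#'
#' @param sino Sinogram matrix (n_angles x n_det).
#' @param angles Projection angles in degrees, strictly increasing and
#'   equally spaced.
#' @param pixel_pitch Detector pitch in um.
#' @param filter `"ram-lak"` (default) or `"shepp-logan"`.
#' @param apodization `"none"`, `"hann"` or `"hamming"`.
#' @param det Detector s-coordinates (um); defaults to centred.
#' @param out_dim Output grid size (pixels); defaults to n_det.
#' @return A matrix (out_dim x out_dim) of reconstructed values, voxel
#'   pitch equal to the detector pitch.
#' @export
fbp_slice <- function(sino, angles, pixel_pitch,
                      filter = c("ram-lak", "shepp-logan"),
                      apodization = c("none", "hann", "hamming"),
                      det = NULL, out_dim = NULL) {
  filter <- match.arg(filter)
  apodization <- match.arg(apodization)
  sino <- rbind(sino)
  nA <- nrow(sino); nD <- ncol(sino)
  if (nA < 2L) abort("need at least 2 projection angles")
  if (length(angles) != nA) abort("length(angles) must equal nrow(sino)")
  dth <- diff(angles)
  if (any(dth <= 0) || (nA > 2 && diff(range(dth)) > 1e-6))
    abort("angles must be strictly increasing and equally spaced")
  span <- angles[nA] - angles[1] + dth[1]
  if (span < 180 - 1e-6)
    abort(sprintf(
      "angular span %.1f deg < 180 deg: limited-angle data not supported",
      span))
  det <- det %||% default_detector(nD, pixel_pitch)
  out_dim <- out_dim %||% nD

  np <- next_pow2(2L * nD)
  h <- ramp_filter(np, pixel_pitch, filter, apodization)
  P <- matrix(0, np, nA)
  P[seq_len(nD), ] <- t(sino)
  Q <- Re(stats::mvfft(stats::mvfft(P) * h, inverse = TRUE)) / np
  filt <- t(Q[seq_len(nD), , drop = FALSE])

  # average over [0, span): half-turn data weight pi/nA, full-turn pi/nA
  # with the doubled coverage compensated by averaging opposing rays
  w <- (span * pi / 180) / nA
  if (span > 180 + 1e-6) w <- w / 2
  cpp_backproject(filt, angles * pi / 180, det, pixel_pitch,
                  out_dim, out_dim) * w
}

#' Reconstruct a full volume from thickness projections
#'
#' Applies [fbp_slice()] to every slice row of a (phase-retrieved)
#' projection set.
#'
#' @param pset A `projection_set` (normally kind `"thickness"`).
#' @param ... Passed to [fbp_slice()] (`filter`, `apodization`, `out_dim`).
#' @return An object of class `recon_volume`: `voxels` (nz, ny, nx) array,
#'   `voxel_pitch` (um) and a `provenance` list.
#' @export
reconstruct_volume <- function(pset, ...) {
  geom <- pset$geometry
  nz <- dim(pset$data)[2]
  first <- fbp_slice(pset$data[, 1, , drop = TRUE], pset$angles,
                     geom$pixel_pitch_um, det = pset$det, ...)
  voxels <- array(0, dim = c(nz, nrow(first), ncol(first)))
  voxels[1, , ] <- first
  if (nz > 1) for (z in 2:nz) {
    voxels[z, , ] <- fbp_slice(pset$data[, z, , drop = TRUE], pset$angles,
                               geom$pixel_pitch_um, det = pset$det, ...)
  }
  recon_volume(voxels, geom$pixel_pitch_um,
               provenance = list(geometry = unclass(geom),
                                 n_angles = length(pset$angles)))
}

#' @rdname reconstruct_volume
#' @param voxels 3D array (nz, ny, nx).
#' @param voxel_pitch Voxel pitch in um.
#' @param provenance Free-form processing log.
#' @export
recon_volume <- function(voxels, voxel_pitch, provenance = list()) {
  if (any(!is.finite(voxels))) abort("reconstruction contains non-finite values")
  structure(list(voxels = voxels, voxel_pitch = voxel_pitch,
                 provenance = provenance),
            class = "recon_volume")
}

#' @export
print.recon_volume <- function(x, ...) {
  cat(sprintf("<recon_volume> %s voxels @ %g um\n",
              paste(dim(x$voxels), collapse = " x "), x$voxel_pitch))
  invisible(x)
}

#' Half-acquisition (extended field-of-view) stitch
#'
#' Converts a 360-degree scan with the rotation axis near one edge of the
#' field of view into a 180-degree set of roughly double width: each
#' projection at angle theta in \[0, 180) is paired with its partner at
#' theta + 180, the partner is mirrored horizontally, and the two are
#' joined at the axis column, blending any overlap with a linear ramp.
#' With the axis exactly on the last detector column the output width is
#' `2 W - 1` (the shared axis column is counted once).
#'
#' @param pset A 360-degree `projection_set` (even number of angles) whose
#'   geometry carries a positive `rotation_axis_offset`; the axis column
#'   must lie inside the detector frame.
#' @return A 180-degree `projection_set` of stitched projections with the
#'   rotation axis at the output centre.
#' @export
halfacq_stitch <- function(pset) {
  geom <- pset$geometry
  if (geom$angular_range != 360)
    abort("half-acquisition stitching needs a 360-degree projection set")
  nA <- dim(pset$data)[1]
  if (nA %% 2L != 0L) abort("need an even number of angles over 360 degrees")
  W <- dim(pset$data)[3]
  axis_col <- (W - 1) / 2 + geom$rotation_axis_offset  # 0-based column
  if (axis_col < (W - 1) / 2 || axis_col > W - 1)
    abort(sprintf(
      "rotation axis column %.1f outside the usable frame [%d, %d]",
      axis_col, ceiling((W - 1) / 2), W - 1))
  if (abs(axis_col - round(axis_col)) > 1e-9)
    abort("axis column must fall on a detector column for stitching")
  axis_col <- round(axis_col)
  half <- nA %/% 2L
  nz <- dim(pset$data)[2]
  Wout <- 2L * axis_col + 1L
  out <- array(0, dim = c(half, nz, Wout))
  # original occupies output columns 1..W (s <= right edge), mirrored
  # partner occupies columns (2*axis_col - W + 2)..Wout; both 1-based
  lo <- 2L * axis_col - W + 2L
  w1 <- rep(1, Wout); w2 <- rep(1, Wout)
  ov <- seq(max(lo, 1L), W)  # overlap columns
  if (length(ov) == 1L) {
    w1[ov] <- 0.5; w2[ov] <- 0.5
  } else {
    ramp <- seq(1, 0, length.out = length(ov))
    w1[ov] <- ramp; w2[ov] <- 1 - ramp
  }
  for (a in seq_len(half)) {
    m1 <- pset$data[a, , , drop = FALSE][1, , , drop = TRUE]
    m2 <- pset$data[a + half, , , drop = FALSE][1, , rev(seq_len(W)),
                                                drop = TRUE]
    m1 <- rbind(m1); m2 <- rbind(m2)
    o <- matrix(0, nz, Wout)
    o[, seq_len(W)] <- m1 * rep(w1[seq_len(W)], each = nz)
    o[, seq(lo, Wout)] <- o[, seq(lo, Wout)] +
      m2 * rep(w2[seq(lo, Wout)], each = nz)
    out[a, , ] <- o
  }
  geom_out <- ct_geometry(
    energy_kev = geom$energy_kev, prop_distance_m = geom$prop_distance_m,
    pixel_pitch_um = geom$pixel_pitch_um, n_angles = half,
    angular_range = 180, photon_count = geom$photon_count,
    rotation_axis_offset = 0)
  det_out <- (seq_len(Wout) - 1L - axis_col) * geom$pixel_pitch_um
  projection_set(out, pset$angles[seq_len(half)], geom_out, det = det_out,
                 kind = pset$kind)
}

#' Vertically stitch overlapping reconstructed volumes
#'
#' Sub-volumes acquired at different vertical sample positions are merged
#' into one volume; overlapping slices are averaged with linear ramp
#' weights. With `refine = TRUE` each pairwise overlap is scanned for a
#' small integer slice-offset correction (minimising the mean squared
#' mismatch) before merging, recovering sub-stack positioning errors.
#'
#' @param volumes List of `recon_volume`s, bottom first.
#' @param z_offsets Numeric vector: starting z position of each volume in
#'   um (same length as `volumes`).
#' @param refine Logical: refine offsets by cross-correlation of the
#'   overlap region.
#' @param max_lag Maximum offset correction searched, in slices.
#' @return A `recon_volume` covering the union; the applied per-volume
#'   slice corrections are stored in `provenance$offset_corrections`.
#' @export
vertical_stitch <- function(volumes, z_offsets, refine = FALSE,
                            max_lag = 3L) {
  if (length(volumes) != length(z_offsets))
    abort("`z_offsets` must match `volumes` in length")
  if (length(volumes) == 1L) return(volumes[[1]])
  pitch <- volumes[[1]]$voxel_pitch
  if (any(vapply(volumes, function(v) v$voxel_pitch, numeric(1)) != pitch))
    abort("all volumes must share the same voxel pitch")
  ord <- order(z_offsets)
  volumes <- volumes[ord]
  start <- round(z_offsets[ord] / pitch)  # slice index of each volume start
  nzs <- vapply(volumes, function(v) dim(v$voxels)[1], integer(1))
  corr <- integer(length(volumes))
  for (i in seq_along(volumes)[-1]) {
    gap <- start[i] - (start[i - 1] + nzs[i - 1])
    if (gap > 0)
      abort(sprintf(
        "gap between volumes %d and %d: missing z range [%g, %g) um",
        i - 1, i, (start[i] - gap) * pitch, start[i] * pitch))
    if (refine) {
      sc <- vapply(seq(-max_lag, max_lag), function(d) {
        s <- start[i] + d
        n_ov <- nzs[i - 1] - (s - start[i - 1])
        if (n_ov < 2 || n_ov > nzs[i] || s - start[i - 1] < 0)
          return(Inf)
        o1 <- seq(s - start[i - 1] + 1, nzs[i - 1])
        o2 <- seq_along(o1)
        mean((volumes[[i - 1]]$voxels[o1, , , drop = FALSE] -
                volumes[[i]]$voxels[o2, , , drop = FALSE])^2)
      }, numeric(1))
      d <- seq(-max_lag, max_lag)[which.min(sc)]
      corr[i] <- -d  # correction applied to the nominal offset
      start[i] <- start[i] + d
    }
  }
  z0 <- min(start); z1 <- max(start + nzs)
  nz <- z1 - z0
  shp <- dim(volumes[[1]]$voxels)[2:3]
  acc <- array(0, dim = c(nz, shp))
  wsum <- numeric(nz)
  for (i in seq_along(volumes)) {
    idx <- seq(start[i] - z0 + 1, length.out = nzs[i])
    w <- rep(1, nzs[i])
    # taper towards the cut ends that face a neighbouring volume
    if (i > 1) {
      ov <- (start[i - 1] + nzs[i - 1]) - start[i]
      if (ov > 0) w[seq_len(min(ov, nzs[i]))] <-
          seq(0, 1, length.out = min(ov, nzs[i]) + 2)[-c(1, min(ov, nzs[i]) + 2)]
    }
    if (i < length(volumes)) {
      ov <- (start[i] + nzs[i]) - start[i + 1]
      if (ov > 0) {
        k <- min(ov, nzs[i])
        w[seq(nzs[i] - k + 1, nzs[i])] <-
          rev(seq(0, 1, length.out = k + 2)[-c(1, k + 2)])
      }
    }
    acc[idx, , ] <- acc[idx, , , drop = FALSE] +
      volumes[[i]]$voxels * rep(w, times = prod(shp))
    wsum[idx] <- wsum[idx] + w
  }
  acc <- acc / rep(pmax(wsum, .Machine$double.eps), times = prod(shp))
  recon_volume(acc, pitch,
               provenance = list(stitched = length(volumes),
                                 offset_corrections = corr))
}
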