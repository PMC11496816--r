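# Paganin single-material, single-distance phase retrieval: a Lorentzian
# low-pass filter on the normalised intensity followed by a logarithm. The
# single tuning parameter is the delta/beta ratio; its "adjust until the
# image looks right" selection is automated in adaptive_delta_beta().

#' Phase-retrieval parameters
#'
#' @param delta_beta The delta/beta ratio (>= 0; 0 reduces retrieval to
#'   Beer-Lambert inversion of the attenuation).
#' @param geometry A [ct_geometry()] supplying wavelength, propagation
#'   distance and pixel pitch.
#' @param beta Absorption index of the reference material. When supplied,
#'   [retrieve_thickness()] divides by mu = 4 pi beta / lambda and returns
#'   projected thickness in um; when `NULL` (default) the retrieved
#'   attenuation line integral (dimensionless optical depth) is returned,
#'   which is the natural input for tomographic reconstruction.
#' @param pad_mode Boundary handling for the Fourier filter; `"reflect"`
#'   (symmetric) padding is the default.
#' @return An object of class `retrieval_params`.
#' @export
retrieval_params <- function(delta_beta, geometry, beta = NULL,
                             pad_mode = c("reflect")) {
  assert_scalar_num(delta_beta, "delta_beta", min = 0)
  pad_mode <- match.arg(pad_mode)
  structure(list(delta_beta = delta_beta, geometry = geometry, beta = beta,
                 pad_mode = pad_mode),
            class = "retrieval_params")
}

#' Paganin filter gain at a spatial frequency
#'
#' The Fourier-domain kernel of single-material retrieval:
#' `H(f) = 1 / (1 + pi * lambda * z * (delta/beta) * |f|^2)`, a low-pass
#' with DC gain exactly 1; for `delta_beta = 0` the gain is 1 at every
#' frequency (pure-attenuation limit). `H` is strictly decreasing in `|f|`
#' and in `delta_beta`.
#'
#' @param f Spatial frequency in cycles/um (vectorised).
#' @param params A [retrieval_params()].
#' @return Gain values in (0, 1].
#' @export
paganin_filter_value <- function(f, params) {
  lam <- wavelength_um(params$geometry)
  z <- params$geometry$prop_distance_m * 1e6
  1 / (1 + pi * lam * z * params$delta_beta * f^2)
}

#' Paganin phase retrieval of one projection
#'
#' Applies `T = -(1/mu) * ln( IFFT[ FFT(I) * H(f) ] )` on a reflect-padded
#' grid. With `delta_beta = 0` this is exactly Beer-Lambert inversion; with
#' `beta = NULL` in the params, `mu = 1` and the output is the retrieved
#' attenuation line integral.
#'
#' @param proj Matrix of flat-field-normalised intensities (> 0).
#' @param params A [retrieval_params()].
#' @return Matrix of retrieved thickness (um) or optical depth, same shape
#'   as `proj`.
#' @export
retrieve_thickness <- function(proj, params) {
  proj <- rbind(proj)
  if (any(proj <= 0))
    abort(sprintf(
      "non-positive intensity at %d pixel(s) (min %.3g): cannot take log",
      sum(proj <= 0), min(proj)))
  geom <- params$geometry
  ny <- nrow(proj); nx <- ncol(proj)
  nyp <- next_pow2(ceiling(1.5 * ny)); nxp <- next_pow2(ceiling(1.5 * nx))
  P <- pad_reflect(proj, nyp, nxp)
  fy <- fft_freq(nyp, geom$pixel_pitch_um)
  fx <- fft_freq(nxp, geom$pixel_pitch_um)
  H <- 1 / (1 + pi * wavelength_um(geom) * geom$prop_distance_m * 1e6 *
              params$delta_beta * outer(fy^2, fx^2, `+`))
  filt <- Re(ifft2(fft2(P) * H))[seq_len(ny), seq_len(nx), drop = FALSE]
  if (any(filt <= 0)) {
    bad <- which(filt <= 0, arr.ind = TRUE)
    abort(sprintf(
      paste("filtered intensity non-positive at %d pixel(s), first at",
            "(row %d, col %d): delta/beta likely too low for the noise floor"),
      nrow(bad), bad[1, 1], bad[1, 2]))
  }
  mu <- if (is.null(params$beta)) 1 else
    4 * pi * params$beta / wavelength_um(geom)
  -log(filt) / mu
}

#' Retrieve every projection of a set
#'
#' @param pset An intensity `projection_set`.
#' @param params A [retrieval_params()].
#' @return A thickness-kind `projection_set`.
#' @export
retrieve_projections <- function(pset, params) {
  if (pset$kind != "intensity")
    abort("`pset` must contain intensity projections")
  out <- pset$data
  for (a in seq_len(dim(out)[1])) {
    out[a, , ] <- retrieve_thickness(pset$data[a, , , drop = TRUE], params)
  }
  projection_set(out, pset$angles, pset$geometry, det = pset$det,
                 kind = "thickness")
}

#' Automated delta/beta selection
#'
#' Retrieves a sample projection at each candidate ratio and scores the
#' result, replacing the visual "adjust until the image quality is
#' acceptable" tuning with an auditable criterion:
#' * `"negativity"` (default): penalises negative values in the retrieved
#'   projected density (score = minus the fraction of integrated mass that
#'   is negative). An under-retrieved map carries oscillatory fringe
#'   undershoot below zero, which no physical projected thickness can
#'   have; matched and over-retrieved maps are non-negative and therefore
#'   tie at (near) zero, and the tie rule below then selects the smallest
#'   ratio, i.e. the least smoothing consistent with a physical map.
#' * `"cnr"`: contrast-to-noise ratio between two marked pixel regions,
#'   `|m1 - m2| / sqrt((s1^2 + s2^2)/2)`. Note that the Lorentzian kernel
#'   reduces within-region spread at least as fast as it erodes contrast,
#'   so CNR can keep rising under heavy smoothing; bracket candidates
#'   sensibly.
#' * `"fringe"`: negative residual energy above `cutoff_frac` of the
#'   Nyquist frequency (minimising leftover fringe power); monotone in the
#'   ratio by construction, so only meaningful against under-retrieval.
#'
#' Candidates scoring within `tie_tol` of the best are treated as tied;
#' ties are broken towards the lowest candidate (least smoothing) and
#' flagged in the log.
#'
#' @param proj_sample A representative intensity projection (matrix).
#' @param candidates Numeric vector of candidate delta/beta ratios.
#' @param geometry A [ct_geometry()].
#' @param criterion `"negativity"`, `"cnr"` or `"fringe"`.
#' @param region_a,region_b Logical masks (same shape as `proj_sample`)
#'   marking the two regions for the CNR criterion.
#' @param cutoff_frac Fraction of Nyquist above which energy counts as
#'   fringe residue (fringe criterion).
#' @param tie_tol Absolute score difference below which candidates count
#'   as tied.
#' @return A list with `delta_beta` (chosen), `scores` (tibble of candidate
#'   and score), and `tie` flag.
#' @export
adaptive_delta_beta <- function(proj_sample, candidates,
                                geometry,
                                criterion = c("negativity", "cnr",
                                              "fringe"),
                                region_a = NULL, region_b = NULL,
                                cutoff_frac = 0.5, tie_tol = 0.01) {
  criterion <- match.arg(criterion)
  if (length(candidates) < 1L) abort("need at least one candidate")
  candidates <- sort(candidates)
  if (criterion == "cnr" && (is.null(region_a) || is.null(region_b)))
    abort("the CNR criterion needs `region_a` and `region_b` masks")
  score_one <- function(db) {
    t_map <- retrieve_thickness(proj_sample,
                                retrieval_params(db, geometry))
    if (criterion == "negativity") {
      tot <- sum(abs(t_map))
      if (tot == 0) return(0)
      return(-sum(abs(pmin(t_map, 0))) / tot)
    }
    if (criterion == "cnr") {
      m1 <- mean(t_map[region_a]); m2 <- mean(t_map[region_b])
      s1 <- stats::var(t_map[region_a]); s2 <- stats::var(t_map[region_b])
      denom <- sqrt((s1 + s2) / 2)
      if (denom == 0) return(Inf * abs(m1 - m2))
      abs(m1 - m2) / denom
    } else {
      ny <- nrow(t_map); nx <- ncol(t_map)
      Fm <- fft2(t_map - mean(t_map))
      fy <- fft_freq(ny, geometry$pixel_pitch_um)
      fx <- fft_freq(nx, geometry$pixel_pitch_um)
      fnyq <- 1 / (2 * geometry$pixel_pitch_um)
      hi <- outer(abs(fy), abs(fx), pmax) > cutoff_frac * fnyq
      tot <- sum(Mod(Fm)^2)
      if (tot == 0) return(0)
      -sum(Mod(Fm[hi])^2) / tot
    }
  }
  scores <- vapply(candidates, score_one, numeric(1))
  scores[is.nan(scores)] <- 0
  best <- max(scores)
  winners <- which(scores >= best - tie_tol)
  tie <- length(winners) > 1L
  if (tie)
    inform(sprintf(
      "delta/beta tie between {%s}; choosing the lowest (least smoothing)",
      paste(candidates[winners], collapse = ", ")))
  list(delta_beta = candidates[min(winners)],
       scores = tibble::tibble(delta_beta = candidates, score = scores),
       tie = tie)
}
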