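# Procedural thymus phantoms: a lobulated organ with an outer cortex,
# per-lobule central medulla, Hassall's-body (HB) inclusions confined to the
# medulla, and optional interlobular gaps. Label codes follow a fixed
# convention used throughout the package.

#' Phantom label codes
#'
#' Integer codes used in phantom label volumes, annotations and masks:
#' 0 background, 1 interlobular gap, 2 cortex, 3 medulla, 4 Hassall's body.
#' @export
PHANTOM_LABELS <- c(background = 0L, gap = 1L, cortex = 2L,
                    medulla = 3L, hb = 4L)

#' Parameters of a synthetic thymus phantom
#'
#' The generator emulates the developmental anatomy of the human thymus:
#' a single central medulla surrounded by cortex before lobulation
#' (`n_lobules = 1`), and multiple lobules, each with its own central
#' medulla, afterwards. `target_medulla_frac` is the desired volumetric
#' fraction of the medulla (including any HBs carved out of it) over the
#' cortex+medulla tissue; `target_hb_frac` the desired fraction of HB
#' voxels over the medulla (medulla + HB). Foetal-like organs use wide
#' interlobular gaps; the compact postnatal arrangement corresponds to
#' `interlobular_gap = 0`.
#'
#' @param grid_shape Integer vector of voxels per axis, ordered
#'   (slice z, row y, column x); at least 32 per axis.
#' @param voxel_pitch Isotropic voxel pitch in micrometres.
#' @param n_lobules Number of lobules (>= 1; 1 = pre-lobulation stage).
#' @param target_medulla_frac Target medulla/(cortex+medulla) volume
#'   fraction in \[0, 1\].
#' @param target_hb_frac Target HB/(medulla+HB) volume fraction in \[0, 1\].
#' @param interlobular_gap Width of interlobular gaps in micrometres
#'   (0 = compact arrangement).
#' @param elongation Organ z semi-axis as a multiple of the grid half-height
#'   (>= 1). Values > 1 emulate scanning a window of a sample taller than
#'   the field of view: the organ extends beyond the grid in z and the
#'   volume is a quasi-stationary mid-organ section, the situation in which
#'   a fixed central-slice budget is representative of the whole scan.
#' @param rng_seed Integer seed; generation is fully deterministic given the
#'   seed.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(64, 64, 64),
                           voxel_pitch = 3.5,
                           n_lobules = 1,
                           target_medulla_frac = 0.38,
                           target_hb_frac = 0,
                           interlobular_gap = 0,
                           elongation = 1,
                           rng_seed = 1) {
  if (length(grid_shape) != 3L || any(grid_shape < 32))
    abort("`grid_shape` must give >= 32 voxels on each of the three axes")
  assert_scalar_num(voxel_pitch, "voxel_pitch", min = 1e-9)
  assert_scalar_num(n_lobules, "n_lobules", min = 1)
  assert_scalar_num(target_medulla_frac, "target_medulla_frac", 0, 1)
  assert_scalar_num(target_hb_frac, "target_hb_frac", 0, 1)
  assert_scalar_num(interlobular_gap, "interlobular_gap", min = 0)
  assert_scalar_num(elongation, "elongation", min = 1)
  structure(
    list(grid_shape = as.integer(grid_shape), voxel_pitch = voxel_pitch,
         n_lobules = as.integer(n_lobules),
         target_medulla_frac = target_medulla_frac,
         target_hb_frac = target_hb_frac,
         interlobular_gap = interlobular_gap,
         elongation = elongation,
         rng_seed = as.integer(rng_seed)),
    class = "phantom_params")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a ground-truth thymus phantom
#'
#' Builds an integer-labelled 3D voxel volume: an ellipsoidal organ with a
#' smoothly perturbed outline is partitioned into lobules by a seeded,
#' noise-perturbed Voronoi tessellation; interlobular gaps erode the Voronoi
#' boundaries; each lobule receives a central medulla whose extent is set by
#' thresholding a centrality score field at the quantile that realises
#' `target_medulla_frac`; HB inclusions are irregular blobs grown around
#' random medullary sites, again quantile-thresholded to realise
#' `target_hb_frac`. Realised fractions are therefore within +/- 0.03 of the
#' targets (typically much closer), and generation is bit-reproducible given
#' `rng_seed`.
#'
#' The medulla fraction is measured HB-inclusively,
#' (V_medulla + V_HB) / (V_cortex + V_medulla + V_HB), so that carving HBs
#' out of the medulla does not move a phantom away from its medulla target.
#'
#' @param params A [phantom_params()] object.
#' @return An object of class `phantom_volume` with elements `labels`
#'   (integer array, dims = `grid_shape`), `voxel_pitch`, `params`,
#'   `label_counts` and `realized` (realised fractions).
#' @examples
#' ph <- generate_thymus_phantom(phantom_params(rng_seed = 7))
#' ph$realized$medulla_frac
#' @export
generate_thymus_phantom <- function(params) {
  if (!inherits(params, "phantom_params"))
    abort("`params` must be created by phantom_params()")
  p <- params
  dm <- p$grid_shape
  with_seed(p$rng_seed, {
    # voxel centre coordinates (um), origin at the grid centre
    cz <- (seq_len(dm[1]) - (dm[1] + 1) / 2) * p$voxel_pitch
    cy <- (seq_len(dm[2]) - (dm[2] + 1) / 2) * p$voxel_pitch
    cx <- (seq_len(dm[3]) - (dm[3] + 1) / 2) * p$voxel_pitch
    Z <- array(rep(cz, times = dm[2] * dm[3]), dim = dm)
    Y <- array(rep(rep(cy, each = dm[1]), times = dm[3]), dim = dm)
    X <- array(rep(cx, each = dm[1] * dm[2]), dim = dm)

    # all random fields are drawn up front, independent of the targets, so
    # that raising a target moves a quantile threshold on a fixed field
    outline_noise <- smooth_field3d(dm, coarse = 5L)
    score_noise <- smooth_field3d(dm, coarse = 7L)
    hb_noise <- smooth_field3d(dm, coarse = 9L)

    semi <- 0.42 * dm * p$voxel_pitch * c(p$elongation, 1, 1)
    r_ell <- sqrt((Z / semi[1])^2 + (Y / semi[2])^2 + (X / semi[3])^2) *
      (1 + 0.10 * outline_noise)
    organ <- r_ell <= 1

    # lobule seeds inside the organ core, kept within the scanned window
    # along z so that every part of the grid belongs to a nearby lobule
    nseed <- p$n_lobules
    semi_seed <- 0.65 * pmin(semi, 0.55 * dm * p$voxel_pitch)
    zs <- runif(nseed, -1, 1) * semi_seed[1]
    th <- runif(nseed, 0, 2 * pi)
    rr <- sqrt(runif(nseed))
    seeds <- cbind(zs, rr * sin(th) * semi_seed[2],
                   rr * cos(th) * semi_seed[3])

    d1 <- array(Inf, dim = dm); d2 <- array(Inf, dim = dm)
    for (i in seq_len(nseed)) {
      di <- sqrt((Z - seeds[i, 1])^2 + (Y - seeds[i, 2])^2 +
                   (X - seeds[i, 3])^2)
      closer <- di < d1
      d2 <- pmin(d2, ifelse(closer, d1, di))
      d1 <- pmin(d1, di)
    }
    d_vor <- if (nseed > 1) (d2 - d1) / 2 else
      array(Inf, dim = dm)  # no inter-lobule boundary pre-lobulation

    gap <- organ & (d_vor < p$interlobular_gap / 2)
    tissue <- organ & !gap

    n_tissue <- sum(tissue)
    if (n_tissue == 0) abort("degenerate phantom: no tissue voxels")

    # centrality score: 0 at the lobule centre, -> 1 at the lobule edge
    # (organ boundary, Voronoi boundary or gap), so medulla level sets stay
    # interior and surrounded by cortex
    d_bnd <- pmax(1 - r_ell, 0) * min(semi)
    d_edge <- pmin(d_bnd, pmax(d_vor - p$interlobular_gap / 2, 0))
    score <- d1 / (d1 + d_edge + 1e-6) + 0.06 * score_noise

    # the medulla must stay surrounded by cortex: tissue voxels that touch
    # background or gap (6-neighbourhood) are cortex by fiat, and the
    # medulla quantile is renormalised over the remaining eligible voxels
    non_tissue <- !tissue
    adj <- array(FALSE, dim = dm)
    for (d in 1:3) for (off in c(-1L, 1L)) {
      shifted <- shift_array(non_tissue, d, off, fill = FALSE)
      adj <- adj | shifted
    }
    eligible <- tissue & !adj
    n_eligible <- sum(eligible)

    medulla_all <- tissue & FALSE
    if (p$target_medulla_frac > 0) {
      if (p$target_medulla_frac * n_tissue > n_eligible)
        abort(sprintf(
          "infeasible medulla target %.2f: only %d of %d tissue voxels lie inside the cortex rim",
          p$target_medulla_frac, n_eligible, n_tissue))
      q_eff <- p$target_medulla_frac * n_tissue / n_eligible
      if (p$elongation > 1) {
        # mid-organ window of a tall sample: composition is stationary
        # along z, so the centrality threshold is taken slice-wise
        zi <- slice.index(score, 1)
        thr_z <- vapply(seq_len(dm[1]), function(z) {
          sel <- eligible & zi == z
          if (!any(sel)) return(-Inf)
          n_tis_z <- sum(tissue & zi == z)
          qz <- min(1, p$target_medulla_frac * n_tis_z / sum(sel))
          quantile(score[sel], qz, names = FALSE)
        }, numeric(1))
        medulla_all <- eligible & (score <= thr_z[zi])
      } else {
        thr <- quantile(score[eligible], q_eff, names = FALSE)
        medulla_all <- eligible & (score <= thr)
      }
    }

    hb <- tissue & FALSE
    if (p$target_hb_frac > 0) {
      n_med <- sum(medulla_all)
      if (n_med == 0)
        abort(paste("infeasible targets: target_hb_frac > 0 but the",
                    "phantom has no medulla voxels"))
      n_hb_target <- p$target_hb_frac * n_med
      n_sites <- max(2L, min(round(n_hb_target / 1500), 12L))
      idx_med <- which(medulla_all)
      sites <- sample(idx_med, n_sites)
      dh <- array(Inf, dim = dm)
      for (i in sites) {
        dh <- pmin(dh, sqrt((Z - Z[i])^2 + (Y - Y[i])^2 + (X - X[i])^2))
      }
      blob_r <- (n_hb_target / n_sites * 3 / (4 * pi))^(1 / 3) *
        p$voxel_pitch
      hscore <- dh + 0.35 * blob_r * hb_noise
      thr_hb <- quantile(hscore[medulla_all], p$target_hb_frac,
                         names = FALSE)
      hb <- medulla_all & (hscore <= thr_hb)
    }

    labels <- array(PHANTOM_LABELS[["background"]], dim = dm)
    labels[gap] <- PHANTOM_LABELS[["gap"]]
    labels[tissue] <- PHANTOM_LABELS[["cortex"]]
    labels[medulla_all & !hb] <- PHANTOM_LABELS[["medulla"]]
    labels[hb] <- PHANTOM_LABELS[["hb"]]
    storage.mode(labels) <- "integer"

    counts <- label_counts(labels)
    med_incl <- counts[["medulla"]] + counts[["hb"]]
    realized_med <- med_incl / (counts[["cortex"]] + med_incl)
    realized_hb <- if (med_incl > 0) counts[["hb"]] / med_incl else 0
    if (abs(realized_med - p$target_medulla_frac) > 0.03)
      abort(sprintf(
        "infeasible medulla target: realised %.3f vs target %.3f",
        realized_med, p$target_medulla_frac))
    if (p$target_hb_frac > 0 && abs(realized_hb - p$target_hb_frac) > 0.03)
      abort(sprintf("infeasible HB target: realised %.3f vs target %.3f",
                    realized_hb, p$target_hb_frac))

    structure(
      list(labels = labels, voxel_pitch = p$voxel_pitch, params = p,
           label_counts = counts,
           realized = list(medulla_frac = realized_med,
                           hb_frac = realized_hb)),
      class = "phantom_volume")
  })
}

#' Per-label voxel counts of a label volume
#'
#' @param labels Integer array (or `phantom_volume`) with the package label
#'   codes.
#' @return Named numeric vector of voxel counts for background, gap, cortex,
#'   medulla and hb.
#' @export
label_counts <- function(labels) {
  if (inherits(labels, "phantom_volume")) labels <- labels$labels
  tab <- tabulate(as.integer(labels) + 1L, nbins = 5L)
  setNames(as.numeric(tab), names(PHANTOM_LABELS))
}

#' @export
print.phantom_volume <- function(x, ...) {
  cat(sprintf(
    "<phantom_volume> %s voxels @ %g um, %d lobule(s)\n",
    paste(dim(x$labels), collapse = " x "), x$voxel_pitch,
    x$params$n_lobules))
  cat(sprintf("  medulla fraction %.3f (target %.3f), HB fraction %.3f (target %.3f)\n",
              x$realized$medulla_frac, x$params$target_medulla_frac,
              x$realized$hb_frac, x$params$target_hb_frac))
  invisible(x)
}

#' Material table: refractive index per tissue label
#'
#' Per-label refractive-index decrement delta and absorption index beta at a
#' stated energy (n = 1 - delta + i beta). The shipped defaults are
#' plausible values for critical-point-dried soft tissue, chosen so that the
#' reconstructed intensity ordering matches the observed contrast (denser
#' areas brighter: HB > cortex > medulla; background and gaps are air,
#' delta = beta = 0). They are synthetic defaults anchored at 35 keV and
#' scaled as delta ~ 1/E^2, beta ~ 1/E^3 for other energies; they are not
#' measured thymic values and can be overridden freely.
#'
#' @param energy_kev Energy at which the table is expressed.
#' @param delta,beta Optional named numeric vectors (names from
#'   `names(PHANTOM_LABELS)`) overriding the defaults.
#' @return A tibble with columns `label`, `name`, `delta`, `beta` and an
#'   `energy_kev` attribute.
#' @export
material_table <- function(energy_kev = 35, delta = NULL, beta = NULL) {
  fd <- (35 / energy_kev)^2  # delta ~ 1/E^2
  fb <- (35 / energy_kev)^3  # beta ~ 1/E^3
  d <- c(background = 0, gap = 0, cortex = 1.05e-7, medulla = 7.5e-8,
         hb = 1.6e-7) * fd
  b <- c(background = 0, gap = 0, cortex = 2.1e-10, medulla = 1.5e-10,
         hb = 3.2e-10) * fb
  if (!is.null(delta)) d[names(delta)] <- delta
  if (!is.null(beta)) b[names(beta)] <- beta
  if (any(d < 0) || any(b < 0)) abort("delta and beta must be >= 0")
  out <- tibble::tibble(label = unname(PHANTOM_LABELS),
                        name = names(PHANTOM_LABELS),
                        delta = unname(d[names(PHANTOM_LABELS)]),
                        beta = unname(b[names(PHANTOM_LABELS)]))
  attr(out, "energy_kev") <- energy_kev
  out
}

#' Map phantom labels to refractive-index volumes
#'
#' Produces per-voxel delta and beta maps, piecewise constant within each
#' label region; background has delta = beta = 0.
#'
#' @param phantom A `phantom_volume` (or plain integer label array).
#' @param table A [material_table()]; every label present in the phantom
#'   must have a row.
#' @param voxel_pitch Voxel pitch in um, required when `phantom` is a plain
#'   array.
#' @return An object of class `refractive_volume` with `delta`, `beta`
#'   arrays, `voxel_pitch` and `energy_kev`.
#' @export
assign_materials <- function(phantom, table = material_table(),
                             voxel_pitch = NULL) {
  if (inherits(phantom, "phantom_volume")) {
    labels <- phantom$labels
    voxel_pitch <- phantom$voxel_pitch
  } else {
    labels <- phantom
    if (is.null(voxel_pitch)) abort("`voxel_pitch` required for raw labels")
  }
  present <- sort(unique(as.integer(labels)))
  missing <- setdiff(present, table$label)
  if (length(missing))
    abort(sprintf("material table has no entry for label(s): %s",
                  paste(missing, collapse = ", ")))
  lut_d <- lut_b <- numeric(max(table$label) + 1L)
  lut_d[table$label + 1L] <- table$delta
  lut_b[table$label + 1L] <- table$beta
  dm <- dim(labels)
  structure(
    list(delta = array(lut_d[as.integer(labels) + 1L], dim = dm),
         beta = array(lut_b[as.integer(labels) + 1L], dim = dm),
         voxel_pitch = voxel_pitch,
         energy_kev = attr(table, "energy_kev") %||% 35),
    class = "refractive_volume")
}

#' @export
print.refractive_volume <- function(x, ...) {
  cat(sprintf("<refractive_volume> %s voxels @ %g um, %g keV\n",
              paste(dim(x$delta), collapse = " x "), x$voxel_pitch,
              x$energy_kev))
  invisible(x)
}

#' Write / read a phantom as a TIFF label stack with YAML sidecar
#'
#' The label volume is stored as a multi-page uint8 TIFF (one page per z
#' slice) plus a `<path>.yaml` sidecar holding the generating parameters;
#' the pair round-trips bit-exactly.
#'
#' @param phantom A `phantom_volume`.
#' @param path Output TIFF path.
#' @return `write_phantom()` returns `path` invisibly; `read_phantom()`
#'   returns the reconstructed `phantom_volume`.
#' @export
write_phantom <- function(phantom, path) {
  write_tiff_stack(phantom$labels, path, type = "uint8")
  side <- unclass(phantom$params)
  side$grid_shape <- as.integer(side$grid_shape)
  update_sidecar(path, "phantom_params", side)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  labels <- read_tiff_stack(path, type = "uint8")
  side <- yaml::read_yaml(sidecar_path(path))$phantom_params
  params <- do.call(phantom_params, side)
  counts <- label_counts(labels)
  med_incl <- counts[["medulla"]] + counts[["hb"]]
  structure(
    list(labels = labels, voxel_pitch = params$voxel_pitch, params = params,
         label_counts = counts,
         realized = list(
           medulla_frac = med_incl / (counts[["cortex"]] + med_incl),
           hb_frac = if (med_incl > 0) counts[["hb"]] / med_incl else 0)),
    class = "phantom_volume")
}

sidecar_path <- function(path) paste0(path, ".yaml")
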