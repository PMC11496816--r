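# Sparse-annotation segmentation: a handful of manually labelled slices at
# regular intervals are propagated to the whole volume by a random-forest
# pixel classifier on handcrafted intensity features, mirroring
# interpolation-style ML segmentation workflows. Hassall's bodies can
# additionally be detected by a rule-based intensity criterion inside the
# medulla.

#' Sparse slice annotations
#'
#' @param slice_idx Integer vector of annotated slice indices (1-based).
#' @param labels List of integer label matrices (package label codes), one
#'   per annotated slice.
#' @param interval Nominal annotation interval k (informational).
#' @return An object of class `sparse_annotation`.
#' @export
sparse_annotation <- function(slice_idx, labels, interval = NULL) {
  if (length(slice_idx) != length(labels))
    abort("`slice_idx` and `labels` must have the same length")
  bad <- setdiff(unique(unlist(lapply(labels, unique))), PHANTOM_LABELS)
  if (length(bad))
    abort(sprintf("illegal label code(s): %s", paste(bad, collapse = ", ")))
  structure(list(slice_idx = as.integer(slice_idx), labels = labels,
                 interval = interval),
            class = "sparse_annotation")
}

#' Annotate every k-th slice from a label volume
#'
#' Convenience constructor emulating the manual annotation protocol:
#' ground-truth (or manually drawn) labels are taken on every `interval`-th
#' slice.
#'
#' @param labels Integer label array (nz, ny, nx) or `phantom_volume`.
#' @param interval Annotation interval k.
#' @param offset Index of the first annotated slice.
#' @return A `sparse_annotation`.
#' @export
annotate_every_kth <- function(labels, interval = 10L, offset = 1L) {
  if (inherits(labels, "phantom_volume")) labels <- labels$labels
  idx <- seq(offset, dim(labels)[1], by = interval)
  sparse_annotation(idx,
                    lapply(idx, function(z) labels[z, , , drop = TRUE]),
                    interval = interval)
}

central_diff_rows <- function(m) {
  n <- nrow(m)
  up <- m[pmin(seq_len(n) + 1L, n), , drop = FALSE]
  dn <- m[pmax(seq_len(n) - 1L, 1L), , drop = FALSE]
  (up - dn) / 2
}

slice_features <- function(slice, sigmas = c(1, 2, 4)) {
  feats <- list(intensity = slice)
  for (s in sigmas) {
    sm <- gauss_smooth2d(slice, s)
    feats[[paste0("gauss", s)]] <- sm
    gy <- central_diff_rows(sm)
    gx <- t(central_diff_rows(t(sm)))
    feats[[paste0("grad", s)]] <- sqrt(gy^2 + gx^2)
  }
  vapply(feats, as.vector, numeric(length(slice)))
}

modal_filter3 <- function(lab) {
  ny <- nrow(lab); nx <- ncol(lab)
  classes <- sort(unique(as.vector(lab)))
  if (length(classes) == 1L) return(lab)
  votes <- array(0L, dim = c(ny, nx, length(classes)))
  px <- function(m, dy, dx) {
    yi <- pmin(pmax(seq_len(ny) + dy, 1L), ny)
    xi <- pmin(pmax(seq_len(nx) + dx, 1L), nx)
    m[yi, xi, drop = FALSE]
  }
  for (dy in -1:1) for (dx in -1:1) {
    nb <- px(lab, dy, dx)
    for (k in seq_along(classes))
      votes[, , k] <- votes[, , k] + (nb == classes[k])
  }
  best <- apply(votes, c(1, 2), which.max)
  matrix(classes[best], ny, nx)
}

#' Propagate sparse annotations to a full volume
#'
#' Trains a random-forest pixel classifier (intensity plus multi-scale
#' smoothed and gradient-magnitude features) on the annotated slices and
#' applies it to every unannotated slice; annotated slices are passed
#' through unchanged, so annotating every slice reproduces the annotation
#' exactly. The volume is z-scored before feature extraction, making the
#' segmentation invariant to global affine intensity rescaling. Labels
#' present in fewer than `min_label_pixels` annotated pixels are dropped
#' from training with a warning. Deterministic given `seed`.
#'
#' @param volume A `recon_volume` or plain 3D array.
#' @param ann A [sparse_annotation()] with at least 2 annotated slices
#'   (a single slice is accepted but flagged).
#' @param sigmas Gaussian feature scales in pixels.
#' @param cleanup Apply a 3x3 modal (majority) filter to predicted slices.
#' @param num_trees Trees in the random forest.
#' @param min_label_pixels Minimum annotated pixels for a label to enter
#'   training.
#' @param seed RNG seed for the forest.
#' @return A `compartment_masks` object (binary cortex/medulla/hb volumes
#'   plus the full predicted label array in `$labels`).
#' @export
propagate_annotations <- function(volume, ann, sigmas = c(1, 2, 4),
                                  cleanup = TRUE, num_trees = 100L,
                                  min_label_pixels = 50L, seed = 1L) {
  vol <- if (inherits(volume, "recon_volume")) volume$voxels else volume
  if (!inherits(ann, "sparse_annotation"))
    abort("`ann` must be a sparse_annotation")
  nz <- dim(vol)[1]
  if (any(ann$slice_idx < 1 | ann$slice_idx > nz))
    abort("annotated slice indices outside the volume")
  if (length(ann$slice_idx) < 2L)
    warn("fewer than 2 annotated slices: propagation is poorly constrained")
  s <- sd(as.vector(vol))
  volz <- if (s > 0) (vol - mean(vol)) / s else vol * 0

  train_x <- list(); train_y <- list()
  for (i in seq_along(ann$slice_idx)) {
    z <- ann$slice_idx[i]
    train_x[[i]] <- slice_features(volz[z, , , drop = TRUE], sigmas)
    train_y[[i]] <- as.vector(ann$labels[[i]])
  }
  X <- do.call(rbind, train_x)
  y <- unlist(train_y)
  tab <- table(y)
  drop <- names(tab)[tab < min_label_pixels]
  if (length(drop)) {
    warn(sprintf(
      "label(s) %s present in < %d annotated pixels: dropped from training",
      paste(drop, collapse = ", "), min_label_pixels))
    keep <- !(y %in% as.integer(drop))
    X <- X[keep, , drop = FALSE]; y <- y[keep]
  }
  if (length(unique(y)) < 1L) abort("no trainable labels in the annotation")

  out <- array(0L, dim = dim(vol))
  for (i in seq_along(ann$slice_idx))
    out[ann$slice_idx[i], , ] <- ann$labels[[i]]

  todo <- setdiff(seq_len(nz), ann$slice_idx)
  if (length(todo)) {
    if (length(unique(y)) == 1L) {
      for (z in todo) out[z, , ] <- unique(y)
    } else {
      with_seed(seed, {
        df <- as.data.frame(X)
        df$.label <- factor(y)
        rf <- ranger::ranger(dependent.variable.name = ".label", data = df,
                             num.trees = num_trees, seed = seed,
                             num.threads = 1)
        for (z in todo) {
          fz <- as.data.frame(slice_features(volz[z, , , drop = TRUE],
                                             sigmas))
          pred <- as.integer(as.character(
            stats::predict(rf, data = fz, num.threads = 1)$predictions))
          lab <- matrix(pred, dim(vol)[2], dim(vol)[3])
          if (cleanup) lab <- modal_filter3(lab)
          out[z, , ] <- lab
        }
      })
    }
  }
  compartment_masks(cortex = out == PHANTOM_LABELS[["cortex"]],
                    medulla = out == PHANTOM_LABELS[["medulla"]],
                    hb = out == PHANTOM_LABELS[["hb"]],
                    labels = out)
}

#' Binary compartment masks
#'
#' Co-registered binary volumes for cortex, medulla and Hassall's bodies.
#' Masks must be pairwise disjoint and share one shape; HB voxels lie
#' inside the (HB-inclusive) medulla support by construction of every
#' producer in the package.
#'
#' @param cortex,medulla,hb Logical arrays of identical shape.
#' @param labels Optional full label array the masks were derived from.
#' @param slice_range Optional 2-vector of covered slice indices.
#' @return An object of class `compartment_masks`.
#' @export
compartment_masks <- function(cortex, medulla, hb = NULL, labels = NULL,
                              slice_range = NULL) {
  if (is.null(hb)) hb <- array(FALSE, dim = dim(medulla))
  if (!identical(dim(cortex), dim(medulla)) ||
      !identical(dim(cortex), dim(hb)))
    abort("masks must share one shape")
  if (any(cortex & medulla) || any(cortex & hb) || any(medulla & hb))
    abort("compartment masks must be pairwise disjoint")
  structure(list(cortex = cortex, medulla = medulla, hb = hb,
                 labels = labels,
                 slice_range = slice_range %||% c(1L, dim(cortex)[1])),
            class = "compartment_masks")
}

#' Ground-truth masks from a label volume
#'
#' @param labels Integer label array or `phantom_volume`.
#' @return A `compartment_masks`.
#' @export
masks_from_labels <- function(labels) {
  if (inherits(labels, "phantom_volume")) labels <- labels$labels
  compartment_masks(cortex = labels == PHANTOM_LABELS[["cortex"]],
                    medulla = labels == PHANTOM_LABELS[["medulla"]],
                    hb = labels == PHANTOM_LABELS[["hb"]],
                    labels = labels)
}

#' @export
print.compartment_masks <- function(x, ...) {
  cat(sprintf(
    "<compartment_masks> %s: cortex %d, medulla %d, hb %d voxels\n",
    paste(dim(x$cortex), collapse = " x "), sum(x$cortex), sum(x$medulla),
    sum(x$hb)))
  invisible(x)
}

#' Dice overlap coefficient
#'
#' @param a,b Logical arrays of identical shape.
#' @return `2|a & b| / (|a| + |b|)`; 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) abort("masks must share one shape")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Rule-based Hassall's-body detection
#'
#' Inside the medulla support, voxels whose intensity is beyond robust
#' bounds (above the `q_hi` or below the `q_lo` quantile of the reference
#' medullary intensity) are grouped into 6-connected 3D components;
#' components smaller than `min_component` voxels are discarded. Both the
#' bright (dense, keratin-rich) and dark (cystic) parts of a component are
#' retained.
#'
#' @param volume A `recon_volume` or 3D array.
#' @param medulla_mask Logical array: the (HB-inclusive) medulla support to
#'   search.
#' @param reference_mask Logical array over which the intensity quantiles
#'   are taken; defaults to `medulla_mask`. When HBs occupy a sizeable part
#'   of the support, pass an HB-poor reference (e.g. a classifier's
#'   medulla-only mask) so the quantiles describe unremarkable medulla.
#' @param q_hi,q_lo High/low quantiles of the reference intensity.
#' @param min_component Minimum component volume in voxels.
#' @return Logical HB mask, same shape as the input volume.
#' @export
segment_hbs <- function(volume, medulla_mask, reference_mask = NULL,
                        q_hi = 0.99, q_lo = 0.01, min_component = 50L) {
  vol <- if (inherits(volume, "recon_volume")) volume$voxels else volume
  if (!identical(dim(vol), dim(medulla_mask)))
    abort("`medulla_mask` must match the volume shape")
  if (!any(medulla_mask)) {
    warn("empty medulla mask: returning an empty HB mask")
    return(array(FALSE, dim = dim(vol)))
  }
  ref <- reference_mask %||% medulla_mask
  bounds <- quantile(vol[ref], c(q_lo, q_hi), names = FALSE)
  cand <- medulla_mask & (vol < bounds[1] | vol > bounds[2])
  if (!any(cand)) return(array(FALSE, dim = dim(vol)))
  lab <- cpp_label3d(as.vector(cand), dim(vol)[1], dim(vol)[2], dim(vol)[3])
  sizes <- tabulate(lab, nbins = attr(lab, "n_components"))
  keep <- which(sizes >= min_component)
  out <- array(lab > 0L & lab %in% keep, dim = dim(vol))
  out
}
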