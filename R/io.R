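# TIFF stack + YAML sidecar I/O. Volumes are arrays with dims
# (slice z, row y, col x); one TIFF page per slice, z ascending.
#
# The underlying TIFF writer stores 32-bit samples quantised on [0, 1]
# (step 2^-32), so "float32" stacks are written affinely normalised with
# the offset/scale recorded in the sidecar and round-trip to ~2^-32 of
# the value range; uint8 label stacks are stored verbatim and round-trip
# bit-exactly.

#' Write a 3D volume as a multi-page TIFF stack
#'
#' @param volume Numeric or integer array, dims (nz, ny, nx); slice order is
#'   z ascending.
#' @param path Output path.
#' @param type `"float32"` for image data (stored normalised, with
#'   offset/scale in the YAML sidecar `<path>.yaml`) or `"uint8"` for label
#'   data (values 0..255, stored verbatim).
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(volume, path, type = c("float32", "uint8")) {
  type <- match.arg(type)
  if (is.null(dim(volume)) || length(dim(volume)) != 3L)
    abort("`volume` must be a 3D array (z, y, x)")
  if (dim(volume)[1] == 0L) abort("empty stack: no slices to write")
  if (any(!is.finite(volume))) abort("`volume` contains non-finite values")
  nz <- dim(volume)[1]
  if (type == "uint8") {
    if (any(volume < 0 | volume > 255 | volume != round(volume)))
      abort("uint8 stack values must be integers in 0..255")
    pages <- lapply(seq_len(nz), function(z) volume[z, , , drop = TRUE] / 255)
    tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  } else {
    lo <- min(volume); hi <- max(volume)
    scale <- if (hi > lo) hi - lo else 1
    norm <- (volume - lo) / scale
    pages <- lapply(seq_len(nz), function(z) norm[z, , , drop = TRUE])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
    update_sidecar(path, "tiff_scaling",
                   list(offset = lo, scale = scale))
  }
  invisible(path)
}

#' Read a multi-page TIFF stack written by [write_tiff_stack()]
#'
#' @param path TIFF path.
#' @param type Storage type used when writing.
#' @return A 3D array with dims (nz, ny, nx).
#' @export
read_tiff_stack <- function(path, type = c("float32", "uint8")) {
  type <- match.arg(type)
  if (!file.exists(path)) abort(sprintf("no such TIFF stack: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = (type == "uint8"))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) abort("empty TIFF stack")
  shp <- dim(pages[[1]])
  if (length(shp) != 2L) abort("expected single-channel grayscale pages")
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1))))
    abort("TIFF pages have inconsistent shapes")
  vol <- aperm(simplify2array(pages), c(3, 1, 2))
  if (type == "uint8") {
    storage.mode(vol) <- "integer"
  } else {
    sc <- read_sidecar(path)$tiff_scaling
    if (!is.null(sc)) vol <- vol * sc$scale + sc$offset
  }
  vol
}

update_sidecar <- function(path, key, value) {
  sp <- sidecar_path(path)
  side <- if (file.exists(sp)) yaml::read_yaml(sp) else list()
  side[[key]] <- value
  yaml::write_yaml(side, sp)
  invisible(sp)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (file.exists(sp)) yaml::read_yaml(sp) else list()
}
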