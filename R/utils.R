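# Internal numerical helpers shared across the pipeline.

# FFT sample frequencies in cycles per unit, matching the layout of stats::fft.
fft_freq <- function(n, d = 1) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / (n * d)
}

next_pow2 <- function(n) 2L^ceiling(log2(n))

# Pad a matrix to (ny, nx) by edge reflection (no repeated edge sample where
# possible), keeping the original in the top-left corner.
pad_reflect <- function(m, ny, nx) {
  ry <- m[pad_index(nrow(m), ny), , drop = FALSE]
  ry[, pad_index(ncol(m), nx), drop = FALSE]
}

pad_index <- function(n, n_out) {
  if (n_out < n) stop("padding target smaller than input")
  idx <- seq_len(n_out)
  # reflect indices about the [1, n] range: 1..n, n-1..1, 2..n, ...
  period <- max(2L * (n - 1L), 1L)
  r <- (idx - 1L) %% period
  ifelse(r < n, r + 1L, 2L * n - 1L - r)
}

fft2 <- function(m) stats::fft(m)
ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

# Separable Gaussian smoothing of a 2D image with replicate-edge handling.
gauss_smooth2d <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  sm_rows <- function(m) {
    n <- nrow(m)
    idx <- pmin(pmax(outer(seq_len(n), -r:r, `+`), 1L), n)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
    out
  }
  t(sm_rows(t(sm_rows(img))))
}

# Smooth random field on an arbitrary grid: white noise on a coarse lattice,
# trilinearly interpolated, scaled to zero mean / unit max-abs. Deterministic
# in the supplied RNG state.
smooth_field3d <- function(dim, coarse = 6L) {
  coarse <- pmax(2L, rep_len(coarse, 3L))
  g <- array(rnorm(prod(coarse)), dim = coarse)
  ax <- lapply(1:3, function(i) {
    if (dim[i] == 1L) return(list(i0 = rep(1L, 1), i1 = rep(1L, 1), f = 0))
    p <- seq(0, 1, length.out = dim[i]) * (coarse[i] - 1L) + 1
    i0 <- pmin(floor(p), coarse[i] - 1L)
    list(i0 = as.integer(i0), i1 = as.integer(i0) + 1L, f = p - i0)
  })
  out <- array(0, dim = dim)
  for (bz in 0:1) for (by in 0:1) for (bx in 0:1) {
    wz <- if (bz) ax[[1]]$f else 1 - ax[[1]]$f
    wy <- if (by) ax[[2]]$f else 1 - ax[[2]]$f
    wx <- if (bx) ax[[3]]$f else 1 - ax[[3]]$f
    iz <- if (bz) ax[[1]]$i1 else ax[[1]]$i0
    iy <- if (by) ax[[2]]$i1 else ax[[2]]$i0
    ix <- if (bx) ax[[3]]$i1 else ax[[3]]$i0
    vals <- g[cbind(rep(iz, times = dim[2] * dim[3]),
                    rep(rep(iy, each = dim[1]), times = dim[3]),
                    rep(ix, each = dim[1] * dim[2]))]
    w <- rep(wz, times = dim[2] * dim[3]) *
      rep(rep(wy, each = dim[1]), times = dim[3]) *
      rep(wx, each = dim[1] * dim[2])
    out <- out + array(vals * w, dim = dim)
  }
  out <- out - mean(out)
  m <- max(abs(out))
  if (m > 0) out <- out / m
  out
}

# result[i] = x[i + off] along dimension d; out-of-range positions get
# `fill`. Used for 6-neighbourhood queries on 3D masks.
shift_array <- function(x, d, off, fill = FALSE) {
  dm <- dim(x)
  src <- lapply(dm, seq_len)
  dst <- src
  if (off > 0) {
    src[[d]] <- seq(1 + off, dm[d])
    dst[[d]] <- seq(1, dm[d] - off)
  } else {
    src[[d]] <- seq(1, dm[d] + off)
    dst[[d]] <- seq(1 - off, dm[d])
  }
  out <- array(fill, dim = dm)
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

# Deterministic per-stage seed fan-out from the single pipeline seed: each
# stage gets seed * 97 + offset, reduced into the 32-bit integer range.
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97 + offset) %% .Machine$integer.max)
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

assert_scalar_num <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    abort(sprintf("`%s` must be a single number in [%s, %s]", name,
                  format(min), format(max)))
  invisible(x)
}
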