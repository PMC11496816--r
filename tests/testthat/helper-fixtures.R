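# Shared fixtures and independent oracles. Oracles deliberately use
# different code paths (pure R, closed forms, brute-force enumeration)
# from the implementation they check.

wavelength_at_35kev <- 12.398 / 35 * 1e-4  # um

# Binary cylinder (disk extruded along z) as a label/value slice stack.
cylinder_volume <- function(n = 128, nz = 1, radius_px = 40, pitch = 3.5,
                            value = 1) {
  cc <- (n + 1) / 2
  d2 <- outer((seq_len(n) - cc)^2, (seq_len(n) - cc)^2, `+`)
  sl <- matrix(0, n, n)
  sl[d2 <= radius_px^2] <- value
  array(rep(sl, each = nz), dim = c(nz, n, n))
}

# Closed-form parallel projection of a uniform disk: value * chord length.
disk_chords <- function(n = 128, radius_px = 40, pitch = 3.5, value = 1) {
  s <- (seq_len(n) - (n + 1) / 2) * pitch
  R <- radius_px * pitch
  ifelse(abs(s) < R, 2 * value * sqrt(pmax(R^2 - s^2, 0)), 0)
}

make_refractive <- function(vol, delta, beta, pitch = 3.5) {
  structure(list(delta = vol * delta, beta = vol * beta,
                 voxel_pitch = pitch, energy_kev = 35),
            class = "refractive_volume")
}

# Closed-form Fresnel diffraction of a half-plane (support x' < 0):
# U_h(x) = (1 - i)/2 * (C(u) + i S(u) + (1 + i)/2), u = -x sqrt(2/(lambda z)),
# with C/S the Fresnel integrals. A phase step of phi0 on x < 0 then gives
# U = 1 + (exp(i phi0) - 1) U_h by superposition.
fresnel_phase_step <- function(x, phi0, z_um, lam_um) {
  u <- -x * sqrt(2 / (lam_um * z_um))
  Uh <- (1 - 1i) / 2 *
    (pracma::fresnelC(u) + 1i * pracma::fresnelS(u) + (1 + 1i) / 2)
  Mod(1 + (exp(1i * phi0) - 1) * Uh)^2
}

# Independent filtered backprojection: spatial-domain Ram-Lak convolution
# (linear, not circular) and approx()-based backprojection, zero outside
# the detector.
oracle_fbp <- function(sino, angles_deg, pitch) {
  nA <- nrow(sino); n <- ncol(sino)
  m <- -(n - 1):(n - 1)
  h <- ifelse(m == 0, 1 / (4 * pitch^2),
              ifelse(m %% 2 != 0, -1 / (pi * m * pitch)^2, 0))
  filt <- t(apply(sino, 1, function(p)
    convolve(p, rev(h), type = "open")[n:(2 * n - 1)] * pitch))
  s <- (seq_len(n) - (n + 1) / 2) * pitch
  xc <- s
  rec <- matrix(0, n, n)
  for (a in seq_len(nA)) {
    th <- angles_deg[a] * pi / 180
    tpos <- outer(xc * sin(th), xc * cos(th), `+`)
    v <- approx(s, filt[a, ], xout = as.vector(tpos), rule = 1)$y
    v[is.na(v)] <- 0
    rec <- rec + matrix(v, n, n)
  }
  rec * pi / nA
}

# Brute-force two-sided rank-sum p: enumerate every group assignment.
oracle_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  w_obs <- sum(r[seq_len(na)])
  mu <- na * (length(pooled) + 1) / 2
  ws <- combn(length(pooled), na, function(ix) sum(r[ix]))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# Noise-free stand-in for a reconstructed volume: per-label intensities
# plus a small deterministic texture.
fake_recon_from_labels <- function(labels, levels = c(`0` = 0, `1` = 0.02,
                                                      `2` = 1, `3` = 0.7,
                                                      `4` = 1.6),
                                   noise_sd = 0.02, seed = 99) {
  vol <- array(levels[as.character(as.integer(labels))], dim = dim(labels))
  set.seed(seed)
  vol + array(rnorm(length(vol), 0, noise_sd), dim = dim(vol))
}

# Full simulate -> retrieve -> reconstruct -> segment -> quantify chain,
# cached so several tests can score different aspects of one run.
.e2e_cache <- new.env(parent = emptyenv())
run_chain <- function(med_frac, hb_frac, n_lobules, seed,
                      n_angles = 180, gap = NULL) {
  key <- paste(med_frac, hb_frac, n_lobules, seed, n_angles, sep = "_")
  if (!is.null(.e2e_cache[[key]])) return(.e2e_cache[[key]])
  gap <- gap %||% if (n_lobules > 1) 14 else 0
  ph <- generate_thymus_phantom(phantom_params(
    grid_shape = c(64, 64, 64), n_lobules = n_lobules,
    target_medulla_frac = med_frac, target_hb_frac = hb_frac,
    interlobular_gap = gap, rng_seed = seed))
  rv <- assign_materials(ph)
  geom <- ct_geometry(n_angles = n_angles)
  pset <- acquire(rv, geom)
  mt <- material_table()
  db <- mt$delta[mt$name == "cortex"] / mt$beta[mt$name == "cortex"]
  tset <- retrieve_projections(pset, retrieval_params(db, geom))
  rec <- reconstruct_volume(tset)
  ann <- annotate_every_kth(ph, interval = 10)
  masks <- propagate_annotations(rec, ann, seed = 11)
  support <- masks$medulla | masks$hb
  hb <- segment_hbs(rec, support, reference_mask = masks$medulla)
  final <- compartment_masks(cortex = masks$cortex & !hb,
                             medulla = support & !hb, hb = hb)
  out <- list(phantom = ph, recon = rec, classifier_masks = masks,
              masks = final,
              medulla_pct = medulla_content(final, hb_in_medulla = TRUE),
              hb_pct = hb_content(final))
  .e2e_cache[[key]] <- out
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
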