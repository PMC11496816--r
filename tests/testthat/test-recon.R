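test_that("FBP is linear and recovers a uniform disk", {
  n <- 128; pitch <- 3.5; nA <- 360
  angles <- seq(0, 180, length.out = nA + 1)[1:nA]
  zero <- fbp_slice(matrix(0, nA, n), angles, pitch)
  expect_true(all(zero == 0))

  sino <- matrix(rep(disk_chords(n = n, radius_px = 40), each = nA), nA)
  rec <- fbp_slice(sino, angles, pitch)
  cc <- (n + 1) / 2
  rr <- sqrt(outer((seq_len(n) - cc)^2, (seq_len(n) - cc)^2, `+`)) * pitch
  R <- 40 * pitch
  expect_lt(abs(mean(rec[rr < 0.8 * R]) - 1), 0.02)
  expect_lt(abs(mean(rec[rr > 1.2 * R & rr < 1.55 * R])), 0.02)
  # linearity in the sinogram
  rec3 <- fbp_slice(3 * sino, angles, pitch)
  expect_equal(rec3, 3 * rec, tolerance = 1e-12)
})

test_that("FBP agrees with an independently coded oracle", {
  n <- 256; pitch <- 3.5; nA <- 720
  angles <- seq(0, 180, length.out = nA + 1)[1:nA]
  # numeric multi-ellipse phantom sinogram built from disk chords
  s <- (seq_len(n) - (n + 1) / 2) * pitch
  sino <- matrix(0, nA, n)
  chord <- function(s0, R, v) ifelse(abs(s - s0) < R,
                                     2 * v * sqrt(pmax(R^2 - (s - s0)^2, 0)),
                                     0)
  for (a in seq_len(nA)) {
    th <- angles[a] * pi / 180
    # three off-centre disks (centres rotate with the view angle)
    sino[a, ] <- chord(60 * cos(th), 80 * pitch, 1) +
      chord(-100 * sin(th + 0.4), 30 * pitch, 0.5) +
      chord(150 * cos(th - 1.1), 20 * pitch, -0.3)
  }
  rec <- fbp_slice(sino, angles, pitch)
  ora <- oracle_fbp(sino, angles, pitch)
  dr <- diff(range(ora))
  expect_lt(sqrt(mean((rec - ora)^2)) / dr, 0.01)
})

test_that("limited-angle and malformed angle sets are rejected", {
  expect_error(fbp_slice(matrix(0, 10, 16), seq(0, 90, length.out = 10), 3.5),
               "limited-angle")
  expect_error(fbp_slice(matrix(0, 3, 16), c(0, 10, 15), 3.5),
               "equally spaced")
  expect_error(fbp_slice(matrix(0, 1, 16), 0, 3.5), "at least 2")
})

test_that("a point phantom reconstructs at its true location", {
  set.seed(77)
  n <- 64; pitch <- 3.5
  g <- ct_geometry(prop_distance_m = 0, n_angles = 90)
  for (i in 1:25) {
    pos <- sample(12:52, 2)
    vol <- array(0, dim = c(1, n, n))
    vol[1, pos[1], pos[2]] <- 1
    rv <- make_refractive(vol, 0, 1e-9)
    tset <- retrieve_projections(acquire(rv, g),
                                 retrieval_params(0, g))
    rec <- reconstruct_volume(tset)$voxels[1, , ]
    peak <- which(rec == max(rec), arr.ind = TRUE)[1, ]
    expect_lte(max(abs(peak - pos)), 1)
  }
})

test_that("reconstruction commutes with a 90-degree phantom rotation", {
  ph <- generate_thymus_phantom(phantom_params(
    grid_shape = c(32, 48, 48), n_lobules = 2, rng_seed = 12))
  g <- ct_geometry(prop_distance_m = 0, n_angles = 180)
  recon_of <- function(lab) {
    rv <- assign_materials(lab, material_table(), voxel_pitch = 3.5)
    tset <- retrieve_projections(acquire(rv, g), retrieval_params(0, g))
    reconstruct_volume(tset)$voxels
  }
  lab <- ph$labels
  r1 <- recon_of(lab)
  lab90 <- array(0L, dim = dim(lab))
  for (z in seq_len(dim(lab)[1]))
    lab90[z, , ] <- t(lab[z, , ])[, rev(seq_len(dim(lab)[2]))]  # rotate 90
  r2 <- recon_of(lab90)
  r2back <- array(0, dim = dim(r2))
  for (z in seq_len(dim(r2)[1]))
    r2back[z, , ] <- t(r2[z, , rev(seq_len(dim(r2)[3]))])       # rotate back
  dr <- diff(range(r1))
  expect_lt(sqrt(mean((r1 - r2back)^2)) / dr, 0.01)
})

test_that("half-acquisition stitching has the right geometry and joins once", {
  # axis on the last detector column, zero overlap: width 2W - 1
  W <- 40
  g360 <- ct_geometry(n_angles = 8, angular_range = 360,
                      rotation_axis_offset = (W - 1) / 2)
  pset <- projection_set(array(1, dim = c(8, 2, W)),
                         projection_angles(g360), g360)
  st <- halfacq_stitch(pset)
  expect_equal(dim(st$data), c(4L, 2L, 2L * W - 1L))
  expect_equal(st$geometry$angular_range, 180)
  expect_true(all(abs(st$data - 1) < 1e-12))  # flat field stays flat

  # axis outside the frame fails
  gbad <- ct_geometry(n_angles = 8, angular_range = 360,
                      rotation_axis_offset = W)
  pbad <- projection_set(array(1, dim = c(8, 2, W)),
                         projection_angles(gbad), gbad)
  expect_error(halfacq_stitch(pbad), "outside")
})

test_that("stitched half-acquisition equals direct full-width simulation", {
  # mirror-symmetric object (centred cylinder); contact images isolate the
  # stitch geometry from propagation boundary effects
  rv <- make_refractive(cylinder_volume(n = 64, nz = 1, radius_px = 20),
                        1.05e-7, 2.1e-10)
  W <- 40
  ghalf <- ct_geometry(prop_distance_m = 0, n_angles = 120,
                       angular_range = 360,
                       rotation_axis_offset = (W - 1) / 2)
  gfull <- ct_geometry(prop_distance_m = 0, n_angles = 60,
                       angular_range = 180)
  st <- halfacq_stitch(acquire(rv, ghalf, det_width = W))
  direct <- acquire(rv, gfull, det_width = 2 * W - 1)
  expect_lt(max(abs(st$data - direct$data)), 1e-6)
})

test_that("half-acquisition reconstruction matches full-FOV reconstruction", {
  # asymmetric two-blob object
  lab <- array(0L, dim = c(1, 64, 64))
  for (y in 1:64) for (x in 1:64) {
    if ((y - 28)^2 + (x - 30)^2 < 14^2) lab[1, y, x] <- 2L
    if ((y - 40)^2 + (x - 38)^2 < 7^2) lab[1, y, x] <- 3L
  }
  rv <- assign_materials(lab, material_table(), voxel_pitch = 3.5)
  W <- 40
  ghalf <- ct_geometry(n_angles = 360, angular_range = 360,
                       rotation_axis_offset = (W - 1) / 2)
  gfull <- ct_geometry(n_angles = 180, angular_range = 180)
  db <- 500
  st <- halfacq_stitch(acquire(rv, ghalf, det_width = W))
  rec_s <- reconstruct_volume(retrieve_projections(
    st, retrieval_params(db, st$geometry)))
  direct <- acquire(rv, gfull, det_width = 2 * W - 1)
  rec_f <- reconstruct_volume(retrieve_projections(
    direct, retrieval_params(db, gfull)))
  dr <- diff(range(rec_f$voxels))
  expect_lt(sqrt(mean((rec_s$voxels - rec_f$voxels)^2)) / dr, 0.01)
})

test_that("vertical stitching is exact for identity and round-trip splits", {
  set.seed(21)
  vol <- recon_volume(array(rnorm(40 * 16 * 16), dim = c(40, 16, 16)), 3.5)
  expect_identical(vertical_stitch(list(vol), 0), vol)

  a <- recon_volume(vol$voxels[1:24, , , drop = FALSE], 3.5)
  b <- recon_volume(vol$voxels[17:40, , , drop = FALSE], 3.5)
  merged <- vertical_stitch(list(a, b), c(0, 16 * 3.5))
  expect_equal(dim(merged$voxels), dim(vol$voxels))
  expect_lt(max(abs(merged$voxels - vol$voxels)), 1e-6)

  # a deliberate +1-slice offset error is recovered by refinement
  merged2 <- vertical_stitch(list(a, b), c(0, 17 * 3.5), refine = TRUE)
  expect_equal(merged2$provenance$offset_corrections, c(0L, 1L))
  expect_lt(max(abs(merged2$voxels - vol$voxels)), 1e-6)

  # a gap between volumes fails with the missing range
  expect_error(vertical_stitch(list(a, b), c(0, 30 * 3.5)), "missing z range")
})
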