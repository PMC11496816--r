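test_that("line integrals match the closed-form chord length of a cylinder", {
  n <- 128
  rv <- make_refractive(cylinder_volume(n = n, radius_px = 40), 1e-7, 1e-10)
  truth <- disk_chords(n = n, radius_px = 40) * 1e-7
  for (ang in c(0, 30, 117)) {
    li <- line_integrals(rv, ang)
    expect_lt(max(abs(li$delta - truth)), 0.02 * max(truth))
  }
  # linearity in the maps and zero volume -> zero projections
  rv0 <- make_refractive(cylinder_volume(n = 64) * 0, 1, 1)
  li0 <- line_integrals(rv0, 45)
  expect_true(all(li0$delta == 0) && all(li0$beta == 0))
  rv2 <- make_refractive(cylinder_volume(n = n, radius_px = 40), 3e-7, 1e-10)
  expect_equal(line_integrals(rv2, 20)$delta, line_integrals(rv, 20)$delta * 3,
               tolerance = 1e-12)
})

test_that("a 180-degree rotation mirrors the projection", {
  set.seed(5)
  vol <- array(runif(1 * 48 * 48), dim = c(1, 48, 48))
  rv <- make_refractive(vol, 1e-7, 1e-10)
  p0 <- line_integrals(rv, 33)$delta
  p180 <- line_integrals(rv, 213)$delta
  expect_equal(p0, rev(p180), tolerance = 1e-12)
})

test_that("propagation reduces to Beer-Lambert at contact and to unity in air", {
  lam <- wavelength_at_35kev
  g0 <- ct_geometry(prop_distance_m = 0, n_angles = 4)
  bp <- matrix(2e-9, 8, 8)
  expect_equal(propagate(bp * 0, bp, g0),
               matrix(exp(-4 * pi * 2e-9 / lam), 8, 8), tolerance = 1e-15)
  g <- ct_geometry(n_angles = 4)
  expect_equal(propagate(matrix(0, 4, 64), matrix(0, 4, 64), g),
               matrix(1, 4, 64), tolerance = 1e-12)
})

test_that("the aliasing guard rejects undersampled propagation", {
  g <- ct_geometry(pixel_pitch_um = 0.1, n_angles = 4)  # Fresnel number ~8e-5
  expect_error(propagate(matrix(0, 4, 16), matrix(0, 4, 16), g),
               "Fresnel number")
})

test_that("edge fringes match the closed-form Fresnel half-plane solution", {
  lam <- wavelength_at_35kev
  g <- ct_geometry(n_angles = 4)  # 35 keV, 3.45 m
  z_um <- 3.45e6
  # fine pitch so the local chirp frequency stays below detector Nyquist
  # over the compared window (|x| < Nyquist * lambda * z ~ 70 um)
  n <- 1024; pitch <- 0.875
  g <- ct_geometry(pixel_pitch_um = pitch, n_angles = 4)
  phi0 <- 0.5  # radians on the left half-plane
  # step placed at a pixel boundary: columns with centre x < 0 carry phi0
  x <- (seq_len(n) - n / 2 - 0.5) * pitch
  phi_prof <- ifelse(x < 0, phi0, 0)
  delta_proj <- -phi_prof * lam / (2 * pi)
  I <- propagate(matrix(rep(delta_proj, each = 4), 4),
                 matrix(0, 4, n), g, fresnel_floor = 0.002)[2, ]
  If <- fresnel_phase_step(x, phi0, z_um, lam)
  inner <- abs(x) < 60 & abs(x) > 4 * pitch  # resolved fringe window
  expect_lt(sqrt(mean((I[inner] - If[inner])^2)), 0.01)
})

test_that("pure-phase propagation conserves energy for compact objects", {
  g <- ct_geometry(n_angles = 4)
  n <- 96
  x <- (seq_len(n) - (n + 1) / 2)
  blob <- exp(-outer(x^2, x^2, `+`) / (2 * 10^2))
  lam <- wavelength_at_35kev
  I <- propagate(blob * lam / (2 * pi) * 0.5, matrix(0, n, n), g)
  expect_lt(abs(mean(I) - 1), 1e-3)
})

test_that("propagation converges to the contact image as z shrinks", {
  n <- 96
  rv_prof <- disk_chords(n = n, radius_px = 25)
  dproj <- matrix(rep(rv_prof * 1e-7, each = 8), 8)
  bproj <- matrix(rep(rv_prof * 2e-10, each = 8), 8)
  lam <- wavelength_at_35kev
  contact <- exp(-4 * pi * bproj / lam)
  zs <- 3.45 / 2^(0:8)
  sup <- vapply(zs, function(z) {
    g <- ct_geometry(prop_distance_m = z, n_angles = 4)
    max(abs(propagate(dproj, bproj, g, fresnel_floor = 0) - contact))
  }, numeric(1))
  expect_lt(sup[length(sup)], 0.02)
  # broadly decreasing over the dyadic sweep
  expect_true(all(diff(log(sup[3:9])) < 0))
})

test_that("acquisition angles, determinism and noise statistics behave", {
  g <- ct_geometry(n_angles = 4, angular_range = 180)
  expect_equal(projection_angles(g), c(0, 45, 90, 135))
  g360 <- ct_geometry(n_angles = 8, angular_range = 360,
                      rotation_axis_offset = 10)
  expect_equal(projection_angles(g360), seq(0, 315, by = 45))

  rv <- make_refractive(cylinder_volume(n = 48, nz = 2, radius_px = 12),
                        1e-7, 2e-10)
  p1 <- acquire(rv, ct_geometry(n_angles = 6))
  p2 <- acquire(rv, ct_geometry(n_angles = 6))
  expect_identical(p1$data, p2$data)  # noiseless

  # 360-degree mode without an axis offset is a configuration error
  expect_error(acquire(rv, ct_geometry(n_angles = 8, angular_range = 360)),
               "rotation_axis_offset")

  # Poisson noise on an empty field: per-pixel variance ~ 1/N over >= 1e6 px
  empty <- make_refractive(array(0, dim = c(64, 64, 64)), 1, 1)
  gn <- ct_geometry(n_angles = 250, photon_count = 1e4)
  pn <- acquire(empty, gn, seed = 8)
  expect_gte(length(pn$data), 1e6)
  v <- stats::var(as.vector(pn$data))
  expect_lt(abs(v - 1e-4) / 1e-4, 0.10)
  # seeded noise is reproducible
  pn2 <- acquire(empty, gn, seed = 8)
  expect_identical(pn$data, pn2$data)
})
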