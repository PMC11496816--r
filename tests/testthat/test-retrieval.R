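test_that("the Paganin kernel has the analytic form and monotonicity", {
  g <- ct_geometry()
  p <- retrieval_params(500, g)
  lam <- wavelength_at_35kev
  expect_identical(paganin_filter_value(0, p), 1)
  p0 <- retrieval_params(0, g)
  f <- seq(0, 0.2, length.out = 200)
  expect_true(all(paganin_filter_value(f, p0) == 1))
  # closed form at arbitrary frequencies
  expect_equal(paganin_filter_value(f, p),
               1 / (1 + pi * lam * 3.45e6 * 500 * f^2), tolerance = 1e-12)
  # strictly decreasing in |f| and in delta/beta (dense sweep)
  H <- paganin_filter_value(f, p)
  expect_true(all(diff(H) < 0))
  for (fi in c(0.01, 0.05, 0.14)) {
    Hd <- vapply(c(10, 100, 500, 2000, 1e4), function(db)
      paganin_filter_value(fi, retrieval_params(db, g)), numeric(1))
    expect_true(all(diff(Hd) < 0))
  }
})

test_that("retrieval limits: unit intensity and Beer-Lambert inversion", {
  g <- ct_geometry()
  beta <- 2e-10
  p <- retrieval_params(500, g, beta = beta)
  expect_equal(retrieve_thickness(matrix(1, 16, 16), p),
               matrix(0, 16, 16), tolerance = 1e-12)
  # delta/beta = 0 on a contact image of a slab: exact thickness
  lam <- wavelength_at_35kev
  mu <- 4 * pi * beta / lam
  thick <- matrix(rep(c(0, 150, 150, 0), each = 8), 8)
  I <- exp(-mu * thick)
  g0 <- ct_geometry(prop_distance_m = 0)
  T0 <- retrieve_thickness(I, retrieval_params(0, g0, beta = beta))
  expect_equal(T0, thick, tolerance = 1e-9)
})

test_that("non-positive input or filtered intensity fails with diagnostics", {
  g <- ct_geometry()
  I <- matrix(1, 8, 8); I[3, 4] <- 0
  expect_error(retrieve_thickness(I, retrieval_params(100, g)),
               "non-positive intensity")
})

test_that("matched retrieval recovers the cylinder thickness profile", {
  n <- 128
  delta <- 1.05e-7; beta <- 2.1e-10
  rv <- make_refractive(cylinder_volume(n = n, radius_px = 40), delta, beta)
  g <- ct_geometry(n_angles = 4)
  li <- line_integrals(rv, 0)
  I <- propagate(matrix(rep(li$delta, each = 16), 16),
                 matrix(rep(li$beta, each = 16), 16), g)
  Tm <- retrieve_thickness(I, retrieval_params(delta / beta, g, beta = beta))
  truth <- disk_chords(n = n, radius_px = 40)
  rms <- sqrt(mean((Tm[8, ] - truth)^2))
  expect_lt(rms, 0.02 * 2 * 40 * 3.5)  # < 2% of the diameter
})

test_that("retrieval is log-linear: I^a yields a * T", {
  g <- ct_geometry()
  # exact in the attenuation limit
  I <- matrix(exp(-runif(64, 0, 0.1)), 8, 8)
  p0 <- retrieval_params(0, g)
  expect_equal(retrieve_thickness(I^2.5, p0),
               2.5 * retrieve_thickness(I, p0), tolerance = 1e-10)
  # to first order for a weak-contrast image under filtering
  set.seed(1)
  Iw <- 1 + 0.01 * matrix(rnorm(32 * 32), 32)
  p <- retrieval_params(300, g)
  expect_equal(retrieve_thickness(Iw^2, p), 2 * retrieve_thickness(Iw, p),
               tolerance = 0.01)
})

test_that("retrieve-then-repropagate closes the loop for smooth objects", {
  # self-consistency: a single-material object with gentle gradients is
  # reproduced by pushing the retrieved map back through the forward model
  n <- 96
  delta <- 1.05e-7; beta <- 2.1e-10
  x <- seq_len(n) - (n + 1) / 2
  # gentle thickness blob (phase well under a radian), the regime the
  # single-distance linearisation is designed for
  blob <- 15 * exp(-outer(x^2, x^2, `+`) / (2 * 12^2))
  g <- ct_geometry(n_angles = 4)
  I <- propagate(blob * delta, blob * beta, g)
  Tm <- retrieve_thickness(I, retrieval_params(delta / beta, g, beta = beta))
  I2 <- propagate(Tm * delta, Tm * beta, g)
  expect_lt(sqrt(mean((I2 - I)^2)), 0.02)
})

test_that("adaptive selection finds the matched ratio and applies the tie rule", {
  n <- 128
  delta <- 1.05e-7; beta <- 2.1e-10
  true_db <- delta / beta
  rv <- make_refractive(cylinder_volume(n = n, radius_px = 40), delta, beta)
  g <- ct_geometry(n_angles = 4)
  li <- line_integrals(rv, 0)
  I <- propagate(matrix(rep(li$delta, each = 16), 16),
                 matrix(rep(li$beta, each = 16), 16), g)
  sel <- adaptive_delta_beta(I, c(true_db / 4, true_db, 4 * true_db), g)
  expect_equal(sel$delta_beta, true_db)
  expect_equal(nrow(sel$scores), 3L)

  # constant image: identical scores, tie flagged, lowest candidate wins
  expect_message(
    sel2 <- adaptive_delta_beta(matrix(1, 8, 16), c(100, 500), g),
    "tie")
  expect_true(sel2$tie)
  expect_equal(sel2$delta_beta, 100)

  # single candidate: returned with a degenerate table
  sel3 <- adaptive_delta_beta(I, 500, g)
  expect_equal(sel3$delta_beta, 500)
  expect_equal(nrow(sel3$scores), 1L)
})
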