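test_that("phantom generation is deterministic and hits its fraction targets", {
  p <- phantom_params(target_medulla_frac = 0.38, target_hb_frac = 0,
                      n_lobules = 1, rng_seed = 1)
  ph1 <- generate_thymus_phantom(p)
  ph2 <- generate_thymus_phantom(p)
  expect_identical(ph1$labels, ph2$labels)
  # foetal-stage generating parameter: realised fraction in [0.35, 0.41]
  expect_gte(ph1$realized$medulla_frac, 0.35)
  expect_lte(ph1$realized$medulla_frac, 0.41)
  expect_equal(sum(ph1$labels == PHANTOM_LABELS[["hb"]]), 0)

  ph3 <- generate_thymus_phantom(phantom_params(
    n_lobules = 4, target_medulla_frac = 0.38, target_hb_frac = 0.25,
    interlobular_gap = 14, rng_seed = 2))
  expect_lt(abs(ph3$realized$medulla_frac - 0.38), 0.03)
  expect_lt(abs(ph3$realized$hb_frac - 0.25), 0.03)
})

test_that("reported label counts equal an independent voxel scan", {
  ph <- generate_thymus_phantom(phantom_params(
    n_lobules = 3, target_hb_frac = 0.15, interlobular_gap = 10,
    rng_seed = 7))
  counts <- ph$label_counts
  for (nm in names(PHANTOM_LABELS)) {
    brute <- sum(as.vector(ph$labels) == PHANTOM_LABELS[[nm]])
    expect_identical(unname(counts[[nm]]), as.numeric(brute))
  }
  expect_identical(sum(counts), prod(dim(ph$labels)) + 0)
})

test_that("raising the medulla target never lowers the realised fraction", {
  targets <- c(0.1, 0.22, 0.38, 0.5, 0.65)
  realized <- vapply(targets, function(tt) {
    generate_thymus_phantom(phantom_params(
      grid_shape = c(40, 40, 40), n_lobules = 2, target_medulla_frac = tt,
      interlobular_gap = 8, rng_seed = 42))$realized$medulla_frac
  }, numeric(1))
  expect_true(all(diff(realized) >= 0))
})

test_that("HB voxels are confined to the medulla support across many seeds", {
  set.seed(1234)
  for (seed in 1:100) {
    ph <- generate_thymus_phantom(phantom_params(
      grid_shape = c(64, 64, 64), n_lobules = sample(1:5, 1),
      target_medulla_frac = runif(1, 0.2, 0.45),
      target_hb_frac = runif(1, 0.05, 0.3),
      interlobular_gap = sample(c(0, 10), 1), rng_seed = seed))
    hb <- ph$labels == PHANTOM_LABELS[["hb"]]
    med <- ph$labels == PHANTOM_LABELS[["medulla"]]
    # every HB voxel must sit inside the (HB-inclusive) medulla support:
    # a dilation of hb by one voxel may only meet medulla, hb or more hb
    dm <- dim(ph$labels)
    idx <- which(hb, arr.ind = TRUE)
    for (d in 1:3) for (off in c(-1L, 1L)) {
      nb <- idx
      nb[, d] <- pmin(pmax(nb[, d] + off, 1L), dm[d])
      touches <- ph$labels[nb]
      expect_true(all(touches %in% PHANTOM_LABELS[c("medulla", "hb",
                                                    "cortex")]))
    }
    expect_true(all(hb[!med & !hb] == FALSE))
  }
})

test_that("the medulla is surrounded by cortex, not by background or gap", {
  ph <- generate_thymus_phantom(phantom_params(
    n_lobules = 4, target_medulla_frac = 0.38, interlobular_gap = 14,
    rng_seed = 3))
  med <- ph$labels == PHANTOM_LABELS[["medulla"]]
  dm <- dim(ph$labels)
  idx <- which(med, arr.ind = TRUE)
  for (d in 1:3) for (off in c(-1L, 1L)) {
    nb <- idx
    nb[, d] <- pmin(pmax(nb[, d] + off, 1L), dm[d])
    expect_false(any(ph$labels[nb] %in% PHANTOM_LABELS[c("background",
                                                         "gap")]))
  }
})

test_that("infeasible targets fail loudly instead of clamping", {
  expect_error(phantom_params(target_medulla_frac = 1.2), "target_medulla_frac")
  expect_error(phantom_params(n_lobules = 0), "n_lobules")
  expect_error(phantom_params(grid_shape = c(16, 64, 64)), ">= 32")
  # HB requested but no medulla to put it in
  expect_error(generate_thymus_phantom(phantom_params(
    target_medulla_frac = 0, target_hb_frac = 0.2, rng_seed = 1)),
    "infeasible")
})

test_that("material assignment is an exact per-voxel lookup", {
  tab <- material_table()
  # all-background phantom -> identically zero maps
  bg <- array(0L, dim = c(32, 32, 32))
  rv0 <- assign_materials(bg, tab, voxel_pitch = 3.5)
  expect_true(all(rv0$delta == 0) && all(rv0$beta == 0))

  ph <- generate_thymus_phantom(phantom_params(rng_seed = 4))
  rv <- assign_materials(ph, tab)
  lut_d <- setNames(tab$delta, tab$label)
  lut_b <- setNames(tab$beta, tab$label)
  expect_equal(as.vector(rv$delta),
               unname(lut_d[as.character(as.vector(ph$labels))]))
  expect_equal(as.vector(rv$beta),
               unname(lut_b[as.character(as.vector(ph$labels))]))

  # cortex delta set to twice the medulla delta -> exact voxelwise ratio 2
  tab2 <- material_table(delta = c(cortex = 2e-7, medulla = 1e-7))
  rv2 <- assign_materials(ph, tab2)
  cor_vals <- rv2$delta[ph$labels == PHANTOM_LABELS[["cortex"]]]
  med_vals <- rv2$delta[ph$labels == PHANTOM_LABELS[["medulla"]]]
  expect_true(all(cor_vals == 2e-7) && all(med_vals == 1e-7))

  # missing label entry -> error naming the label
  tab3 <- tab[tab$label != 3, ]
  expect_error(assign_materials(ph, tab3), "3")
})

test_that("phantom TIFF + YAML round-trip is bit-exact", {
  ph <- generate_thymus_phantom(phantom_params(
    grid_shape = c(32, 40, 48), n_lobules = 2, target_hb_frac = 0.1,
    interlobular_gap = 10, rng_seed = 9))
  path <- file.path(withr::local_tempdir(), "labels.tif")
  write_phantom(ph, path)
  ph2 <- read_phantom(path)
  expect_identical(ph2$labels, ph$labels)
  expect_equal(unclass(ph2$params), unclass(ph$params))
  expect_equal(ph2$realized, ph$realized)
})
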