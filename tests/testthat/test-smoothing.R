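test_that("layer smoothing is a partition of unity and respects layers", {
  set.seed(21)
  dims <- c(10, 10, 8)
  lay <- array(0L, dim = dims)
  lay[2:9, 2:9, 2:4] <- 1L
  lay[2:9, 2:9, 5:7] <- 2L

  cst <- layer_smooth(array(3.7, dim = dims), lay, fwhm = 3)
  expect_lt(max(abs(cst$data - 3.7)), 1e-12)

  # impulse response support never leaves the source layer
  imp <- array(0, dim = dims)
  imp[5, 5, 4] <- 1  # layer 1
  sm <- layer_smooth(imp, lay, fwhm = 4)
  expect_true(all(sm$data[lay == 2L] == 0))
  expect_gt(sm$data[5, 5, 3], 0)

  # voxel alone in its layer keeps its value at any FWHM
  lay2 <- lay
  lay2[5, 5, 4] <- 9L
  sm2 <- layer_smooth(imp, lay2, fwhm = 8)
  expect_equal(sm2$data[5, 5, 4], 1)

  # unlabeled voxels pass through untouched
  x <- array(rnorm(prod(dims)), dim = dims)
  sm3 <- layer_smooth(x, lay, fwhm = 2)
  expect_equal(sm3$data[lay == 0L], x[lay == 0L])
})

test_that("layer smoothing matches the brute-force kernel oracle", {
  set.seed(22)
  dims <- c(9, 8, 7)
  vs <- c(0.7, 1.0, 1.3)
  lay <- array(sample(0:2, prod(dims), replace = TRUE), dim = dims)
  x <- array(rnorm(prod(dims)), dim = dims)
  for (fwhm in c(1, 2.5)) {
    got <- layer_smooth(voxel_grid(x, voxel_size = vs), lay, fwhm = fwhm)
    want <- bf_layer_smooth(x, lay, vs, fwhm)
    expect_lt(max(abs(got$data - want)), 1e-12)
  }
})

test_that("1D triple against the closed-form Gaussian weights", {
  # voxels at -1, 0, +1 mm in one layer, values (0, 1, 0), FWHM 2 mm:
  # center output = 1 / (1 + 2 * exp(-1 / (2 sigma^2)))
  a <- array(0, dim = c(3, 1, 1))
  a[2, 1, 1] <- 1
  lay <- array(1L, dim = c(3, 1, 1))
  sigma <- 2 / (2 * sqrt(2 * log(2)))
  w1 <- exp(-1 / (2 * sigma^2))
  w2 <- exp(-4 / (2 * sigma^2))
  got <- layer_smooth(a, lay, fwhm = 2)
  expect_equal(got$data[2, 1, 1], 1 / (1 + 2 * w1), tolerance = 1e-12)
  # edge voxel additionally sees the far end at distance 2
  expect_equal(got$data[1, 1, 1], w1 / (1 + w1 + w2), tolerance = 1e-12)
})

test_that("NoKissing blocks transfer across a one-voxel CSF gap", {
  ph <- make_rim_phantom("kissing_gyri", shape = c(10, 10, 16),
                         thickness = 4)
  dims <- dim(ph$rim$data)
  lay <- array(0L, dim = dims)
  lay[ph$rim$data == 3] <- 1L  # single depth bin: worst case for leakage
  x <- array(0, dim = dims)
  x[, , ph$truth$slab_a_gm] <- 1
  plain <- layer_smooth(x, lay, fwhm = 4)
  guarded <- layer_smooth(x, lay, fwhm = 4, no_kissing = TRUE)
  b <- ph$truth$slab_b_gm
  expect_gt(max(plain$data[, , b]), 0)            # unflagged run leaks
  expect_equal(max(abs(guarded$data[, , b])), 0)  # flagged run does not
  expect_equal(guarded$data[, , ph$truth$slab_a_gm],
               x[, , ph$truth$slab_a_gm])
})

test_that("gradient smoothing reduces to Gaussian for flat contrast", {
  set.seed(23)
  dims <- c(8, 8, 6)
  x <- array(rnorm(prod(dims)), dim = dims)
  lay1 <- array(1L, dim = dims)
  flat_grad <- array(5, dim = dims)
  gs <- grad_smooth(x, flat_grad, fwhm = 2, selectivity = 0.08)
  iso <- layer_smooth(x, lay1, fwhm = 2)  # same Gaussian, whole volume
  expect_lt(max(abs(gs$data - iso$data)), 1e-12)
  expect_true(all(attr(gs, "flat_window")))

  # constant data unchanged regardless of the contrast image
  g2 <- array(rnorm(prod(dims)), dim = dims)
  cst <- grad_smooth(array(2, dim = dims), g2, fwhm = 3)
  expect_lt(max(abs(cst$data - 2)), 1e-12)
})

test_that("gradient smoothing matches brute force and preserves edges", {
  set.seed(24)
  dims <- c(10, 9, 1)
  x <- array(rnorm(prod(dims)), dim = dims)
  g <- array(rnorm(prod(dims), sd = 2), dim = dims)
  got <- grad_smooth(x, g, fwhm = 2, selectivity = 0.3)
  want <- bf_grad_smooth(x, g, c(1, 1, 1), 2, 0.3)
  expect_lt(max(abs(got$data - want)), 1e-12)

  # step-edge contrast, indicator input: contamination below 1e-3
  dims2 <- c(16, 8, 1)
  gstep <- array(rep(c(0, 100), each = 8), dim = dims2)
  ind <- array(as.numeric(gstep == 0), dim = dims2)
  sm <- grad_smooth(ind, gstep, fwhm = 2, selectivity = 0.08)
  expect_lt(max(sm$data[9:16, , 1]), 1e-3)
  expect_error(grad_smooth(ind, gstep, fwhm = 2, selectivity = 0),
               "selectivity")
})
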