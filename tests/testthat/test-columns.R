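# a 2D cortical strip: GM 5 voxels thick, 30 voxels long, single slice
strip_fixture <- function(nx = 30) {
  ph <- make_rim_phantom("flat_slab", shape = c(nx, 9, 1), thickness = 5,
                         normal_axis = 2)
  res <- layerify(ph$rim, n_layers = 5, metric = "equidist")
  list(ph = ph, res = res)
}

test_that("columnar distances grow from the landmark along the ribbon", {
  fx <- strip_fixture()
  gm_rows <- fx$ph$truth$gm_rows
  mid <- gm_rows[3]
  cd <- columnar_distances(fx$ph$rim, fx$res$metrics,
                           landmark = c(0, mid - 1, 0))
  expect_equal(cd$landmark, c(0, mid - 1, 0))
  ok <- !is.na(cd$distance)
  expect_equal(sum(ok), sum(fx$ph$rim$data == 3))
  # origin is (near) zero; smoothing may pull in tiny mass from neighbors
  expect_lt(cd$distance[1, mid, 1], 0.5)
  expect_equal(cd$column_bin[1, mid, 1], 1L)
  # far end of a straight strip: arc length within 5% of the oracle (29)
  expect_lt(abs(cd$distance[30, mid, 1] - 29) / 29, 0.05)
  # one-voxel bins when n_columns is absent: 30 bins on a 30-voxel strip
  expect_equal(max(cd$column_bin, na.rm = TRUE), 30L)

  # equal-width middle-layer bins when n_columns is given
  cd6 <- columnar_distances(fx$ph$rim, fx$res$metrics,
                            landmark = c(0, mid - 1, 0), n_columns = 6)
  tabs <- table(cd6$column_bin[cbind(1:30, mid, 1)])
  expect_equal(length(tabs), 6L)
  expect_lte(max(tabs) - min(tabs), 1)
})

test_that("columnar growth never jumps across a CSF gap", {
  # two kissing slabs: landmark in slab A must leave slab B unassigned
  ph <- make_rim_phantom("kissing_gyri", shape = c(12, 12, 16),
                         thickness = 4)
  res <- layerify(ph$rim, n_layers = 4, metric = "equidist")
  mid_a <- ph$truth$slab_a_gm[2]
  expect_warning(
    cd <- columnar_distances(ph$rim, res$metrics,
                             landmark = c(0, 0, mid_a - 1)),
    "not reachable")
  expect_true(all(is.na(cd$distance[, , ph$truth$slab_b_gm])))
  expect_true(all(!is.na(cd$distance[, , ph$truth$slab_a_gm])))
})

test_that("off-band landmarks snap to the middle-depth band", {
  fx <- strip_fixture()
  gm_rows <- fx$ph$truth$gm_rows
  expect_message(
    cd <- columnar_distances(fx$ph$rim, fx$res$metrics,
                             landmark = c(0, gm_rows[1] - 1, 0)),
    "snapped")
  expect_equal(sum(!is.na(cd$distance)), sum(fx$ph$rim$data == 3))
})

test_that("flattening copies values, averages collisions, keeps counts", {
  fx <- strip_fixture()
  gm <- fx$ph$rim$data == 3
  mid <- fx$ph$truth$gm_rows[3]
  cd <- columnar_distances(fx$ph$rim, fx$res$metrics,
                           landmark = c(0, mid - 1, 0))
  src <- array(rnorm(prod(dim(fx$ph$rim$data))), dim = dim(fx$ph$rim$data))
  lay <- fx$res$metrics
  other <- array(1L, dim = dim(src))  # trivial second axis
  fl <- flatten_imagiro(src, cd, other, lay,
                        flat_shape = c(30, 1, 5))
  # value conservation: every GM voxel contributes exactly once
  expect_equal(sum(fl$count), sum(gm))
  # the strip maps 1:1 (one voxel per column x layer): permutation of values
  expect_true(all(fl$count[!is.na(fl$flat$data)] == 1))
  expect_equal(sort(fl$flat$data[!is.na(fl$flat$data)]), sort(src[gm]))

  # two voxels in one cell average (2 + 4) / 2 = 3 with count 2
  v <- array(0, dim = c(2, 1, 1))
  v[1, 1, 1] <- 2; v[2, 1, 1] <- 4
  b1 <- array(1L, dim = dim(v)); b2 <- b1; b3 <- b1
  fl2 <- flatten_imagiro(v, b1, b2, b3, flat_shape = c(1, 1, 1))
  expect_equal(fl2$flat$data[1, 1, 1], 3)
  expect_equal(fl2$count[1, 1, 1], 2L)

  expect_error(flatten_imagiro(src, cd, other, lay,
                               flat_shape = c(10, 1, 5)),
               "flat_shape")
})

test_that("radially symmetric input flattens to constant rows", {
  ph <- make_rim_phantom("annulus_2d", shape = c(70, 70, 1), r1 = 12,
                         r2 = 28)
  res <- layerify(ph$rim, n_layers = 4, metric = "equidist")
  m <- res$metrics
  gm <- m$gm_mask
  # signal depends only on depth -> each (fixed layer) flat row constant
  src <- array(0, dim = dim(gm))
  src[gm] <- sin(2 * pi * m$equidist[gm])
  mid <- which(gm & abs(m$equidist - 0.5) <= 0.15, arr.ind = TRUE)
  cd <- columnar_distances(ph$rim, m, landmark = mid[1, ] - 1L,
                           n_columns = 12)
  other <- array(1L, dim = dim(src))
  fl <- flatten_imagiro(src, cd, other, m, flat_shape = c(12, 1, 4))
  for (k in 1:4) {
    row <- fl$flat$data[, 1, k]
    row <- row[!is.na(row)]
    expect_lt(diff(range(row)), 0.35)  # quantization-limited spread
  }
})
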