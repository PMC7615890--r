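test_that("geodesic depths are exact on the flat slab and respect sources", {
  ph <- make_rim_phantom("flat_slab", shape = c(7, 7, 12), thickness = 5)
  d <- grow_geodesic_depths(ph$rim)
  gm <- which(d$gm_mask)
  # one-voxel steps along the slab normal: d_inner = row index in mm
  for (j in seq_len(5)) {
    sel <- ph$truth$gm_rows[j]
    expect_equal(unname(d$d_inner[4, 4, sel]), j)
    expect_equal(unname(d$d_outer[4, 4, sel]), 6 - j)
  }
  expect_equal(d$thickness[gm], d$d_inner[gm] + d$d_outer[gm])
  expect_error(grow_geodesic_depths(voxel_grid(array(3, c(3, 3, 3)))),
               "code-1")
})

test_that("geodesic growth never crosses the CSF gap between kissing gyri", {
  ph <- make_rim_phantom("kissing_gyri", shape = c(8, 8, 16), thickness = 4)
  d <- grow_geodesic_depths(ph$rim)
  # slab B's inner border is on the far side; if growth leaked across the
  # gap, slab B's d_inner would be smaller than its in-slab depth
  for (j in seq_along(ph$truth$slab_b_gm)) {
    z <- ph$truth$slab_b_gm[j]
    expect_equal(unname(d$d_inner[4, 4, z]), length(ph$truth$slab_b_gm) + 1 - j)
  }
})

test_that("equi-distant metric follows d_inner / thickness with guards", {
  ph <- make_rim_phantom("flat_slab", shape = c(6, 6, 11), thickness = 6)
  m <- compute_equidist(grow_geodesic_depths(ph$rim))
  gm <- m$gm_mask
  expect_true(all(m$equidist[gm] >= 0 & m$equidist[gm] <= 1))
  expect_equal(m$equidist[gm], ph$truth$equidist[gm])
  # mid-depth symmetry: d_inner == d_outer -> 0.5
  mid <- ph$truth$gm_rows[3] + 0  # thickness 6: rows 3 and 4 straddle 0.5
  expect_equal(unname(m$equidist[3, 3, ph$truth$gm_rows[3]]), 3 / 7)

  # direct formula case: d_inner 1, d_outer 3 -> 0.25
  ph3 <- make_rim_phantom("flat_slab", shape = c(5, 5, 9), thickness = 3)
  df <- grow_geodesic_depths(ph3$rim)
  v <- which(df$gm_mask & df$d_inner == 1 & df$d_outer == 3)
  expect_true(length(v) > 0)
  expect_equal(compute_equidist(df)$equidist[v][1], 0.25)
})

test_that("equidist increases monotonically along annulus rays", {
  ph <- make_rim_phantom("annulus_2d", shape = c(70, 70, 1), r1 = 12,
                         r2 = 28)
  m <- compute_equidist(grow_geodesic_depths(ph$rim))
  r <- ph$truth$radius
  # sample rays at several angles; equidist must be non-decreasing in radius
  for (ang in seq(0, 2 * pi, length.out = 13)[-13]) {
    rr <- seq(12.5, 27.5, by = 0.5)
    ix <- pmin(pmax(round(35.5 + rr * cos(ang)), 1), 70)
    iy <- pmin(pmax(round(35.5 + rr * sin(ang)), 1), 70)
    vals <- m$equidist[cbind(ix, iy, 1)]
    vals <- vals[!is.na(vals)]
    expect_true(all(diff(vals) >= -1e-9))
  }
})

test_that("unit columns partition gray matter and classify curvature", {
  # flat slab: every column is a single vertical stack -> straight
  ph <- make_rim_phantom("flat_slab", shape = c(6, 6, 11), thickness = 5)
  d <- grow_geodesic_depths(ph$rim)
  uc <- build_unit_columns(ph$rim, d)
  expect_equal(sum(uc$columns$n_members), sum(ph$rim$data == 3))
  expect_true(all(uc$columns$curvature_class == "straight"))
  expect_true(all(uc$columns$n_inner_touched == 1))
  expect_true(all(uc$columns$n_outer_touched == 1))
  expect_equal(nrow(uc$columns), 36)  # one column per (x, y) stack

  # convex ring (outer surface longer): gyrus-type voxels dominate;
  # swapping the borders turns the same geometry sulcus-dominated
  counts <- lapply(c(FALSE, TRUE), function(sw) {
    ph2 <- make_rim_phantom("annulus_2d", shape = c(90, 90, 1), r1 = 20,
                            r2 = 40, swap_borders = sw)
    d2 <- grow_geodesic_depths(ph2$rim)
    uc2 <- build_unit_columns(ph2$rim, d2)
    expect_equal(sum(uc2$columns$n_members), sum(ph2$rim$data == 3))
    tapply(uc2$columns$n_members, uc2$columns$curvature_class, sum)
  })
  expect_gt(counts[[1]][["gyrus"]], counts[[1]][["sulcus"]])
  expect_gt(counts[[2]][["sulcus"]], counts[[2]][["gyrus"]])
})

test_that("equi-volume equals equi-distant on flat slabs (fixed point)", {
  for (vs in list(c(1, 1, 1), c(0.5, 0.5, 1))) {
    ph <- make_rim_phantom("flat_slab", shape = c(6, 6, 12), thickness = 6,
                           voxel_size = vs)
    res <- layerify(ph$rim, n_layers = 3)
    gm <- res$metrics$gm_mask
    expect_lt(max(abs(res$metrics$equivol[gm] - res$metrics$equidist[gm])),
              1e-12)
  }
})

test_that("equi-volume is a strictly increasing simplex perturbation", {
  ph <- make_rim_phantom("annulus_2d", shape = c(70, 70, 1), r1 = 12,
                         r2 = 28)
  res <- layerify(ph$rim, n_layers = 2, smooth_iters = 0)
  m <- res$metrics
  gm <- which(m$gm_mask & !is.na(m$equivol))
  expect_true(all(m$equivol[gm] >= 0 & m$equivol[gm] <= 1))
  # within every column, ordering by equidist implies ordering by equivol
  cid <- res$columns$column_id
  for (cc in sample(unique(cid[gm]), 20)) {
    v <- gm[cid[gm] == cc]
    o <- order(m$equidist[v])
    ev <- m$equivol[v][o]
    eq <- m$equidist[v][o]
    expect_true(all(diff(ev)[diff(eq) > 0] > 0))
  }
})

test_that("single-column simplex balance: symmetric depths give no push", {
  # synthesize a rim with one 4-voxel column; equidist {0.2,0.4,0.6,0.8}
  a <- array(0L, dim = c(3, 3, 7))
  a[2, 2, 1] <- 1L
  a[2, 2, 2:5] <- 3L
  a[2, 2, 6] <- 2L
  res <- layerify(voxel_grid(a), n_layers = 2, smooth_iters = 0)
  fac <- attr(res$metrics, "factors")
  expect_equal(fac$m_star, 0.5)
  gm <- res$metrics$gm_mask
  expect_equal(res$metrics$equivol[gm], res$metrics$equidist[gm])
})

test_that("layer quantization uses half-open bins and partitions GM", {
  ph <- make_rim_phantom("flat_slab", shape = c(5, 5, 11), thickness = 6)
  res <- layerify(ph$rim, n_layers = 3, metric = "equidist")
  m <- res$metrics
  gm <- m$gm_mask
  # thickness 6, 3 layers -> exactly 2 voxels per layer per column
  tab <- table(m$layer_id[gm])
  expect_equal(as.integer(tab), rep(2 * 25, 3))
  expect_equal(sum(tab), sum(gm))

  # bin arithmetic and clamping
  mm <- m
  mm$equidist[gm][1] <- 0.5
  mm$equidist[gm][2] <- 1.0
  mm <- quantize_layers(mm, 3, "equidist")
  expect_equal(mm$layer_id[gm][1], 2L)
  expect_equal(mm$layer_id[gm][2], 3L)  # metric 1.0 clamps to top layer
  one <- quantize_layers(m, 1, "equidist")
  expect_true(all(one$layer_id[gm] == 1L))
  expect_error(quantize_layers(m, 0), "count")
})

test_that("a single-slice volume reproduces the embedded 2D computation", {
  ph2d <- make_rim_phantom("annulus_2d", shape = c(60, 60, 1), r1 = 10,
                           r2 = 24)
  d2 <- grow_geodesic_depths(ph2d$rim)
  # extrude to 3 identical slices: in-plane geodesics cannot be shortened
  # by out-of-plane detours, so every slice must match the 2D field
  a3 <- array(rep(ph2d$rim$data, 3), dim = c(60, 60, 3))
  d3 <- grow_geodesic_depths(voxel_grid(a3))
  for (z in 1:3)
    expect_equal(d3$d_inner[, , z], d2$d_inner[, , 1], tolerance = 1e-12)
})
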