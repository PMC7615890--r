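test_that("leakage model structure follows the CBVv ratio rule", {
  # uniform CBVv: pure cumulative-sum operator, unit scaling
  mu <- build_leakage_model(c(2, 2, 2))
  expect_equal(mu$A, matrix(c(1, 1, 1, 0, 1, 1, 0, 0, 1), 3))
  expect_equal(mu$s, rep(1, 3))

  # K = 2, c = (1, 2): direct evaluation of the stated rule
  m2 <- build_leakage_model(c(1, 2))
  expect_equal(m2$A, matrix(c(1, 0.5, 0, 1), 2))
  expect_equal(m2$s, c(2 / 3, 4 / 3))

  # structural invariants for random valid weights
  set.seed(51)
  for (rep in 1:10) {
    K <- sample(2:8, 1)
    mod <- build_leakage_model(runif(K, 0.2, 3))
    expect_equal(diag(mod$A), rep(1, K))
    expect_true(all(mod$A[upper.tri(mod$A)] == 0))
    expect_true(all(mod$A >= 0))
    expect_equal(mean(mod$s), 1)
  }
  expect_error(build_leakage_model(c(1, 0)), "positive")
})

test_that("leakage deconvolution inverts the forward mixing exactly", {
  set.seed(52)
  for (rep in 1:25) {
    K <- sample(2:9, 1)
    mod <- build_leakage_model(runif(K, 0.2, 3))
    m <- rnorm(K)
    S <- as.numeric(mod$A %*% m)
    expect_lt(max(abs(devein_leakage(S, mod) - m)), 1e-12)
  }
  # cumulative leakage of a flat profile comes back flat
  mu <- build_leakage_model(rep(1, 5))
  S <- as.numeric(mu$A %*% rep(2, 5))  # strictly increasing to the surface
  expect_true(all(diff(S) > 0))
  expect_lt(max(abs(devein_leakage(S, mu) - 2)), 1e-12)
  # identity model leaves profiles unchanged
  eye <- build_leakage_model(rep(1, 4))
  eye$A <- diag(4)
  expect_equal(devein_leakage(c(1, 3, 2, 5), eye), c(1, 3, 2, 5))
  expect_error(devein_leakage(1:3, build_leakage_model(c(1, 2))), "match")
})

test_that("scaling correction removes a pure layer-dependent gain", {
  mod <- build_leakage_model(c(1, 2))
  expect_equal(devein_scaling(c(1, 4), mod), c(1.5, 3.0))
  # S = alpha * s flattens to alpha; s == 1 leaves input unchanged
  set.seed(53)
  mod5 <- build_leakage_model(runif(5, 0.5, 2))
  expect_equal(devein_scaling(3.2 * mod5$s, mod5), rep(3.2, 5))
  expect_equal(devein_scaling(c(2, 1, 4), build_leakage_model(rep(1, 3))),
               c(2, 1, 4))
  # exactly invertible
  S <- rnorm(5)
  expect_equal(devein_scaling(S, mod5) * mod5$s, S)
})

test_that("linear offset removal annihilates trends and is idempotent", {
  expect_equal(devein_linear(2 * (1:6) - 3), rep(0, 6))
  expect_equal(devein_linear(rep(4, 5)), rep(0, 5))
  # trend + symmetric double bump: bump recovered up to its mean
  K <- 9
  x <- seq_len(K)
  bump <- dnorm(x, 3, 0.8) + dnorm(x, 7, 0.8)
  prof <- 5 + 0.7 * x + bump
  got <- devein_linear(prof)
  want <- bump - mean(bump)  # bump is symmetric: no linear component
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(devein_linear(got), got, tolerance = 1e-12)
  expect_error(devein_linear(c(1, 2)), "3")
})

test_that("all three corrections are linear operators on profiles", {
  set.seed(54)
  mod <- build_leakage_model(runif(6, 0.3, 2))
  f <- list(function(p) devein_leakage(p, mod),
            function(p) devein_scaling(p, mod),
            devein_linear)
  for (fn in f) for (rep in 1:5) {
    p1 <- rnorm(6); p2 <- rnorm(6); a <- rnorm(1)
    expect_equal(fn(p1 + a * p2), fn(p1) + a * fn(p2), tolerance = 1e-10)
  }
})

test_that("voxel-wise deveining broadcasts the 1D corrections", {
  lk <- make_leaky_volume(3, m = c(2, 1, 3), cbv = c(1, 2, 3),
                          n_columns = 1)
  out <- devein_voxelwise(lk$vol, lk$layer_id, method = "leakage",
                          cbv = c(1, 2, 3), roi = lk$column_id)
  expect_equal(out$data[1, 1, ], as.numeric(lk$truth), tolerance = 1e-12)

  # forward-simulated leaky volume, many columns, noiseless
  set.seed(55)
  M <- matrix(rnorm(4 * 12, mean = 3), 4, 12)
  lk2 <- make_leaky_volume(4, m = M, cbv = c(0.8, 1, 1.5, 2),
                           n_columns = 12)
  out2 <- devein_voxelwise(lk2$vol, lk2$layer_id, method = "leakage",
                           cbv = c(0.8, 1, 1.5, 2), roi = lk2$column_id)
  expect_equal(out2$data[, 1, ], t(lk2$truth), tolerance = 1e-10)

  # scaling method via CBVv estimated from residual SDs
  set.seed(56)
  K <- 3
  resid <- array(rnorm(5 * 1 * K * 200), dim = c(5, 1, K, 200))
  for (k in seq_len(K)) resid[, , k, ] <- resid[, , k, ] * k
  lk3 <- make_leaky_volume(K, m = c(1, 2, 3), cbv = c(1, 2, 3),
                           n_columns = 5)
  out3 <- devein_voxelwise(lk3$vol, lk3$layer_id, method = "CBV",
                           cbv = "from-residuals", residuals = resid)
  # estimated weights are proportional to (1, 2, 3)/2: check the gain
  s_est <- c(1, 2, 3) / 2
  S <- as.numeric(lk3$model$A %*% c(1, 2, 3))
  expect_equal(out3$data[1, 1, ], S / s_est, tolerance = 0.05)

  expect_error(devein_voxelwise(lk$vol, lk$layer_id, method = "CBV"),
               "CBV")
})

test_that("noise amplification follows the rows of the inverse mixing", {
  set.seed(57)
  mod <- build_leakage_model(c(0.7, 1, 1.6, 2.4))
  Ainv <- solve(mod$A)
  sigma <- 0.5
  n <- 20000
  m0 <- c(1, 2, 1.5, 1)
  S0 <- as.numeric(mod$A %*% m0)
  noise <- matrix(rnorm(4 * n, sd = sigma), 4, n)
  rec <- Ainv %*% (S0 + noise)
  v_emp <- apply(rec, 1, var)
  v_th <- rowSums(Ainv^2) * sigma^2
  expect_true(all(abs(v_emp - v_th) / v_th < 0.1))
  # deepest layer passes through unamplified; superficial layers amplify
  expect_equal(v_th[1], sigma^2)
  expect_true(all(v_th[-1] > sigma^2))
})
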