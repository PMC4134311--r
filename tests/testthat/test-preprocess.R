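make_vol <- function(mat, grid = tiny_grid(), tr = 2) vol4d(mat, grid, tr)

test_that("initial volumes are discarded with metadata preserved", {
  g <- tiny_grid()
  v <- make_vol(matrix(rnorm(10 * prod(g$dim)), 10))
  out <- discard_initial(v, 2)
  expect_identical(n_volumes(out), 8L)
  expect_equal(out$mat, v$mat[-(1:2), ])
  expect_identical(out$tr_s, v$tr_s)
  expect_identical(discard_initial(v, 0)$mat, v$mat)
  v2 <- make_vol(matrix(rnorm(2 * prod(g$dim)), 2))
  expect_error(discard_initial(v2, 2), "no volumes left")
})

test_that("motion QC thresholds at half a voxel for shifts and rotations", {
  p <- matrix(0, 5, 6)
  ok <- motion_check(p, voxel_mm = 3)
  expect_true(ok$pass)
  expect_equal(ok$max_excursion_mm, 0)

  p[3, 2] <- 1.6                       # 1.6 mm > 1.5 mm on a 3-mm grid
  expect_false(motion_check(p, 3)$pass)

  p <- matrix(0, 5, 6); p[2, 5] <- 0.5 # 0.5 deg at 65 mm = 0.567 mm
  chk <- motion_check(p, 3)
  expect_true(chk$pass)
  expect_equal(chk$max_excursion_mm, 65 * pi * 0.5 / 180, tolerance = 1e-12)
})

test_that("detrending removes an exact line, keeps means, and is idempotent", {
  g <- tiny_grid()
  nt <- 20
  tt <- seq_len(nt)
  a <- rnorm(prod(g$dim)); b <- rnorm(prod(g$dim))
  v <- make_vol(outer(rep(1, nt), a) + outer(tt, b))
  out <- detrend_voxelwise(v)
  expected <- outer(rep(1, nt), a + b * mean(tt))
  expect_equal(out$mat, expected, tolerance = 1e-9)
  expect_equal(colMeans(out$mat), colMeans(v$mat), tolerance = 1e-9)

  # planted sine + line: matches an independent per-voxel regression oracle
  s <- sin(2 * pi * tt / 10)
  v2 <- make_vol(outer(s, rep(1, prod(g$dim))) + outer(tt, b))
  out2 <- detrend_voxelwise(v2)
  oracle <- unname(residuals(lm(v2$mat[, 1] ~ tt))) + mean(v2$mat[, 1])
  expect_gt(cor(out2$mat[, 1], oracle), 0.999)
  expect_equal(out2$mat[, 1], oracle, tolerance = 1e-9)
  expect_equal(detrend_voxelwise(out2)$mat, out2$mat, tolerance = 1e-9)
})

test_that("Gaussian smoothing reproduces the kernel on an impulse and conserves mass", {
  g <- make_grid(c(-30, 30), c(-30, 30), c(-30, 30), voxel_mm = 3)
  V <- prod(g$dim)
  imp <- numeric(V)
  ctr <- c(11, 11, 11)
  imp[ctr[1] + g$dim[1] * (ctr[2] - 1 + g$dim[2] * (ctr[3] - 1))] <- 1
  v <- make_vol(rbind(imp, imp), g)
  out <- smooth_gaussian(v, fwhm_mm = 6)
  s <- fwhm_to_sigma(6) / 3
  R <- ceiling(4 * s)
  k <- exp(-0.5 * ((-R:R) / s)^2); k <- k / sum(k)
  arr <- array(out$mat[1, ], g$dim)
  expect_equal(arr[11, 11, 11], max(k)^3, tolerance = 1e-12)
  expect_equal(sum(arr), 1, tolerance = 1e-6)      # interior impulse: mass kept
  expect_identical(smooth_gaussian(v, 0)$mat, v$mat)
})

test_that("nuisance regression projects out mask signals exactly", {
  g <- tiny_grid()
  masks <- default_nuisance_masks(g)
  nt <- 30
  wm_tc <- sin(seq_len(nt)); csf_tc <- cos(3 * seq_len(nt))

  # data that is the WM signal everywhere -> residual identically zero
  # (both covariates see the same series, so collinearity is also flagged)
  v <- make_vol(outer(wm_tc, rep(1, prod(g$dim))))
  expect_warning(out <- nuisance_regression(v, masks$wm, masks$csf),
                 "collinear")
  expect_lt(max(abs(out$vol$mat)), 1e-10)

  # planted network + planted nuisance: nuisance removed, signal kept
  net <- simulate_timecourse(nt, 2, seed = 8)
  bump <- gaussian_bump(g, c(0, 0, 0), 12)
  X <- tcrossprod(net, as.vector(bump))
  X[, as.vector(masks$wm)] <- X[, as.vector(masks$wm)] + wm_tc
  X[, as.vector(masks$csf)] <- X[, as.vector(masks$csf)] + csf_tc
  X <- X + matrix(rnorm(length(X), 0, 0.01), nt)
  out2 <- nuisance_regression(make_vol(X), masks$wm, masks$csf)
  expect_lt(max(abs(crossprod(out2$wm, out2$vol$mat))) / nt, 1e-10)
  expect_lt(max(abs(crossprod(out2$csf, out2$vol$mat))) / nt, 1e-10)
  pk <- which.max(as.vector(bump))
  expect_gt(cor(out2$vol$mat[, pk], net), 0.95)

  # single-voxel masks reproduce those voxels' series as covariates
  m1 <- array(FALSE, g$dim); m1[3, 3, 3] <- TRUE
  m2 <- array(FALSE, g$dim); m2[8, 8, 8] <- TRUE
  out3 <- nuisance_regression(make_vol(X), m1, m2)
  expect_equal(out3$wm, X[, which(as.vector(m1))])
  expect_equal(out3$csf, X[, which(as.vector(m2))])

  expect_error(nuisance_regression(v, array(FALSE, g$dim), masks$csf),
               "empty WM")
  expect_warning(nuisance_regression(make_vol(X), masks$wm, masks$wm),
                 "collinear")
})
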