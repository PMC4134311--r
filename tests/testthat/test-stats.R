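test_that("voxel-wise ANOVA: F = t^2, zero for identical groups, flags ties", {
  set.seed(4)
  z1 <- matrix(rnorm(6 * 200), 6)
  z2 <- matrix(rnorm(8 * 200, 0.3), 8)
  sm <- voxelwise_group_anova(z1, z2)
  expect_equal(sm$F, sm$t^2, tolerance = 1e-8)
  expect_identical(sm$df, c(1, 12))
  # a voxel-level oracle: classical pooled t at an arbitrary voxel
  ref <- t.test(z1[, 17], z2[, 17], var.equal = TRUE)
  expect_equal(sm$t[17], unname(ref$statistic), tolerance = 1e-10)

  same <- voxelwise_group_anova(z1, z1)
  expect_true(all(same$F == 0))

  z1c <- z1; z2c <- z2
  z1c[, 3] <- 1; z2c[, 3] <- 1          # degenerate voxel
  smc <- voxelwise_group_anova(z1c, z2c)
  expect_true(smc$flagged[3])
  expect_identical(smc$t[3], 0)
  expect_error(voxelwise_group_anova(z1[1, , drop = FALSE], z2), "2 subjects")
})

test_that("cluster labelling respects extent and connectivity", {
  g <- tiny_grid(3)
  mask <- array(TRUE, g$dim)
  tv <- numeric(sum(mask))
  sm <- list(t = tv, df = c(1, 33))
  class(sm) <- "stat_map"
  empty <- threshold_and_label(sm, g, mask, 0.005, 22, 26)
  expect_identical(nrow(empty), 0L)

  # a 3x3x3 cube of strong voxels survives min extent 22 as one cluster
  arr <- array(0, g$dim)
  arr[5:7, 5:7, 5:7] <- 10
  sm$t <- arr[mask]
  one <- threshold_and_label(sm, g, mask, 0.005, 22, 26)
  expect_identical(nrow(one), 1L)
  expect_identical(one$size, 27L)
  expect_identical(one$sign, 10 %/% 10)
  # peak reported in mm at the highest |t| voxel
  arr[6, 6, 6] <- 12
  sm$t <- arr[mask]
  one2 <- threshold_and_label(sm, g, mask, 0.005, 22, 26)
  expect_equal(c(one2$peak_x, one2$peak_y, one2$peak_z),
               as.vector(voxel_to_mm(g, c(6, 6, 6))))

  # two blobs joined by one corner voxel: 1 cluster at 26-conn, 2 at 6-conn
  arr2 <- array(FALSE, c(9, 9, 9))
  arr2[1:3, 1:3, 1:3] <- TRUE
  arr2[4:6, 4:6, 4:6] <- TRUE
  for (conn in c(26, 6)) {
    lab <- sogica:::.label3d_cpp(arr2, dim(arr2), as.integer(conn))
    oracle <- label_components_R(arr2, conn)
    expect_identical(attr(lab, "n_components"), attr(oracle, "n_components"))
  }
  expect_identical(attr(sogica:::.label3d_cpp(arr2, dim(arr2), 26L),
                        "n_components"), 1L)
  expect_identical(attr(sogica:::.label3d_cpp(arr2, dim(arr2), 6L),
                        "n_components"), 2L)
})

test_that("compiled labelling agrees with the R oracle on random fields", {
  set.seed(11)
  for (conn in c(6, 18, 26)) {
    arr <- array(runif(10 * 9 * 8) < 0.3, c(10, 9, 8))
    lab <- sogica:::.label3d_cpp(arr, dim(arr), as.integer(conn))
    oracle <- label_components_R(arr, conn)
    expect_identical(attr(lab, "n_components"), attr(oracle, "n_components"))
    # same partition up to label permutation
    key <- paste(lab[arr], oracle[arr])
    expect_identical(length(unique(key)), attr(lab, "n_components"))
  }
})

test_that("Monte Carlo extent threshold is deterministic, monotone, and sane", {
  g <- tiny_grid(3)                        # 21^3 grid
  mask <- ellipsoid_mask(g, c(0, 0, 0), c(27, 27, 27))
  cfg <- stats_config(n_iterations = 500, sim_seed = 99L)
  mc1 <- montecarlo_min_cluster(mask, cfg)
  mc2 <- montecarlo_min_cluster(mask, cfg)
  expect_identical(mc1$min_cluster, mc2$min_cluster)
  expect_identical(mc1$max_sizes, mc2$max_sizes)
  expect_lte(mc1$attained, 0.05)

  # a voxel p so small that no voxel survives -> min cluster 1, tail 0
  none <- montecarlo_min_cluster(mask, stats_config(voxel_p = 1e-12,
                                                    n_iterations = 100,
                                                    sim_seed = 99L))
  expect_identical(none$min_cluster, 1L)
  expect_identical(none$attained, 0)

  # extent threshold is non-increasing as the voxel threshold tightens
  ks <- vapply(c(0.01, 0.005, 0.001), function(p)
    montecarlo_min_cluster(mask, stats_config(voxel_p = p, n_iterations = 500,
                                              sim_seed = 7L))$min_cluster, 0L)
  expect_true(all(diff(ks) <= 0))
})

test_that("ROI group test matches printed-summary arithmetic and t.test", {
  set.seed(8)
  z1 <- matrix(rnorm(5 * 50), 5); z2 <- matrix(rnorm(7 * 50, 0.4), 7)
  roi <- c(rep(TRUE, 10), rep(FALSE, 40))
  res <- roi_group_ttest(z1, z2, roi)
  ref <- t.test(rowMeans(z1[, 1:10]), rowMeans(z2[, 1:10]), var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  expect_equal(roi_group_ttest(z1, z1, roi)$t, 0)

  # printed left-IPL row: means 1 vs 2.15, SEM 0.28 each, n = 16/19
  t_lipl <- pooled_t_summary(1, 0.28 * sqrt(16), 16,
                             2.15, 0.28 * sqrt(19), 19)$t
  expect_gt(abs(t_lipl), 2.7)
  expect_lt(abs(t_lipl), 3.1)
})

test_that("behavioural group tests reproduce printed t values from summaries", {
  res <- summary_group_tests(behaviour_reference(), 16, 19)
  expect_lt(abs(res$t[res$score == "age"] - 0.076), 0.1)
  expect_equal(res$t[res$score == "IIEF5"], -7.37, tolerance = 0.05)

  # raw-data route: identical groups give t = 0; missing columns warn
  subj <- data.frame(group = rep(c("EDp", "HC"), each = 4),
                     a = rep(c(1, 2, 3, 4), 2), id = letters[1:8],
                     stringsAsFactors = FALSE)
  bt <- behavioral_group_tests(subj)
  expect_equal(bt$t[bt$score == "a"], 0)
  expect_warning(behavioral_group_tests(subj, columns = c("a", "zz")),
                 "zz")
})

test_that("Pearson ROI-behaviour correlation handles exact and degenerate input", {
  x <- 1:10
  res <- roi_behavior_correlation(x, 2 * x + 1)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_lt(res$p, 1e-6)
  set.seed(3)
  y <- rnorm(20)
  ref <- cor.test(y, rnorm(20))
  expect_error(roi_behavior_correlation(x, rep(1, 10)), "zero variance")
  expect_error(roi_behavior_correlation(x[1:2], x[1:2]), "at least 3")
})
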