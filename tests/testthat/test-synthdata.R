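test_that("atlas maps peak at the voxel nearest each node and reject off-grid peaks", {
  grid <- make_grid()
  atlas <- make_network_atlas(default_networks()["SN"], grid)
  map <- atlas$networks$SN$map
  peak_idx <- mm_to_voxel(grid, c(44, 13, 0))
  # right anterior insula node: the voxel nearest the peak attains the
  # map maximum (equal-height nodes tie at machine precision)
  expect_equal(map[peak_idx], max(map), tolerance = 1e-9)
  expect_lte(max(map), 1)

  bad <- network_spec("X", rbind(node_spec("far", "R", c(500, 0, 0))))
  expect_error(make_network_atlas(list(X = bad), grid), "far")
})

test_that("an empty node list yields an all-zero map", {
  grid <- tiny_grid()
  ns <- network_spec("DMN", rbind(node_spec("A", "L", c(0, 0, 0))))
  ns$nodes <- ns$nodes[0, ]
  atlas <- make_network_atlas(list(DMN = ns), grid)
  expect_true(all(atlas$networks$DMN$map == 0))
})

test_that("two nodes 30 mm apart at radius 8 mm give two suprathreshold blobs", {
  grid <- make_grid(c(-30, 30), c(-30, 30), c(-30, 30), voxel_mm = 3)
  ns <- network_spec("N", rbind(node_spec("a", "L", c(-15, 0, 0), 8),
                                node_spec("b", "R", c(15, 0, 0), 8)))
  atlas <- make_network_atlas(list(N = ns), grid)
  sup <- atlas$networks$N$map > 0.5
  lab <- label_components_R(sup, 26)
  expect_identical(attr(lab, "n_components"), 2L)
})

test_that("noise-free single-network data is the planted rank-1 outer product", {
  grid <- tiny_grid()
  cfg <- tiny_cfg(noise_sd = 0, drift_amplitude = 0, nuisance_amplitude = 0,
                  loading_jitter_sd = 0)
  atlas <- make_network_atlas(tiny_networks()["SN"], grid)
  sub <- simulate_subject(atlas, default_group_effects(), "HC", cfg, seed = 3)
  expected <- tcrossprod(sub$truth$timecourses[, "SN"],
                         as.vector(sub$truth$maps$SN))
  expect_equal(sub$vol$mat, expected, tolerance = 1e-12)
})

test_that("at default SNR a node-peak voxel tracks its network time course", {
  grid <- make_grid()
  atlas <- make_network_atlas(planted_networks(), grid)
  cfg <- cohort_config(n_volumes = 100, loading_jitter_sd = 0)
  sub <- simulate_subject(atlas, default_group_effects(), "HC", cfg, seed = 11)
  pk <- mm_to_voxel(grid, c(2, -71, 3))  # VN node
  v <- pk[1] + grid$dim[1] * (pk[2] - 1 + grid$dim[2] * (pk[3] - 1))
  r <- cor(sub$vol$mat[, v], sub$truth$timecourses[, "VN"])
  expect_gt(r, 0.9)
})

test_that("default acquisition spans 210 volumes over 420 s", {
  cfg <- cohort_config()
  expect_identical(cfg$n_volumes, 210L)
  expect_equal(cfg$n_volumes * cfg$tr_s, 420)
  grid <- tiny_grid()
  atlas <- make_network_atlas(tiny_networks(), grid)
  sub <- simulate_subject(atlas, default_group_effects(), "HC",
                          tiny_cfg(n_volumes = 210), seed = 5)
  expect_identical(n_volumes(sub$vol), 210L)
})

test_that("noise-free data rank equals networks + nuisance + drift", {
  grid <- tiny_grid()
  cfg <- tiny_cfg(noise_sd = 0)
  atlas <- make_network_atlas(tiny_networks(), grid)
  sub <- simulate_subject(atlas, default_group_effects(), "HC", cfg, seed = 9)
  sv <- svd(sub$vol$mat)$d
  expect_identical(sum(sv > max(sv) * 1e-9), 2L + 2L + 1L)
})

test_that("generators are deterministic and groups differ only through effects", {
  grid <- tiny_grid()
  atlas <- make_network_atlas(tiny_networks(), grid)
  cfg <- tiny_cfg()
  a <- simulate_subject(atlas, default_group_effects(), "EDp", cfg, seed = 21)
  b <- simulate_subject(atlas, default_group_effects(), "EDp", cfg, seed = 21)
  expect_identical(a$vol$mat, b$vol$mat)
  # no planted effect: group label has no influence on the data
  no_eff <- default_group_effects()[0, ]
  e <- simulate_subject(atlas, no_eff, "EDp", cfg, seed = 22)
  h <- simulate_subject(atlas, no_eff, "HC", cfg, seed = 22)
  expect_identical(e$vol$mat, h$vol$mat)
})

test_that("cohorts have the configured group sizes and a reproducible manifest", {
  cfg <- tiny_cfg()
  co <- simulate_cohort(cfg, tiny_networks(), default_group_effects(),
                        grid = tiny_grid())
  expect_identical(nrow(co$subjects), 6L)
  expect_identical(sum(co$subjects$group == "EDp"), 3L)

  co16 <- simulate_cohort(cohort_config(n_volumes = 12, voxel_mm = 6),
                          tiny_networks(), grid = tiny_grid())
  expect_identical(table(co16$subjects$group)[["EDp"]], 16L)
  expect_identical(table(co16$subjects$group)[["HC"]], 19L)

  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_cohort(cfg, tiny_networks(), grid = tiny_grid(), dir = d1)
  simulate_cohort(cfg, tiny_networks(), grid = tiny_grid(), dir = d2)
  expect_true(file.exists(file.path(d1, "EDp01_bold.nii.gz")))
  m1 <- readLines(file.path(d1, "manifest.json"))
  m2 <- readLines(file.path(d2, "manifest.json"))
  expect_identical(m1, m2)
  expect_error(simulate_cohort(cfg, tiny_networks(), grid = tiny_grid(),
                               dir = d1), "not empty")
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("single-group cohorts are generated but refused by group stats", {
  cfg <- tiny_cfg(n_EDp = 0, n_HC = 4)
  co <- simulate_cohort(cfg, tiny_networks(), grid = tiny_grid())
  expect_identical(sum(co$subjects$group == "EDp"), 0L)
  expect_error(behavioral_group_tests(co$subjects), "both groups")
})

test_that("volumes survive a NIfTI round trip", {
  grid <- tiny_grid()
  atlas <- make_network_atlas(tiny_networks(), grid)
  sub <- simulate_subject(atlas, default_group_effects(), "HC",
                          tiny_cfg(n_volumes = 12), seed = 2)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(sub$vol, f)
  v2 <- read_volume(f, grid)
  expect_equal(v2$mat, sub$vol$mat, tolerance = 1e-6)
  expect_equal(v2$tr_s, 2)
})

test_that("planted physiology is deterministic and carries its truth", {
  cfg <- tiny_cfg()
  p1 <- simulate_physio("HC", cfg, seed = 4)
  p2 <- simulate_physio("HC", cfg, seed = 4)
  expect_identical(p1$tumescence$value, p2$tumescence$value)
  expect_identical(p1$cardiac_events, p2$cardiac_events)
  expect_true(all(diff(p1$cardiac_events) > 0))
  expect_equal(p1$truth$amp_pct, 10.32)
})
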