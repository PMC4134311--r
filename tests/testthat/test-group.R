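# pseudo-decompositions built from atlas maps + noise keep these tests fast
fake_ics <- function(atlas, mask, order, noise = 0.05, extra_noise_ics = 0,
                     seed = 1) {
  set.seed(seed)
  rows <- lapply(order, function(nm)
    atlas$networks[[nm]]$map[mask] + rnorm(sum(mask), 0, noise))
  for (i in seq_len(extra_noise_ics))
    rows[[length(rows) + 1]] <- rnorm(sum(mask), 0, 1)
  M <- do.call(rbind, rows)
  sogica:::zscale_maps(M)
}

test_that("spatial correlation behaves on identities and quadrature patterns", {
  g <- tiny_grid()
  set.seed(2)
  m <- array(rnorm(prod(g$dim)), g$dim)
  mask <- array(TRUE, g$dim)
  expect_equal(spatial_correlation(m, m, mask), 1)
  expect_equal(spatial_correlation(m, -m, mask), -1)
  expect_error(spatial_correlation(m, array(1, g$dim), mask), "zero-variance")

  # period-4 sine/cosine checkerboards in quadrature are exactly orthogonal
  d <- c(8, 6, 6)
  i <- slice.index(array(0, d), 1)
  a <- sin(2 * pi * i / 4); b <- cos(2 * pi * i / 4)
  expect_lt(abs(spatial_correlation(a, b, array(TRUE, d))), 1e-12)
})

test_that("template matching finds planted networks and reports the rest absent", {
  grid <- make_grid()
  mask <- default_brain_mask(grid)
  atlas <- make_network_atlas(default_networks(), grid)
  templates <- make_templates(grid)
  M <- fake_ics(atlas, mask, c("FPN", "VN", "SN", "DMN"), noise = 0.01,
                extra_noise_ics = 3)
  res <- match_templates(M, templates, mask)
  expect_identical(sort(res$template[res$matched]),
                   c("DMN", "FPN", "SN", "VN"))
  expect_identical(res$template[!res$matched], c("AN", "CEN", "SMN"))
  expect_identical(res$component[res$template == "DMN"], 4L)
  expect_true(all(res$r[res$matched] > 0.6))

  # a template equal to a component map is matched with r = 1
  tp2 <- templates["DMN"]
  tp2$DMN$map <- sogica:::unmask_vector(M[4, ], mask)
  res2 <- match_templates(M, tp2, mask)
  expect_equal(res2$r[1], 1, tolerance = 1e-9)

  # pure-noise decompositions match nothing at r_min = 0.25
  set.seed(5)
  noise <- matrix(rnorm(5 * sum(mask)), 5)
  res3 <- match_templates(noise, templates, mask)
  expect_false(any(res3$matched))
})

test_that("components cluster across subjects with one member per subject", {
  grid <- tiny_grid(3)
  mask <- array(TRUE, grid$dim)
  atlas <- make_network_atlas(tiny_networks(), grid)
  # 5 subjects sharing 2 sources (shuffled order) + 1 noise component each
  ic_list <- lapply(1:5, function(s) {
    ord <- if (s %% 2) c("DMN", "SN") else c("SN", "DMN")
    fake_ics(atlas, mask, ord, noise = 0.01, extra_noise_ics = 1, seed = s)
  })
  names(ic_list) <- sprintf("S%02d", 1:5)
  cl <- sogica_cluster(ic_list, n_clusters = 3)
  sizes <- vapply(cl$clusters, function(c) nrow(c$members), 0L)
  expect_identical(sort(sizes, decreasing = TRUE)[1:2], c(5L, 5L))
  for (c in cl$clusters)
    expect_false(anyDuplicated(c$members$subject) > 0)
  # the planted-source clusters are pure: one component per subject, all
  # members the same planted source, high mutual similarity
  for (nm in c("DMN", "SN")) {
    ref <- atlas$networks[[nm]]$map[mask]
    best <- which.max(vapply(cl$clusters, function(c)
      abs(cor(c$map, ref)), 0))
    comp <- cl$clusters[[best]]$members
    expect_identical(nrow(comp), 5L)
    expect_gt(cl$clusters[[best]]$similarity, 0.9)
    planted <- ifelse((as.integer(sub("S", "", comp$subject)) %% 2) == 1,
                      match(nm, c("DMN", "SN")), 3 - match(nm, c("DMN", "SN")))
    expect_identical(comp$component, as.integer(planted))
  }
})

test_that("single-subject clustering degenerates to singleton components", {
  grid <- tiny_grid(3)
  mask <- array(TRUE, grid$dim)
  atlas <- make_network_atlas(tiny_networks(), grid)
  one <- list(S1 = fake_ics(atlas, mask, c("DMN", "SN"), seed = 3))
  cl <- sogica_cluster(one)
  expect_identical(length(cl$clusters), 2L)
  expect_true(all(vapply(cl$clusters, function(c) nrow(c$members), 0L) == 1L))
})

test_that("relabelling subjects permutes membership but not cluster maps", {
  grid <- tiny_grid(3)
  mask <- array(TRUE, grid$dim)
  atlas <- make_network_atlas(tiny_networks(), grid)
  ic_list <- lapply(1:4, function(s)
    fake_ics(atlas, mask, c("DMN", "SN"), noise = 0.01, seed = s))
  names(ic_list) <- sprintf("A%02d", 1:4)
  cl1 <- sogica_cluster(ic_list, 2)
  relabelled <- ic_list
  names(relabelled) <- sprintf("B%02d", 1:4)
  cl2 <- sogica_cluster(relabelled, 2)
  for (i in seq_along(cl1$clusters))
    expect_equal(cl1$clusters[[i]]$map, cl2$clusters[[i]]$map)
})

test_that("subject network Z maps are complete, sign-aligned and warn on gaps", {
  grid <- tiny_grid(3)
  mask <- array(TRUE, grid$dim)
  atlas <- make_network_atlas(tiny_networks(), grid)
  templates <- make_templates(grid, tiny_networks())
  ic_list <- lapply(1:4, function(s)
    fake_ics(atlas, mask, c("DMN", "SN"), noise = 0.01, seed = s))
  names(ic_list) <- sprintf("S%02d", 1:4)
  # flip one subject's first map: it must come back aligned
  flipped <- ic_list
  flipped$S03[1, ] <- -flipped$S03[1, ]
  cl <- sogica_cluster(flipped, 2)
  nz <- subject_network_zmaps(cl, templates, mask, flipped)
  expect_setequal(names(nz), c("DMN", "SN"))
  expect_identical(nrow(nz$DMN$zmaps), 4L)
  ref <- atlas$networks$DMN$map[mask]
  rr <- cor(t(nz$DMN$zmaps), ref)
  expect_true(all(rr > 0.9))

  # a subject without components for a network is excluded with a warning
  short <- flipped
  short$S04 <- short$S04[2, , drop = FALSE]    # only the SN-like map
  cl2 <- sogica_cluster(short, 2)
  expect_warning(nz2 <- subject_network_zmaps(cl2, templates, mask, short),
                 "S04")
  expect_identical(nz2$DMN$missing, "S04")
  expect_identical(nrow(nz2$DMN$zmaps), 3L)
})

test_that("direct (template-first) ordering produces equivalent network maps", {
  grid <- tiny_grid(3)
  mask <- array(TRUE, grid$dim)
  atlas <- make_network_atlas(tiny_networks(), grid)
  templates <- make_templates(grid, tiny_networks())
  ic_list <- lapply(1:4, function(s)
    fake_ics(atlas, mask, c("DMN", "SN"), noise = 0.01, seed = s))
  names(ic_list) <- sprintf("S%02d", 1:4)
  nz <- subject_network_zmaps_direct(ic_list, templates, mask)
  expect_setequal(names(nz), c("DMN", "SN"))
  expect_identical(nrow(nz$DMN$zmaps), 4L)
  expect_gt(min(cor(t(nz$SN$zmaps), atlas$networks$SN$map[mask])), 0.9)
})
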