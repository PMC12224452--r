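# Group inference: t-maps, TFCE, sign-flip and cluster-mass permutations.

test_that("one-sample t matches hand computation and handles edge cases", {
  maps <- list(matrix(0.60, 1, 1), matrix(0.55, 1, 1), matrix(0.65, 1, 1))
  tm <- one_sample_t(maps, popmean = 0.5)
  expect_equal(tm$t[1, 1], 0.10 / (0.05 / sqrt(3)), tolerance = 1e-9)
  expect_equal(tm$t[1, 1], 3.464, tolerance = 1e-3)
  expect_identical(tm$df, 2L)
  # cross-check against the stats oracle
  expect_equal(tm$t[1, 1],
               unname(t.test(c(0.60, 0.55, 0.65), mu = 0.5)$statistic),
               tolerance = 1e-12)
  # all at chance -> t = 0
  tz <- one_sample_t(list(matrix(0.5, 2, 2), matrix(0.5, 2, 2)))
  expect_true(all(tz$t == 0))
  # antisymmetry about chance
  m <- matrix(c(0.6, 0.4), 1, 2)
  ta <- one_sample_t(list(m, m + 0.02, m - 0.02))
  expect_equal(ta$t[1, 1], -ta$t[1, 2], tolerance = 1e-12)
  # zero variance -> infinite sentinel with warning
  expect_warning(ti <- one_sample_t(list(matrix(0.6, 1, 1),
                                         matrix(0.6, 1, 1))),
                 "zero across-subject variance")
  expect_identical(ti$n_infinite, 1L)
  expect_error(one_sample_t(list(matrix(0.5, 1, 1))), ">= 2 subjects")
})

test_that("TFCE matches closed forms for isolated cells and plateaus", {
  geom <- tiny_geometry(0)
  adj1 <- spatiotemporal_adjacency(geom$mesh, geom$mask, 1)
  tv <- matrix(0, 12, 1); tv[1, 1] <- 3
  tf <- tfce_transform(tv, adj1, tfce_params(dh = 0.001))
  expect_equal(tf[1, 1], 9.0, tolerance = 0.01 * 9)   # int_0^3 h^2 dh
  expect_true(all(tf[-1, 1] == 0))
  # 4-cell plateau at t = 2 on a temporal path: 4^0.5 * int_0^2 h^2 dh
  mesh1 <- assign_regions(build_icosphere(0), list(one = 1L))
  mask1 <- make_language_mask(mesh1, "one")
  adj4 <- spatiotemporal_adjacency(mesh1, mask1, 4)
  tv4 <- matrix(2, 1, 4)
  tf4 <- tfce_transform(tv4, adj4, tfce_params(dh = 0.001))
  expect_equal(unname(tf4[1, ]), rep(16 / 3, 4), tolerance = 0.01 * 16 / 3)
  # all-zero map stays zero; oversized dh warns and zeroes
  expect_warning(
    z0 <- tfce_transform(matrix(0, 12, 1), adj1, tfce_params(dh = 0.1)),
    "all zero")
  expect_true(all(z0 == 0))
  expect_warning(z <- tfce_transform(tv / 100, adj1, tfce_params(dh = 10)),
                 "all zero")
  expect_true(all(z == 0))
})

test_that("compiled TFCE agrees with the igraph threshold-loop oracle", {
  geom <- tiny_geometry(1)
  adj <- spatiotemporal_adjacency(geom$mesh, geom$mask, 3)
  set.seed(7)
  for (rep in 1:3) {
    tv <- matrix(pmax(rnorm(adj$n_nodes, 1, 1.5), 0),
                 length(geom$mask$vertices), 3, byrow = FALSE)
    flat <- as.vector(t(tv))
    dh <- 0.05
    oracle <- tfce_oracle(flat, adj, E = 0.5, H = 2, dh = dh)
    got <- tfce_transform(tv, adj, tfce_params(dh = dh))
    expect_equal(as.vector(t(got)), oracle, tolerance = 1e-9)
  }
})

test_that("TFCE is monotone in the input statistics", {
  geom <- tiny_geometry(0)
  adj <- spatiotemporal_adjacency(geom$mesh, geom$mask, 2)
  set.seed(11)
  tv <- matrix(pmax(rnorm(24, 0.5, 1), 0), 12, 2)
  base <- tfce_transform(tv, adj, tfce_params(dh = 0.05))
  for (i in c(1, 9, 20)) {
    tv2 <- tv
    tv2[i] <- tv2[i] + 1
    up <- tfce_transform(tv2, adj, tfce_params(dh = 0.05))
    expect_true(all(up - base >= -1e-9))
  }
})

test_that("TFCE is stable under halving of the integration step", {
  geom <- tiny_geometry(1)
  adj <- spatiotemporal_adjacency(geom$mesh, geom$mask, 2)
  set.seed(13)
  # smooth map: squared-distance bump over the sphere, common to both times
  bump <- 3 * exp(-2 * colSums((t(geom$mesh$coords) - c(1, 0, 0))^2))
  tv <- cbind(bump, bump * 0.9)
  a <- tfce_transform(tv, adj, tfce_params(dh = 0.02))
  b <- tfce_transform(tv, adj, tfce_params(dh = 0.01))
  keep <- a > 0.1 * max(a)
  expect_lt(max(abs(a[keep] - b[keep]) / a[keep]), 0.02)
})

test_that("sign-flip TFCE finds an injected group effect covering its extent", {
  geom <- tiny_geometry(0)
  nbh <- searchlight_neighborhoods(geom$mesh, geom$mask, k = 6)
  cfg <- sim_config(n_subjects = 8, n_epochs_per_class = 20,
                    mesh_level = 0, epoch_ms = c(0, 100),
                    effects = list(two_word = list(
                      effect_spec(1:6, c(20, 60), 5, pattern_seed = 7))))
  maps <- lapply(sprintf("s%02d", 1:8), function(s)
    searchlight_decode(simulate_epochs(cfg, "two_word", s, geom), nbh,
                       quick_spec(), cv_folds = 4))
  adj <- spatiotemporal_adjacency(geom$mesh, geom$mask, 20)
  res <- sign_flip_permutation(maps, adj, tfce_params(n_permutations = 200,
                                                      seed = 3))
  expect_gt(length(res$clusters), 0)
  cl <- res$clusters[[1]]
  expect_lte(cl$p, 0.05)
  expect_true(all(1:6 %in% cl$vertices))
  expect_true(all(c(20, 60) %in% cl$times_ms))
  expect_identical(cl$extent_cells, length(cl$nodes))
})

test_that("opposite-sign subject pairs can never be significant", {
  set.seed(5)
  m <- matrix(runif(24, 0, 0.3), 12, 2)
  maps <- list(0.5 + m, 0.5 - m, 0.5 + m, 0.5 - m, 0.5 + m, 0.5 - m)
  geom <- tiny_geometry(0)
  adj <- spatiotemporal_adjacency(geom$mesh, geom$mask, 2)
  res <- suppressWarnings(
    sign_flip_permutation(maps, adj, tfce_params(n_permutations = 200,
                                                 seed = 1)))
  expect_identical(length(res$clusters), 0L)
  expect_true(all(res$p_map > 0.05))
})

test_that("exhaustive enumeration agrees with Monte-Carlo flips", {
  set.seed(17)
  maps <- lapply(1:8, function(i) 0.5 + matrix(rnorm(24, 0.05, 0.1), 12, 2))
  geom <- tiny_geometry(0)
  adj <- spatiotemporal_adjacency(geom$mesh, geom$mask, 2)
  mc <- sign_flip_permutation(maps, adj,
                              tfce_params(n_permutations = 200, seed = 2))
  expect_false(mc$exact)
  expect_warning(
    ex <- sign_flip_permutation(maps, adj,
                                tfce_params(n_permutations = 1000,
                                            seed = 2)),
    "enumerating all sign flips")
  expect_true(ex$exact)
  expect_lt(max(abs(mc$p_map - ex$p_map)), 2 / sqrt(200))
})

test_that("2-D cluster-mass permutation flags a cross-latency block", {
  set.seed(23)
  base <- matrix(0.5, 10, 12)
  block <- base
  block[3:5, 8:11] <- 0.62
  tgms <- lapply(1:9, function(i) block + matrix(rnorm(120, 0, 0.03), 10, 12))
  res <- cluster_mass_permutation_2d(tgms, n_permutations = 500, seed = 4)
  expect_gt(length(res$significant), 0)
  cl <- res$significant[[1]]
  expect_true(all(3:5 %in% cl$train_idx))
  expect_true(all(8:11 %in% cl$test_idx))
  # null input: usually empty, never an error
  null_tgms <- lapply(1:6, function(i)
    0.5 + matrix(rnorm(120, 0, 0.03), 10, 12))
  resn <- suppressWarnings(
    cluster_mass_permutation_2d(null_tgms, n_permutations = 200, seed = 5))
  expect_true(length(resn$significant) <= 1)
  expect_error(cluster_mass_permutation_2d(list(base)), ">= 2 subjects")
})

test_that("cluster serialization writes valid JSON", {
  geom <- tiny_geometry(0)
  adj <- spatiotemporal_adjacency(geom$mesh, geom$mask, 2)
  set.seed(29)
  maps <- lapply(1:6, function(i) 0.5 + matrix(rnorm(24, 0.3, 0.05), 12, 2))
  res <- suppressWarnings(
    sign_flip_permutation(maps, adj,
                          tfce_params(n_permutations = 200, seed = 1)))
  path <- withr::local_tempfile(fileext = ".json")
  write_clusters_json(res$clusters, path)
  back <- jsonlite::read_json(path, simplifyVector = FALSE)
  expect_identical(length(back), length(res$clusters))
  expect_identical(length(back[[1]]$nodes), res$clusters[[1]]$extent_cells)
})
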