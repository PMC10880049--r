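# Cluster identification, tracking and growth kinetics.

test_that("minimum-image distances match worked examples and the image oracle", {
  cfg <- configuration(rbind(c(1, 0), c(69, 0)), 70)
  expect_equal(min_image_distances(cfg)[1, 2], 2)

  cfg2 <- make_grid_configuration(2, 10)
  d <- min_image_distances(cfg2)
  vals <- round(d[upper.tri(d)], 9)
  expect_setequal(vals, round(c(5, 5 * sqrt(2)), 9))

  set.seed(11)
  cfg3 <- random_configuration(20, 13.7)
  expect_equal(min_image_distances(cfg3), bf_dist_mat(cfg3$positions, 13.7),
               tolerance = 1e-12)
})

test_that("cluster identification matches the canonical worked configurations", {
  grid <- make_grid_configuration(10, 70)
  expect_equal(length(find_clusters(grid, 2.25)$sizes), 100)
  expect_equal(neighbor_counts(grid, 2.25), rep(0L, 100))

  hx <- make_hex_cluster(7, 2.1, 70)
  expect_equal(find_clusters(hx, 2.25)$sizes, 7)
  expect_equal(length(find_clusters(hx, 1.7)$sizes), 7)
  center <- which.min(colSums((t(hx$positions) - c(35, 35))^2))
  expect_equal(neighbor_counts(hx, 2.25)[center], 6L)

  # transitive connectivity along a chain
  chain <- configuration(cbind(10 + 2 * (0:4), 5), 70)
  ca <- find_clusters(chain, 2.25)
  expect_equal(ca$sizes, 5)

  expect_error(find_clusters(grid, 40), "cutoff")
  expect_error(find_clusters(grid, 0), "cutoff")
})

test_that("clustering agrees with a brute-force oracle on random configurations", {
  set.seed(99)
  for (rep in seq_len(100)) {
    n <- sample(5:40, 1)
    L <- runif(1, 8, 30)
    cutoff <- runif(1, 0.5, L / 2 - 1e-6)
    cfg <- random_configuration(n, L)
    got <- find_clusters(cfg, cutoff)$labels
    want <- bf_clusters(cfg$positions, L, cutoff)
    expect_identical(got, want)
  }
})

test_that("coarser cutoffs merge more and labels are permutation-equivariant", {
  set.seed(7)
  for (rep in seq_len(20)) {
    cfg <- random_configuration(30, 20)
    n17 <- length(find_clusters(cfg, 1.7)$sizes)
    n225 <- length(find_clusters(cfg, 2.25)$sizes)
    expect_gte(n17, n225)

    perm <- sample(30)
    lab <- find_clusters(cfg, 2.25)$labels
    cfg_p <- configuration(cfg$positions[perm, ], cfg$box_length)
    lab_p <- find_clusters(cfg_p, 2.25)$labels
    # same partition: co-membership is preserved under the permutation
    expect_identical(outer(lab_p, lab_p, "=="),
                     outer(lab[perm], lab[perm], "=="))
  }
})

test_that("cluster series tracks identities and logs fusion events", {
  # static configuration: constant everything
  pos <- make_hex_cluster(4, 2.1, 30)$positions
  ux <- matrix(rep(pos[, 1], 3), ncol = 3)
  uy <- matrix(rep(pos[, 2], 3), ncol = 3)
  tr <- memclust:::new_trajectory(0:2, 30, ux, uy)
  s <- cluster_series(tr, 2.25)
  expect_equal(s$n_clusters, rep(1L, 3))
  expect_equal(nrow(s$events), 0)

  # hand-built merge: two singletons approach and fuse at frame 3
  ux <- rbind(c(5, 5, 5), c(10, 8, 6.5))
  uy <- matrix(5, 2, 3)
  tr2 <- memclust:::new_trajectory(0:2, 30, ux, uy)
  s2 <- cluster_series(tr2, 2.25)
  expect_equal(s2$n_clusters, c(2L, 2L, 1L))
  expect_equal(s2$n_max, c(1L, 1L, 2L))
  expect_equal(s2$events$type, "fusion")
  expect_equal(s2$events$time, 2)
  expect_equal(s2$events$ids, "1+2")
  # merged cluster inherits the lower identity
  expect_equal(unique(s2$identities[, 3]), 1L)
})

test_that("power-law fits recover noiseless generating laws exactly", {
  t <- seq(1, 100, length.out = 60)
  f <- fit_power_law(data.frame(time = t, n_max = 2 * t^0.65), c(1, 100))
  expect_equal(f$exponent, 0.65, tolerance = 1e-10)
  expect_equal(f$prefactor, 2, tolerance = 1e-10)
  expect_lt(f$residual, 1e-12)

  f0 <- fit_power_law(data.frame(time = t, n_max = rep(7, 60)), c(1, 100))
  expect_equal(f0$exponent, 0, tolerance = 1e-12)

  f1 <- fit_power_law(data.frame(time = t, n_max = t), c(1, 100))
  expect_equal(f1$exponent, 1, tolerance = 1e-12)

  expect_error(fit_power_law(data.frame(time = t[1:3], n_max = t[1:3]),
                             c(1, 100)), "at least 5")
})
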