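# Synthetic membrane generator: starting configurations, Brownian
# aggregation dynamics, tilt fluctuations.

test_that("square grid configurations have the right geometry", {
  cfg <- make_grid_configuration(10, 70)
  expect_equal(nrow(cfg$positions), 100)
  d <- min_image_distances(cfg)
  nn <- apply(d + diag(Inf, 100), 1, min)
  expect_equal(unname(nn), rep(7, 100))

  expect_equal(nrow(make_grid_configuration(1, 70)$positions), 1)

  cfg2 <- make_grid_configuration(2, 10)
  d2 <- min_image_distances(cfg2)
  vals <- sort(unique(round(d2[upper.tri(d2)], 9)))
  expect_equal(vals, round(c(5, 5 * sqrt(2)), 9))

  expect_error(make_grid_configuration(0, 70), "positive")
  expect_error(make_grid_configuration(3, -1), "positive")
})

test_that("hexagonal clusters are packed at the requested spacing", {
  hx <- make_hex_cluster(7, 2.1, 70)
  d <- min_image_distances(hx)
  # central site has 6 neighbors at exactly the packing distance
  center <- which.min(colSums((t(hx$positions) - c(35, 35))^2))
  expect_equal(sort(d[center, -center]), rep(2.1, 6), tolerance = 1e-12)

  expect_equal(nrow(make_hex_cluster(1, 2.1, 70)$positions), 1)

  # second shell of a 19-site cluster contains sqrt(3) * spacing distances
  hx19 <- make_hex_cluster(19, 2.1, 70)
  dists <- sort(unique(round(min_image_distances(hx19)[upper.tri(diag(19))], 9)))
  expect_true(any(abs(dists - 2.1 * sqrt(3)) < 1e-9))
  # and the nearest-neighbor distance is the spacing itself
  expect_equal(min(dists), 2.1, tolerance = 1e-12)

  expect_error(make_hex_cluster(19, 2.1, 10), "fit")
})

test_that("zero temperature freezes all motion", {
  p <- sim_params(n_inclusions = 9, temperature = 0, n_frames = 10,
                  time_step = 1, frame_interval = 1, seed = 1)
  tr <- simulate_aggregation(make_grid_configuration(3, 70), p)
  expect_equal(tr$ux, matrix(tr$ux[, 1], 9, 10), tolerance = 0)
  expect_equal(tr$uy, matrix(tr$uy[, 1], 9, 10), tolerance = 0)
})

test_that("identical parameters and seed give bit-identical trajectories", {
  p <- sim_params(n_inclusions = 16, box_length = 40, n_frames = 30,
                  time_step = 0.5, frame_interval = 1, seed = 42)
  t1 <- simulate_aggregation(make_grid_configuration(4, 40), p)
  t2 <- simulate_aggregation(make_grid_configuration(4, 40), p)
  expect_identical(t1$ux, t2$ux)
  expect_identical(t1$uy, t2$uy)
  f1 <- simulate_fixed_clusters(c(1, 4), p)
  f2 <- simulate_fixed_clusters(c(1, 4), p)
  expect_identical(f1$ux, f2$ux)
})

test_that("cluster count never increases under irreversible aggregation", {
  p <- sim_params(n_inclusions = 100, n_frames = 120, time_step = 0.5,
                  frame_interval = 1, seed = 3)
  tr <- simulate_aggregation(make_grid_configuration(10, 70), p)
  s <- cluster_series(tr, p$fusion_cutoff)
  expect_true(all(diff(s$n_clusters) <= 0))
  expect_equal(sum(s$events$type == "fission"), 0)
  # wrapped and unwrapped positions agree modulo the box
  mism <- abs(memclust:::min_image_delta(tr$x - tr$ux, tr$box_length))
  expect_lt(max(mism), 1e-9)
})

test_that("single-inclusion displacements are Gaussian with variance 2 D dt", {
  p <- sim_params(n_frames = 10001, seed = 5)
  tr <- simulate_fixed_clusters(1, p)
  inc <- diff(tr$ux[1, ])
  D <- memclust:::generating_D(1, p)
  ks <- stats::ks.test(inc, "pnorm", mean = 0, sd = sqrt(2 * D * 1))
  expect_gt(ks$p.value, 0.01)
  # long-run MSD slope matches the generating model within 3 standard errors
  est <- estimate_D(msd_by_size(tr, max_lag = 15)[["1"]])
  expect_lt(abs(est$D - D), 3 * est$sigma + 0.05 * D)
})

test_that("fixed-cluster runs keep memberships and order mobilities by size", {
  p <- sim_params(n_frames = 50, seed = 8)
  tr <- simulate_fixed_clusters(c(1, 1), p)
  for (f in c(1, 25, 50))
    expect_equal(length(find_clusters(get_frame(tr, f), 2.25)$sizes), 2)

  p2 <- sim_params(n_frames = 3000, seed = 9)
  tr2 <- simulate_fixed_clusters(c(4, 9, 16, 25), p2)
  rec <- diffusion_records(msd_by_size(tr2, max_lag = 15))
  expect_equal(rec$cluster_size, c(4, 9, 16, 25))
  expect_true(all(diff(rec$d_pbc) < 0))
})

test_that("unsafe step sizes are refused", {
  p <- sim_params(n_inclusions = 4, box_length = 70, n_frames = 5,
                  time_step = 1e5, frame_interval = 1e5, seed = 1)
  expect_error(simulate_aggregation(make_grid_configuration(2, 70), p),
               "box_length/4")
})

test_that("tilt generator hits its target mean and limits", {
  # zero noise: every frame exactly at the target
  o <- simulate_tilt(5, 10, tilt_params(mean_cos = 0.8, noise_amplitude = 0,
                                        seed = 1))
  expect_equal(as.vector(o[, 3, ]), rep(0.8, 50), tolerance = 1e-12)
  nrm <- sqrt(o[, 1, ]^2 + o[, 2, ]^2 + o[, 3, ]^2)
  expect_lt(max(abs(nrm - 1)), 1e-9)

  # upright limit with small noise
  o2 <- simulate_tilt(50, 500, tilt_params(mean_cos = 1,
                                           noise_amplitude = 0.01, seed = 2))
  expect_gt(mean(tilt_series(o2)$mean_cos_theta), 0.97)

  # ergodic mean converges to mean_cos
  tp <- tilt_params(mean_cos = 0.9, noise_amplitude = 0.05,
                    relaxation_time = 5, seed = 3)
  o3 <- simulate_tilt(50, 4000, tp)
  ts <- tilt_series(o3)
  m <- mean(ts$mean_cos_theta)
  # standard error of the mean of an AR(1) ensemble average, generous bound
  se <- 0.05 / sqrt(50 * 4000 / (2 * 5))
  expect_lt(abs(m - 0.9), 3 * se + 0.002)
})

test_that("parameter validation rejects unphysical inputs", {
  expect_error(sim_params(box_length = -1), "box_length")
  expect_error(sim_params(eta_m = 0), "viscosities")
  expect_error(sim_params(fusion_cutoff = 40, box_length = 70), "fusion_cutoff")
  expect_error(sim_params(packing_distance = 0), "packing")
  expect_error(sim_params(frame_interval = 0.25, time_step = 0.1), "multiple")
  expect_error(tilt_params(mean_cos = 0), "mean_cos")
  expect_error(hydro_params(eta_m = -1), "positive")
})
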