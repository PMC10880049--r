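# Hydrodynamic models, MSD machinery, finite-size correction, viscosity fit.

mk_msd <- function(lags, msd, n = rep(1000, length(lags)), size = 1) {
  structure(list(lags = lags, msd = msd, cluster_size = size, n_samples = n),
            class = "msd_curve")
}

test_that("effective radius is the area-equivalent disk mapping", {
  expect_identical(effective_radius(1, 1.05), 1.05)
  expect_equal(effective_radius(4, 1.05), 2.10)
  expect_equal(effective_radius(100, 1.05), 10.5)
  expect_error(effective_radius(0), "positive")
})

test_that("the SD model matches independent arithmetic", {
  h <- default_hydro()
  # independent evaluation of kT/(4 pi eta_m) [ln(eta_m/(eta_w R)) - gamma]
  kT <- 1.380649e-23 * 300
  R <- 1.05e-9
  want_si <- kT / (4 * pi * 4.5e-11) *
    (log(4.5e-11 / (7e-4 * R)) - 0.57721566490153286)
  expect_equal(sd_model(1.05, h), want_si * 1e9, tolerance = 1e-12)

  # doubling eta_m: closed form recomputed independently
  h2 <- hydro_params(9e-11, 7e-4, 300)
  want2 <- kT / (4 * pi * 9e-11) *
    (log(9e-11 / (7e-4 * R)) - 0.57721566490153286)
  expect_equal(sd_model(1.05, h2), want2 * 1e9, tolerance = 1e-12)

  # bracket root: D crosses zero at R = 2 l_SD exp(-gamma)
  r0 <- 2 * h$sd_length / 1e-9 * exp(-0.57721566490153286)
  expect_equal(suppressWarnings(sd_model(r0, h)), 0, tolerance = 1e-12)
  expect_warning(sd_model(h$sd_length / 1e-9 * 1.5, h), "validity")
})

test_that("HPW-PS reduces to SD at small reduced radius", {
  for (eta_m in c(1e-11, 4.5e-11, 2e-10)) {
    h <- hydro_params(eta_m, 7e-4, 300)
    for (eps in c(1e-4, 1e-3)) {
      r <- eps * h$sd_length / 1e-9
      rel <- abs(hpw_ps_model(r, h) - sd_model(r, h)) / sd_model(r, h)
      expect_lt(rel, if (eps <= 1e-4) 0.005 else 0.01)
    }
  }
})

test_that("HPW-PS is strictly decreasing and crosses over near 10 nm scale", {
  h <- default_hydro()
  eps <- exp(seq(log(1e-3), log(1e2), length.out = 3000))
  r <- eps * h$sd_length / 1e-9
  d <- hpw_ps_model(r, h)
  expect_true(all(diff(d) < 0))

  # order-of-magnitude transition: radius where HPW-PS deviates from the
  # SD (membrane-dominated) branch by 25% is on the 10 nm scale
  hp <- hydro_params(1e-10, 1e-3, 300)
  rr <- seq(0.5, 100, by = 0.1)
  dev <- abs(hpw_ps_model(rr, hp) - suppressWarnings(sd_model(rr, hp))) /
    hpw_ps_model(rr, hp)
  r_trans <- rr[which(dev > 0.25)[1]]
  expect_gt(r_trans, 2)
  expect_lt(r_trans, 50)
})

test_that("finite-size correction obeys its asymptotic contract", {
  h <- default_hydro()
  d0 <- 0.02
  # infinite-box limit
  expect_lt(abs(finite_size_correction(d0, 1e9, Inf, h) - d0), 1e-6 * d0)
  # independent of cluster size (same geometry, any d)
  delta <- finite_size_correction(0, 70, Inf, h)
  expect_equal(finite_size_correction(c(0.02, 0.005), 70, Inf, h),
               c(0.02, 0.005) + delta)
  # grows logarithmically once L << l_SD: slope vs log(1/L) -> kT/(4 pi eta_m)
  lsd_nm <- h$sd_length / 1e-9
  Ls <- lsd_nm / c(100, 200, 400, 800)
  dls <- vapply(Ls, function(L) finite_size_correction(0, L, Inf, h),
                numeric(1))
  slope <- diff(dls) / diff(log(1 / Ls))
  pref <- h$thermal_energy / (4 * pi * h$eta_m) * 1e9
  expect_equal(slope, rep(pref, 3), tolerance = 1e-2)
  # monotone in box size
  expect_gt(finite_size_correction(0, 35, Inf, h),
            finite_size_correction(0, 70, Inf, h))
  # shallow solvent screens the correction
  expect_lt(finite_size_correction(0, 70, 5, h),
            finite_size_correction(0, 70, Inf, h))
  expect_error(finite_size_correction(0.01, -1, Inf, h), "positive")
})

test_that("round trip: generator subtracts the suppression, pipeline adds it back", {
  p <- sim_params(n_frames = 4000, seed = 17)
  tr <- simulate_fixed_clusters(c(1, 9), p)
  rec <- diffusion_records(msd_by_size(tr, max_lag = 15))
  h <- default_hydro()
  rec$d_corrected <- finite_size_correction(rec$d_pbc, 70, Inf, h)
  truth <- hpw_ps_model(rec$effective_radius, h)
  expect_lt(max(abs(rec$d_corrected - truth) / truth), 0.1)
  expect_true(all(abs(rec$d_corrected - truth) <
                    3 * rec$sigma + 0.05 * truth))
})

test_that("estimate_D is exact on linear MSD curves and slope-only", {
  lags <- 0:20
  m1 <- mk_msd(lags, 4 * 0.02 * lags)
  est <- estimate_D(m1, c(5, 15))
  expect_equal(est$D, 0.02, tolerance = 1e-12)

  m2 <- mk_msd(lags, 4 * 0.02 * lags + 3.7)   # offset: same slope
  expect_equal(estimate_D(m2, c(5, 15))$D, 0.02, tolerance = 1e-12)

  expect_error(estimate_D(m1, c(50, 60)), "lags inside")
  expect_error(estimate_D(m1, c(15, 5)), "window")
})

test_that("msd bookkeeping pools samples and handles constant positions", {
  # constant positions: MSD identically zero
  ux <- matrix(rep(c(1, 10), 6), nrow = 2)
  tr <- memclust:::new_trajectory(0:5, 30, ux, ux)
  cur <- msd_by_size(tr, cutoff = 2.25, max_lag = 3)
  expect_equal(cur[["1"]]$msd, rep(0, 4))

  # two independent singletons double the per-lag samples of one
  p <- sim_params(n_frames = 200, seed = 12)
  one <- msd_by_size(simulate_fixed_clusters(1, p), max_lag = 5)[["1"]]
  two <- msd_by_size(simulate_fixed_clusters(c(1, 1), p), max_lag = 5)[["1"]]
  expect_equal(two$n_samples[-1], 2 * one$n_samples[-1])

  # persistence rule: members contribute only over unchanged-membership
  # windows; a mid-trajectory fusion removes spanning windows
  ux <- rbind(c(0, 0, 0, 0, 0, 0),
              c(10, 9, 8, 1.2, 1.2, 1.2)) + 20
  uy <- matrix(20, 2, 6)
  tr2 <- memclust:::new_trajectory(0:5, 40, ux, uy)
  cur2 <- suppressWarnings(msd_by_size(tr2, cutoff = 2.25, max_lag = 2))
  # size-1 curve exists for the pre-fusion frames; size-2 for post-fusion
  expect_equal(cur2[["2"]]$n_samples[2], 4)  # 2 inclusions x 2 origins (4,5)
  expect_equal(cur2[["2"]]$msd, rep(0, 3))   # frozen after fusion here
})

test_that("viscosity fitting recovers exact and noisy generating models", {
  h_star <- 4.5e-11
  h <- hydro_params(h_star, 7e-4, 300)
  sizes <- c(1, 4, 9, 16, 25, 64)
  r <- effective_radius(sizes)
  rec <- data.frame(cluster_size = sizes, effective_radius = r,
                    d_corrected = hpw_ps_model(r, h), sigma = 1)
  fit <- fit_viscosity(rec)
  expect_equal(fit$eta_m_hat, h_star, tolerance = 1e-5)
  expect_equal(fit$chi2_reduced, 0, tolerance = 1e-10)
  expect_equal(fit$n_points, 6)

  # chi^2 calibration: noise at exactly the quoted sigma
  set.seed(31)
  sizes2 <- 1:50
  r2 <- effective_radius(sizes2)
  d2 <- hpw_ps_model(r2, h)
  sig <- 0.05 * d2
  rec2 <- data.frame(effective_radius = r2,
                     d_corrected = d2 + rnorm(50, sd = sig), sigma = sig)
  fit2 <- fit_viscosity(rec2)
  nu <- 49
  expect_gt(fit2$chi2_reduced, 1 - 3 * sqrt(2 / nu))
  expect_lt(fit2$chi2_reduced, 1 + 3 * sqrt(2 / nu))

  expect_error(fit_viscosity(rec[1, ]), "at least 2")
  rec_deg <- rec; rec_deg$effective_radius <- 2
  expect_error(fit_viscosity(rec_deg), "degenerate")
})

test_that("the fit objective matches a brute-force grid scan", {
  h <- hydro_params(3e-11, 7e-4, 300)
  sizes <- c(1, 2, 5, 9, 20)
  r <- effective_radius(sizes)
  set.seed(13)
  d <- hpw_ps_model(r, h) * (1 + rnorm(5, sd = 0.05))
  rec <- data.frame(effective_radius = r, d_corrected = d,
                    sigma = 0.05 * d)
  fit <- fit_viscosity(rec)
  grid <- 10^seq(-12.5, -9.5, length.out = 20001)
  chi2 <- vapply(grid, function(eta) {
    hh <- hydro_params(eta, 7e-4, 300)
    sum(((d - hpw_ps_model(r, hh)) / rec$sigma)^2)
  }, numeric(1))
  expect_lt(abs(fit$chi2 - min(chi2)) / max(min(chi2), 1e-12), 1e-4)
})

test_that("SD fits large-radius data worse than HPW-PS", {
  # small SD length so the records reach deep into the bulk-dominated regime
  h <- hydro_params(7e-12, 1e-3, 300)   # l_SD = 3.5 nm
  sizes <- c(1, 4, 16, 64, 144, 400)
  r <- effective_radius(sizes)
  set.seed(41)
  d <- hpw_ps_model(r, h) * (1 + rnorm(6, sd = 0.03))
  rec <- data.frame(effective_radius = r, d_corrected = d, sigma = 0.03 * d)
  f_hpw <- fit_viscosity(rec, eta_w = 1e-3, model = "HPW-PS")
  f_sd <- fit_viscosity(rec, eta_w = 1e-3, model = "SD")
  expect_gt(f_sd$chi2_reduced, f_hpw$chi2_reduced)
})

test_that("self-consistent corrected fit converges to the generating viscosity", {
  h <- default_hydro()
  sizes <- c(1, 4, 9, 16, 25, 64)
  r <- effective_radius(sizes)
  delta <- memclust:::pbc_suppression(70, Inf, h)
  rec <- data.frame(cluster_size = sizes, effective_radius = r,
                    d_pbc = hpw_ps_model(r, h) - delta, sigma = 1e-4)
  fit <- fit_viscosity_corrected(rec, box_length = 70)
  expect_equal(fit$eta_m_hat, 4.5e-11, tolerance = 1e-4)
  expect_lt(fit$n_iter, 50)
})
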