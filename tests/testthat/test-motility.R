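# MSD, velocity autocorrelation, motion-model fit, regime switch

test_that("MSD is zero for a stationary track and exact for ballistic motion", {
  still <- data.frame(frame = 0:9, t_h = (0:9) * 0.25, x_um = 3, y_um = -1, z_um = 2)
  m <- compute_msd(still, max_lag_fraction = 1)
  expect_true(all(m$msd_um2 == 0))
  expect_equal(m$msd_um2[1], 0)
  bal <- mk_ballistic_track(20, v_um_per_min = 0.45, dt_min = 15)
  mb <- compute_msd(bal, max_lag_fraction = 1)
  expect_equal(mb$msd_um2, (0.45 * mb$lags_min)^2, tolerance = 1e-10)
  expect_true(all(diff(mb$n_pairs) <= 0))
  expect_error(compute_msd(still[1:3, ]), "shorter")
})

test_that("compute_msd equals the naive double-loop oracle on random tracks", {
  set.seed(51)
  for (rep in 1:15) {
    n <- sample(6:25, 1)
    p <- apply(matrix(rnorm(3 * n), n, 3), 2, cumsum)
    tr <- data.frame(frame = 0:(n - 1), t_h = (0:(n - 1)) * 0.25,
                     x_um = p[, 1], y_um = p[, 2], z_um = p[, 3])
    m <- compute_msd(tr, max_lag_fraction = 0.5)
    lag_n <- length(m$lags_min) - 1
    expect_equal(m$msd_um2[-1], oracle_msd(p, lag_n), tolerance = 1e-12)
  }
})

test_that("MSD and VAC are invariant under global rotation and translation", {
  set.seed(52)
  n <- 15
  p <- apply(matrix(rnorm(3 * n), n, 3), 2, cumsum)
  mk <- function(p) data.frame(frame = 0:(n - 1), t_h = (0:(n - 1)) * 0.25,
                               x_um = p[, 1], y_um = p[, 2], z_um = p[, 3])
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  p2 <- p %*% R + matrix(c(100, -50, 30), n, 3, byrow = TRUE)
  expect_equal(compute_msd(mk(p))$msd_um2, compute_msd(mk(p2))$msd_um2,
               tolerance = 1e-9)
  expect_equal(velocity_autocorrelation(mk(p))$vac,
               velocity_autocorrelation(mk(p2))$vac, tolerance = 1e-9)
})

test_that("ensemble MSD weights per-track curves by pair counts", {
  bal <- mk_ballistic_track(12, 0.4)
  same <- as_ov_tracks(list(a = bal, b = bal), 15)
  expect_equal(ensemble_msd(same, 0.5)$msd_um2, compute_msd(bal, 0.5)$msd_um2)
  still <- mk_ballistic_track(12, 0)
  mix <- as_ov_tracks(list(a = bal, b = still), 15)
  em <- ensemble_msd(mix, 0.5)
  expect_equal(em$msd_um2, 0.5 * (0.4 * em$lags_min)^2, tolerance = 1e-10)
  expect_error(ensemble_msd(as_ov_tracks(list(x = bal[1:3, ]), 15)), "long enough")
})

test_that("motion-model fit recovers ballistic and Brownian parameters", {
  bal <- compute_msd(mk_ballistic_track(20, 0.45), max_lag_fraction = 0.5)
  fit <- fit_motion_model(bal, dim = 3)
  expect_equal(fit$v_um_per_min, 0.45, tolerance = 1e-6)
  expect_lt(fit$D_um2_per_min, 1e-9)
  expect_identical(fit$regime, "directed")
  cfg <- sim_config(53, tracks = list(n_cells = 500L, D_um2_per_min = 0.5,
                                      v_um_per_min = 0.4, t_switch_h = 7.5,
                                      duration_h = 8, dt_min = 15,
                                      loc_noise_um = 0))
  sim <- simulate_tracks(cfg)
  pre <- as_ov_tracks(lapply(sim$tracks, function(tr) tr[tr$t_h <= 7.5, ]), 15)
  fitb <- fit_motion_model(ensemble_msd(pre), dim = 3)
  expect_lt(abs(fitb$D_um2_per_min - 0.5) / 0.5, 0.10)
  expect_lt(fitb$v_um_per_min, 0.1)
  expect_identical(fitb$regime, "diffusive")
})

test_that("regime label is monotone in speed at fixed diffusion", {
  lags <- (1:8) * 15
  mk_msd <- function(D, v) structure(
    list(lags_min = c(0, lags), msd_um2 = c(0, 6 * D * lags + v^2 * lags^2),
         n_pairs = rep(10, 9), dt_min = 15), class = "msd_result")
  regimes <- vapply(c(0, 0.05, 0.1, 0.2, 0.5, 1),
                    function(v) fit_motion_model(mk_msd(0.5, v))$regime, "")
  ord <- c(diffusive = 1, mixed = 2, directed = 3)
  expect_true(all(diff(ord[regimes]) >= 0))
  expect_identical(regimes[1], "diffusive")
  expect_identical(regimes[length(regimes)], "directed")
})

test_that("VAC is 1 for straight motion, -1 at lag 1 for alternating steps", {
  bal <- mk_ballistic_track(12, 0.5)
  v <- velocity_autocorrelation(bal, max_lag_fraction = 0.5)
  expect_true(all(abs(v$vac - 1) < 1e-10))
  zig <- data.frame(frame = 0:11, t_h = (0:11) * 0.25,
                    x_um = rep(c(0, 2), 6), y_um = 0, z_um = 0)
  vz <- velocity_autocorrelation(zig)
  expect_equal(vz$vac[2], -1, tolerance = 1e-10)
  expect_error(velocity_autocorrelation(
    data.frame(frame = 0:4, t_h = (0:4) * 0.25, x_um = 1, y_um = 1, z_um = 1)),
    "zero total speed")
})

test_that("Brownian ensemble VAC vanishes at positive lags", {
  cfg <- sim_config(54, tracks = list(n_cells = 300L, D_um2_per_min = 0.5,
                                      v_um_per_min = 0, t_switch_h = 7.5,
                                      duration_h = 8, dt_min = 15,
                                      loc_noise_um = 0, p_outward = 1))
  sim <- simulate_tracks(cfg)
  pre <- as_ov_tracks(lapply(sim$tracks, function(tr) tr[tr$t_h <= 7.5, ]), 15)
  v <- ensemble_vac(pre, max_lag = 6L)
  for (k in 2:length(v$vac))
    expect_lt(abs(v$vac[k]), 3 / sqrt(v$n_pairs[k]))
})

test_that("ensemble MSD is linear before and superlinear after the switch", {
  cfg <- sim_config(55, tracks = list(n_cells = 400L, D_um2_per_min = 0.5,
                                      v_um_per_min = 0.45, t_switch_h = 8,
                                      duration_h = 16, dt_min = 15,
                                      loc_noise_um = 0))
  sim <- simulate_tracks(cfg)
  pre <- as_ov_tracks(lapply(sim$tracks, function(tr) tr[tr$t_h < 8, ]), 15)
  post <- as_ov_tracks(lapply(sim$tracks, function(tr) tr[tr$t_h >= 8, ]), 15)
  fpre <- fit_motion_model(ensemble_msd(pre))
  fpost <- fit_motion_model(ensemble_msd(post))
  expect_identical(fpre$regime, "diffusive")
  expect_identical(fpost$regime, "directed")
  sw <- detect_regime_switch(sim$tracks)
  expect_lte(abs(sw$switch_frame - sim$truth$switch_frame), 2L)
})
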