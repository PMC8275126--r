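# synthetic-data generator: intensity cohorts, organoid images, tracks,
# rendered movies

test_that("sim_config validates its parameter blocks", {
  expect_s3_class(sim_config(1), "sim_config")
  expect_error(sim_config(1, cohort = list(bogus = 3)), "bogus")
  expect_error(sim_config(1, image = list(n_domains = 5)), "n_domains")
  expect_error(sim_config(1, tracks = list(p_outward = 1.2)), "p_outward")
  expect_error(sim_config(1, cohort = list(duration_h = -1)), "duration_h")
})

test_that("noiseless logistic trace has its steepest rise at the drawn onset", {
  cfg <- sim_config(1, cohort = list(n_traces = 1L, onset_mean_h = 10,
                                     onset_sd_h = 0, noise_sd = 0,
                                     duration_h = 20, frame_interval_min = 30))
  sim <- simulate_intensity_cohort(cfg)
  tr <- sim$traces[[1]]
  rise <- diff(tr$intensity_raw)
  expect_equal(tr$times_h[which.max(rise)], 10, tolerance = 0.51)
  expect_equal(sim$truth$true_onsets_h, 10)
})

test_that("cohort simulation is seed-deterministic and refuses censoring setups", {
  cfg <- sim_config(42, cohort = list(n_traces = 3L))
  a <- simulate_intensity_cohort(cfg)
  b <- simulate_intensity_cohort(cfg)
  expect_identical(a, b)
  expect_error(
    simulate_intensity_cohort(sim_config(1, cohort = list(onset_mean_h = 19,
                                                          duration_h = 20))),
    "censored")
})

test_that("medaka-like cohort onsets are recovered within one frame", {
  sim <- simulate_intensity_cohort(preset_config("medaka-onset", seed = 7))
  res <- lapply(sim$traces, function(t) detect_onset(normalize_trace(t)))
  s <- summarize_onsets(res)
  expect_equal(s$n, 17L)
  expect_lt(abs(s$mean_h - mean(sim$truth$true_onsets_h)), 0.5)
})

test_that("organoid images carry exact ground-truth labels and placement fails loudly", {
  cfg <- sim_config(3, image = list(n_domains = 1L, noise_sd = 0))
  sim <- simulate_organoid_image(cfg)
  expect_equal(max(sim$truth$label_image), 1L)
  expect_equal(sort(unique(as.vector(sim$truth$label_image))), c(0L, 1L))
  expect_identical(simulate_organoid_image(cfg)$fluorescence, sim$fluorescence)
  # four domains that cannot fit with the requested gap
  expect_error(
    simulate_organoid_image(sim_config(1, image = list(
      n_domains = 4L, organoid_radius_um = 60, domain_radius_um = 28,
      min_domain_gap_um = 30)), max_attempts = 200L),
    "could not place")
})

test_that("generated domain areas match the analytic pixel count within 2%", {
  for (seed in 1:5) {
    cfg <- sim_config(seed, image = list(n_domains = 2L, domain_radius_um = 40,
                                         pixel_size_um = 2, noise_sd = 0))
    sim <- simulate_organoid_image(cfg)
    for (lb in sim$truth$domains$label) {
      measured <- sum(sim$truth$label_image == lb) * cfg$image$pixel_size_um^2
      expect_lt(abs(measured - pi * 40^2) / (pi * 40^2), 0.02)
    }
  }
})

test_that("domain covering the whole organoid gives 100% expression", {
  cfg <- sim_config(2, image = list(n_domains = 1L, domain_radius_um = 100,
                                    organoid_radius_um = 100, noise_sd = 2))
  sim <- simulate_organoid_image(cfg)
  org <- organoid_mask(sim$bright_field)
  expect_gt(as.numeric(expression_fraction(sim$fluorescence, org$mask)), 97)
})

test_that("pure outward motion increases radius by exactly v*dt per frame", {
  cfg <- sim_config(5, tracks = list(n_cells = 20L, D_um2_per_min = 0,
                                     v_um_per_min = 1, p_outward = 1,
                                     t_switch_h = 1, duration_h = 3,
                                     dt_min = 30, loc_noise_um = 0,
                                     aggregate_radius_um = 50))
  sim <- simulate_tracks(cfg)
  for (tr in sim$tracks[1:5]) {
    r <- sqrt(rowSums(track_positions(tr)^2))
    post <- which(tr$t_h >= 1)
    expect_equal(diff(r[post]), rep(30, length(post) - 1), tolerance = 1e-9)
    expect_equal(diff(r[tr$t_h < 1]), rep(0, sum(tr$t_h < 1) - 1), tolerance = 1e-9)
  }
  expect_true(all(sim$truth$cells$class == "outward"))
})

test_that("outward/inward class counts follow the binomial law", {
  cfg <- sim_config(8, tracks = list(n_cells = 4600L, p_outward = 0.5,
                                     t_switch_h = 1, duration_h = 2))
  sim <- simulate_tracks(cfg)
  k <- sum(sim$truth$cells$class == "outward")
  ci <- qnorm(c(0.005, 0.995), 2300, sqrt(4600 * 0.25))
  expect_gt(k, ci[1]); expect_lt(k, ci[2])
})

test_that("Brownian-phase ensemble MSD matches 6*D*tau within 10%", {
  cfg <- sim_config(11, tracks = list(n_cells = 500L, D_um2_per_min = 0.5,
                                      t_switch_h = 7.5, duration_h = 8,
                                      dt_min = 15, loc_noise_um = 0))
  sim <- simulate_tracks(cfg)
  pre <- as_ov_tracks(lapply(sim$tracks, function(tr) tr[tr$t_h <= 7.5, ]), 15)
  em <- ensemble_msd(pre)
  theory <- 6 * 0.5 * em$lags_min[-1]
  expect_true(all(abs(em$msd_um2[-1] - theory) / theory < 0.10))
})

test_that("net radial displacement sign equals the recorded class without noise", {
  cfg <- sim_config(13, tracks = list(n_cells = 300L, loc_noise_um = 0,
                                      t_switch_h = 4, duration_h = 16))
  sim <- simulate_tracks(cfg)
  net <- vapply(sim$tracks, function(tr) {
    r <- sqrt(rowSums(track_positions(tr)^2))
    r[length(r)] - r[1]
  }, numeric(1))
  expect_identical(unname(ifelse(net > 0, "outward", "inward")),
                   sim$truth$cells$class)
})

test_that("track simulation is seed-deterministic including misses", {
  cfg <- sim_config(9, tracks = list(n_cells = 30L, miss_rate = 0.05,
                                     t_switch_h = 1, duration_h = 3))
  expect_identical(simulate_tracks(cfg), simulate_tracks(cfg))
})

test_that("rendered movies place spots at the right voxels", {
  still <- mk_tracks(data.frame(frame = 0:4, t_h = (0:4) * 0.25,
                                x_um = 10, y_um = -6, z_um = 4), dt_min = 15)
  names(still) <- "c1"
  cfg <- sim_config(1, image = list(size_px = 64L, pixel_size_um = 1,
                                    fg_intensity = 100, bg_intensity = 5,
                                    noise_sd = 0))
  mov <- render_track_movie(still, cfg, spot_sigma_um = 2, n_z = 64L)
  for (f in mov$frames) {
    idx <- which(f == max(f), arr.ind = TRUE)[1, ]
    # origin at (63/2): um position 10 -> px 41.5, brightest at 41 or 42
    expect_equal(unname(idx[2] - 1), 10 / 1 + 31.5, tolerance = 0.51)
    expect_equal(unname(idx[1] - 1), -6 + 31.5, tolerance = 0.51)
    expect_equal(unname(idx[3] - 1), 4 + 31.5, tolerance = 0.51)
  }
  expect_error(render_track_movie(still, cfg, spot_sigma_um = 0.5),
               "spot sigma")
  empty <- render_track_movie(as_ov_tracks(list(), 15), cfg,
                              spot_sigma_um = 2, n_z = 8L, n_frames = 2L)
  expect_equal(length(empty$frames), 2L)
  expect_true(all(vapply(empty$frames, max, numeric(1)) == 5))
})
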