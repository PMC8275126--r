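# spot detection and the simple linear tracker

test_that("detect_spots finds a single rendered spot to sub-pixel accuracy", {
  vol <- array(0, c(48, 48, 48))
  cy <- 20.0; cx <- 30.0; cz <- 25.0
  for (dy in -8:8) for (dx in -8:8) for (dz in -8:8)
    vol[cy + dy + 1, cx + dx + 1, cz + dz + 1] <-
      100 * exp(-(dy^2 + dx^2 + dz^2) / (2 * 4))
  det <- detect_spots(vol, pixel_size_um = 1, sigma_um = 2, quality_min = 1)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$x_um - cx), 0.5)
  expect_lt(abs(det$y_um - cy), 0.5)
  expect_lt(abs(det$z_um - cz), 0.5)
  # empty frame
  expect_equal(nrow(detect_spots(array(0, c(16, 16, 16)), 1, 2, 1)), 0L)
  expect_error(detect_spots(vol, pixel_size_um = 2, sigma_um = 1), "sigma")
})

test_that("rendered movie detections recover >= 95% of ground truth within 1 px", {
  tracks <- mk_separated_walks(50, 4, min_sep = 14, step_max = 1.2,
                               box = 110, seed = 31)
  # recentre into the rendered FOV (origin at stack centre)
  tracks <- as_ov_tracks(lapply(tracks, function(tr) {
    tr$x_um <- tr$x_um - 55; tr$y_um <- tr$y_um - 55; tr$z_um <- tr$z_um - 55
    tr
  }), 15)
  cfg <- sim_config(1, image = list(size_px = 128L, pixel_size_um = 1,
                                    fg_intensity = 100, bg_intensity = 10,
                                    noise_sd = 1))
  mov <- render_track_movie(tracks, cfg, spot_sigma_um = 2, n_z = 128L)
  det <- detect_spots_stack(mov, sigma_um = 2, quality_min = 5)
  tru <- as_detections(tracks)
  hits <- 0L
  for (f in unique(tru$frame)) {
    A <- as.matrix(tru[tru$frame == f, c("x_um", "y_um", "z_um")])
    B <- as.matrix(det[det$frame == f, c("x_um", "y_um", "z_um")])
    d <- as.matrix(dist(rbind(A, B)))[seq_len(nrow(A)), nrow(A) + seq_len(nrow(B))]
    hits <- hits + sum(apply(d, 1, min) < 1)
  }
  expect_gte(hits / nrow(tru), 0.95)
  # linking the detections recovers >= 95% of ground-truth links
  linked <- link_tracks(det, max_disp_um = 5)
  correct <- 0L; total <- 0L
  for (tr in linked) {
    p <- track_positions(tr)
    for (s in seq_len(nrow(p) - 1)) {
      total <- total + 1L
      f1 <- tru[tru$frame == tr$frame[s], ]
      f2 <- tru[tru$frame == tr$frame[s + 1], ]
      id1 <- f1$id[which.min((f1$x_um - p[s, 1])^2 + (f1$y_um - p[s, 2])^2 +
                             (f1$z_um - p[s, 3])^2)]
      id2 <- f2$id[which.min((f2$x_um - p[s + 1, 1])^2 + (f2$y_um - p[s + 1, 2])^2 +
                             (f2$z_um - p[s + 1, 3])^2)]
      if (id1 == id2) correct <- correct + 1L
    }
  }
  expect_gte(correct / total, 0.95)
})

test_that("two distant static points give two full tracks", {
  det <- data.frame(frame = rep(0:9, each = 2),
                    x_um = rep(c(0, 100), 10), y_um = 0, z_um = 0)
  tracks <- link_tracks(det, max_disp_um = 5, dt_min = 15)
  expect_equal(length(tracks), 2L)
  expect_true(all(vapply(tracks, nrow, 1L) == 10L))
})

test_that("a jump beyond the gate terminates both tracks and starts new ones", {
  # both points leap between frames 1 and 2; every cross distance > gate
  det <- data.frame(frame = c(0, 0, 1, 1, 2, 2, 3, 3),
                    x_um = c(0, 40, 0, 40, 18, 58, 18, 58),
                    y_um = 0, z_um = 0)
  tracks <- link_tracks(det, max_disp_um = 10, dt_min = 15)
  expect_equal(length(tracks), 4L)
  expect_true(all(vapply(tracks, nrow, 1L) == 2L))
  expect_setequal(vapply(tracks, function(tr) tr$frame[1], 1L), c(0L, 0L, 2L, 2L))
})

test_that("linking is invariant to detection order within frames", {
  set.seed(41)
  tracks <- mk_separated_walks(12, 6, min_sep = 20, step_max = 2, seed = 41)
  det <- as_detections(tracks)
  a <- link_tracks(det[, -1], max_disp_um = 8, dt_min = 15)
  perm <- det[sample(nrow(det)), -1]
  b <- link_tracks(perm, max_disp_um = 8, dt_min = 15)
  key <- function(trs) unname(sort(vapply(trs, function(tr)
    paste(round(tr$x_um, 9), round(tr$y_um, 9), collapse = "|"), character(1))))
  expect_identical(key(a), key(b))
})

test_that("no linked step ever exceeds the gate", {
  set.seed(42)
  det <- data.frame(frame = rep(0:5, each = 30),
                    x_um = runif(180, 0, 60), y_um = runif(180, 0, 60),
                    z_um = runif(180, 0, 60))
  tracks <- link_tracks(det, max_disp_um = 7, dt_min = 15)
  for (tr in tracks) {
    steps <- sqrt(rowSums(diff(track_positions(tr))^2))
    expect_true(all(steps <= 7 + 1e-9))
  }
})

test_that("greedy linker matches the literal sorted-loop reference on random frames", {
  set.seed(43)
  for (rep in 1:25) {
    nA <- sample(2:12, 1); nB <- sample(2:12, 1)
    A <- matrix(runif(3 * nA, 0, 30), ncol = 3)
    B <- matrix(runif(3 * nB, 0, 30), ncol = 3)
    expect_identical(ovquant:::greedy_match(A, B, 12), oracle_greedy(A, B, 12))
  }
})

test_that("under the separation condition linking equals the optimal assignment", {
  set.seed(44)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    tracks <- mk_separated_walks(n, 2, min_sep = 15, step_max = 6, box = 60,
                                 seed = rep + 100)
    det <- as_detections(tracks)
    A <- as.matrix(det[det$frame == 0, c("x_um", "y_um", "z_um")])
    B <- as.matrix(det[det$frame == 1, c("x_um", "y_um", "z_um")])
    got <- ovquant:::greedy_match(A, B, 7)
    opt <- oracle_optimal_match(A, B, 7)
    expect_identical(unname(got), unname(opt))
  }
})

test_that("representative-track selection follows the product-rank criterion", {
  mk <- function(len_per_step, n_frames) {
    data.frame(frame = seq_len(n_frames) - 1L,
               t_h = (seq_len(n_frames) - 1) * 0.25,
               x_um = (seq_len(n_frames) - 1) * len_per_step, y_um = 0, z_um = 0)
  }
  trks <- as_ov_tracks(list(a = mk(10 / 4, 5), b = mk(5 / 4, 5), c = mk(1 / 4, 5)), 15)
  expect_identical(names(select_representative_tracks(trks, 1)), "a")
  trks2 <- as_ov_tracks(list(short = mk(1, 5), long = mk(0.2, 20)), 15)
  # equal path length (4 um): duration decides
  expect_identical(names(select_representative_tracks(trks2, 1)), "long")
  # oracle: brute-force the ranking criterion on a mixed cohort
  set.seed(45)
  mixed <- lapply(1:8, function(i) mk(runif(1, 0.1, 3), sample(5:15, 1)))
  names(mixed) <- paste0("t", 1:8)
  mixed <- as_ov_tracks(mixed, 15)
  lens <- vapply(mixed, track_path_length, numeric(1))
  durs <- vapply(mixed, track_duration_h, numeric(1))
  score <- rank(lens) * rank(durs)
  want <- names(sort(score, decreasing = TRUE))[1:3]
  expect_setequal(names(select_representative_tracks(mixed, 3)), want)
  expect_warning(select_representative_tracks(mixed, 99), "available")
})
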