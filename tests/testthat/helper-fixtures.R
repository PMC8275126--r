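# shared fixture builders (all generated in code; nothing on disk)

mk_disk_mask <- function(n, r, cx = (n - 1) / 2, cy = (n - 1) / 2) {
  xs <- 0:(n - 1)
  outer((xs - cy)^2, (xs - cx)^2, `+`) <= r^2
}

# small ballistic track along a direction
mk_ballistic_track <- function(n_frames, v_um_per_min, dt_min = 15,
                               dir = c(1, 0, 0), start = c(0, 0, 0)) {
  t <- (seq_len(n_frames) - 1) * dt_min / 60
  step <- v_um_per_min * dt_min
  p <- t(start + outer(dir / sqrt(sum(dir^2)), (seq_len(n_frames) - 1) * step))
  data.frame(frame = seq_len(n_frames) - 1L, t_h = t,
             x_um = p[, 1], y_um = p[, 2], z_um = p[, 3])
}

mk_tracks <- function(..., dt_min = 15) as_ov_tracks(list(...), dt_min)

# n cells with pairwise spacing >= min_sep inside a cube, plus small random
# walks: a fixture that satisfies the tracker's separation condition
mk_separated_walks <- function(n_cells, n_frames, min_sep, step_max,
                               box = 120, dt_min = 15, seed = 1) {
  set.seed(seed)
  pts <- matrix(numeric(0), 0, 3)
  while (nrow(pts) < n_cells) {
    cand <- runif(3, 0, box)
    if (!nrow(pts) || min(sqrt(colSums((t(pts) - cand)^2))) >= min_sep)
      pts <- rbind(pts, cand)
  }
  tracks <- lapply(seq_len(n_cells), function(i) {
    steps <- matrix(runif(3 * (n_frames - 1), -1, 1), ncol = 3)
    steps <- steps / pmax(sqrt(rowSums(steps^2)), 1e-9) *
      runif(n_frames - 1, 0, step_max)
    cums <- matrix(apply(steps, 2, cumsum), ncol = 3)
    p <- rbind(pts[i, ], sweep(cums, 2, pts[i, ], "+"))
    data.frame(frame = seq_len(n_frames) - 1L,
               t_h = (seq_len(n_frames) - 1) * dt_min / 60,
               x_um = p[, 1], y_um = p[, 2], z_um = p[, 3])
  })
  names(tracks) <- as.character(seq_len(n_cells))
  as_ov_tracks(tracks, dt_min)
}
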