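# Mean-squared-displacement and velocity-autocorrelation analysis of
# nuclear tracks, motion-model fitting (diffusive vs directed) and
# ensemble regime-switch detection.

track_dt_min <- function(track) {
  i <- which(diff(track$frame) == 1L)[1]
  if (is.na(i)) stop("track has no consecutive-frame step")
  (track$t_h[i + 1] - track$t_h[i]) * 60
}

#' Time-averaged mean squared displacement of one track
#'
#' For each lag of `l` frames up to `floor(max_lag_fraction * span)`,
#' the mean of `|r(t + l) - r(t)|^2` over every pair of observations `l`
#' frames apart (tracks with dropped frames contribute only the pairs
#' they have).
#'
#' @param track track data.frame (`frame`, `t_h`, `x_um`, `y_um`, `z_um`).
#' @param max_lag_fraction fraction of the track span used as maximum
#'   lag; default 0.25.
#' @return object of class `msd_result`: `lags_min` (starting at 0),
#'   `msd_um2`, `n_pairs`, `dt_min`.
#' @export
compute_msd <- function(track, max_lag_fraction = 0.25) {
  stopifnot(is.data.frame(track))
  if (nrow(track) < 4L) stop("track shorter than 4 frames")
  if (!is.numeric(max_lag_fraction) || max_lag_fraction <= 0 || max_lag_fraction > 1)
    stop("max_lag_fraction must be in (0, 1]")
  dtm <- track_dt_min(track)
  span <- max(track$frame) - min(track$frame)
  max_lag <- max(1L, floor(max_lag_fraction * span))
  p <- track_positions(track)
  fr <- track$frame
  pos_at <- match(min(fr):max(fr), fr)   # row index per frame slot (NA = gap)
  msd <- numeric(max_lag)
  npairs <- integer(max_lag)
  for (l in seq_len(max_lag)) {
    i1 <- pos_at[seq_len(length(pos_at) - l)]
    i2 <- pos_at[seq_len(length(pos_at) - l) + l]
    ok <- !is.na(i1) & !is.na(i2)
    npairs[l] <- sum(ok)
    msd[l] <- if (npairs[l]) mean(rowSums((p[i2[ok], , drop = FALSE] -
                                           p[i1[ok], , drop = FALSE])^2)) else NA_real_
  }
  structure(list(lags_min = c(0, seq_len(max_lag)) * dtm,
                 msd_um2 = c(0, msd),
                 n_pairs = c(nrow(track), npairs),
                 dt_min = dtm),
            class = "msd_result")
}

#' @export
print.msd_result <- function(x, ...) {
  cat("<msd_result>", length(x$lags_min) - 1, "lags, dt =", x$dt_min, "min\n")
  if (!is.null(x$fit))
    cat(sprintf("  fit: D = %.4g um2/min, v = %.4g um/min, regime = %s\n",
                x$fit$D_um2_per_min, x$fit$v_um_per_min, x$fit$regime))
  invisible(x)
}

#' Ensemble mean squared displacement
#'
#' Per-lag weighted mean of the per-track time-averaged MSDs, weighted by
#' each track's number of displacement pairs at that lag.
#'
#' @param tracks an `ov_tracks` object; tracks shorter than 4 frames are
#'   skipped.
#' @param max_lag_fraction per-track maximum-lag fraction.
#' @return an `msd_result`.
#' @export
ensemble_msd <- function(tracks, max_lag_fraction = 0.25) {
  per <- lapply(tracks, function(tr)
    if (nrow(tr) >= 4L) tryCatch(compute_msd(tr, max_lag_fraction),
                                 error = function(e) NULL) else NULL)
  per <- per[!vapply(per, is.null, logical(1))]
  if (!length(per)) stop("no track is long enough for MSD analysis")
  max_l <- max(vapply(per, function(m) length(m$lags_min), 1L))
  wsum <- numeric(max_l); wt <- numeric(max_l)
  for (m in per) {
    k <- seq_along(m$lags_min)
    ok <- !is.na(m$msd_um2)
    wsum[k][ok] <- wsum[k][ok] + m$msd_um2[ok] * m$n_pairs[ok]
    wt[k][ok] <- wt[k][ok] + m$n_pairs[ok]
  }
  dtm <- per[[1]]$dt_min
  keep <- wt > 0
  structure(list(lags_min = (seq_len(max_l) - 1)[keep] * dtm,
                 msd_um2 = (wsum / pmax(wt, 1))[keep],
                 n_pairs = wt[keep],
                 dt_min = dtm),
            class = "msd_result")
}

#' Fit a diffusion-plus-flow motion model to an MSD curve
#'
#' Least squares fit of `MSD(tau) = 2 * dim * D * tau + v^2 * tau^2` with
#' both coefficients constrained non-negative (the best of the free,
#' single-term and null fits is kept). The regime label follows the
#' quadratic term's share of the MSD at the window end: `diffusive`
#' below `share_lo`, `directed` above `share_hi`, otherwise `mixed`; a
#' null fit with substantial residual is `undetermined`.
#'
#' @param msd an `msd_result`.
#' @param dim spatial dimensionality, 2 or 3.
#' @param share_lo,share_hi regime thresholds on the quadratic share.
#' @return list of class `motion_fit`: `D_um2_per_min`, `v_um_per_min`,
#'   `regime`, `window` (lags used, minutes), `quadratic_share`, `rss`.
#' @export
fit_motion_model <- function(msd, dim = 3, share_lo = 0.25, share_hi = 0.75) {
  stopifnot(inherits(msd, "msd_result"), dim %in% c(2, 3))
  pos <- msd$lags_min > 0 & !is.na(msd$msd_um2)
  tau <- msd$lags_min[pos]
  y <- msd$msd_um2[pos]
  if (length(tau) < 4L) stop("need at least 4 positive lags to fit")
  fits <- list()
  X <- cbind(tau, tau^2)
  beta <- tryCatch(solve(crossprod(X), crossprod(X, y)), error = function(e) NULL)
  if (!is.null(beta) && all(beta >= 0))
    fits$free <- c(beta[1], beta[2])
  fits$lin <- c(max(sum(y * tau) / sum(tau^2), 0), 0)
  fits$quad <- c(0, max(sum(y * tau^2) / sum(tau^4), 0))
  fits$null <- c(0, 0)
  rss <- vapply(fits, function(b) sum((y - b[1] * tau - b[2] * tau^2)^2), numeric(1))
  best <- fits[[which.min(rss)]]
  a <- best[1]; b <- best[2]
  te <- max(tau)
  denom <- a * te + b * te^2
  share <- if (denom > 0) b * te^2 / denom else 0
  regime <- if (a == 0 && b == 0 && min(rss) > 1e-6 * max(sum(y^2), 1e-12)) {
    "undetermined"
  } else if (share < share_lo) "diffusive"
  else if (share > share_hi) "directed"
  else "mixed"
  structure(list(D_um2_per_min = a / (2 * dim), v_um_per_min = sqrt(b),
                 regime = regime, window = range(tau), quadratic_share = share,
                 rss = min(rss)),
            class = "motion_fit")
}

#' @export
print.motion_fit <- function(x, ...) {
  cat(sprintf("<motion_fit> D = %.4g um2/min, v = %.4g um/min, regime = %s\n",
              x$D_um2_per_min, x$v_um_per_min, x$regime))
  invisible(x)
}

# per-track frame velocities (um/min) for consecutive-frame steps only
track_velocities <- function(track) {
  dtm <- track_dt_min(track)
  p <- track_positions(track)
  d <- diff(track$frame)
  ok <- which(d == 1L)
  list(frame = track$frame[ok],
       v = (p[ok + 1L, , drop = FALSE] - p[ok, , drop = FALSE]) / dtm,
       dt_min = dtm)
}

#' Normalized velocity autocorrelation of one track
#'
#' Frame velocities `v(t) = (r(t+1) - r(t)) / dt`; the autocorrelation at
#' lag `l` is the mean of `v(t) . v(t+l)` over valid pairs, normalized by
#' the mean squared speed, so that the value at lag 0 is 1, persistent
#' straight motion stays at 1, and uncorrelated Brownian steps decay to 0.
#'
#' @param track track data.frame with at least 3 detections.
#' @param max_lag_fraction maximum lag as a fraction of the track span.
#' @return object of class `vac_result`: `lags_min`, `vac`, `n_pairs`.
#' @export
velocity_autocorrelation <- function(track, max_lag_fraction = 1) {
  stopifnot(is.data.frame(track))
  if (nrow(track) < 3L) stop("track shorter than 3 frames")
  tv <- track_velocities(track)
  if (nrow(tv$v) < 2L) stop("track has fewer than 2 consecutive-frame steps")
  norm <- mean(rowSums(tv$v^2))
  if (norm == 0) stop("zero total speed: normalization undefined")
  span <- max(tv$frame) - min(tv$frame)
  max_lag <- max(1L, floor(max_lag_fraction * span))
  fr <- tv$frame
  pos_at <- match(min(fr):max(fr), fr)
  vac <- numeric(max_lag); npairs <- integer(max_lag)
  for (l in seq_len(max_lag)) {
    i1 <- pos_at[seq_len(length(pos_at) - l)]
    i2 <- pos_at[seq_len(length(pos_at) - l) + l]
    ok <- !is.na(i1) & !is.na(i2)
    npairs[l] <- sum(ok)
    vac[l] <- if (npairs[l]) mean(rowSums(tv$v[i1[ok], , drop = FALSE] *
                                          tv$v[i2[ok], , drop = FALSE])) / norm
    else NA_real_
  }
  structure(list(lags_min = c(0, seq_len(max_lag)) * tv$dt_min,
                 vac = c(1, vac), n_pairs = c(nrow(tv$v), npairs),
                 dt_min = tv$dt_min),
            class = "vac_result")
}

#' Ensemble normalized velocity autocorrelation
#'
#' Dot products and squared speeds are pooled over all tracks before
#' normalizing, matching the per-lag averaged "all tracks" curve.
#'
#' @param tracks an `ov_tracks` object.
#' @param max_lag maximum lag in frames.
#' @return a `vac_result`.
#' @export
ensemble_vac <- function(tracks, max_lag = 10L) {
  dots <- numeric(max_lag); npairs <- numeric(max_lag)
  norm_sum <- 0; norm_n <- 0; dtm <- NA_real_
  for (tr in tracks) {
    if (nrow(tr) < 3L) next
    tv <- tryCatch(track_velocities(tr), error = function(e) NULL)
    if (is.null(tv) || nrow(tv$v) < 2L) next
    dtm <- tv$dt_min
    norm_sum <- norm_sum + sum(rowSums(tv$v^2))
    norm_n <- norm_n + nrow(tv$v)
    fr <- tv$frame
    pos_at <- match(min(fr):max(fr), fr)
    for (l in seq_len(min(max_lag, max(fr) - min(fr)))) {
      i1 <- pos_at[seq_len(length(pos_at) - l)]
      i2 <- pos_at[seq_len(length(pos_at) - l) + l]
      ok <- !is.na(i1) & !is.na(i2)
      if (any(ok)) {
        dots[l] <- dots[l] + sum(rowSums(tv$v[i1[ok], , drop = FALSE] *
                                         tv$v[i2[ok], , drop = FALSE]))
        npairs[l] <- npairs[l] + sum(ok)
      }
    }
  }
  if (norm_n == 0 || norm_sum == 0) stop("no usable velocities in ensemble")
  norm <- norm_sum / norm_n
  keep <- npairs > 0
  structure(list(lags_min = c(0, which(keep)) * dtm,
                 vac = c(1, (dots[keep] / npairs[keep]) / norm),
                 n_pairs = c(norm_n, npairs[keep]),
                 dt_min = dtm),
            class = "vac_result")
}

#' @export
print.vac_result <- function(x, ...) {
  cat("<vac_result>", length(x$lags_min) - 1, "lags; vac(1) =",
      if (length(x$vac) > 1) sprintf("%.3f", x$vac[2]) else NA, "\n")
  invisible(x)
}

#' Detect the diffusive-to-directed regime switch
#'
#' For every frame-step pair the ensemble directional persistence
#' `sum(v(t) . v(t+1)) / sum(|v(t)| |v(t+1)|)` is computed across all
#' tracks; Brownian motion gives values near 0 and radially directed
#' migration values near 1. The switch is placed at the two-segment
#' changepoint (least-squares split) of this persistence series.
#'
#' @param tracks an `ov_tracks` object.
#' @return list: `switch_frame` (0-based frame at which the directed
#'   segment starts), `switch_time_h`, `persistence` data.frame.
#' @export
detect_regime_switch <- function(tracks) {
  dtm <- NA_real_
  f_all <- list(); dot_all <- list(); mag_all <- list()
  k <- 0L
  for (tr in tracks) {
    if (nrow(tr) < 3L) next
    tv <- tryCatch(track_velocities(tr), error = function(e) NULL)
    if (is.null(tv) || nrow(tv$v) < 2L) next
    dtm <- tv$dt_min
    fr <- tv$frame
    consec <- which(diff(fr) == 1L)
    if (!length(consec)) next
    k <- k + 1L
    f_all[[k]] <- fr[consec]
    dot_all[[k]] <- rowSums(tv$v[consec, , drop = FALSE] *
                            tv$v[consec + 1L, , drop = FALSE])
    mag_all[[k]] <- sqrt(rowSums(tv$v[consec, , drop = FALSE]^2) *
                         rowSums(tv$v[consec + 1L, , drop = FALSE]^2))
  }
  if (!k) stop("no usable velocity pairs in ensemble")
  f0 <- unlist(f_all)
  fac <- factor(f0)
  num <- rowsum(unlist(dot_all), fac)[, 1]
  den <- rowsum(unlist(mag_all), fac)[, 1]
  fr <- as.integer(levels(fac))
  pers <- num / pmax(den, .Machine$double.eps)
  # two-segment least-squares changepoint
  n <- length(pers)
  if (n < 3L) stop("too few time points for changepoint detection")
  best <- Inf; best_s <- 2L
  cs <- cumsum(pers); cs2 <- cumsum(pers^2)
  for (s in 2:(n - 1)) {
    n1 <- s - 1; n2 <- n - n1
    s1 <- cs[n1]; s2 <- cs[n] - s1
    q1 <- cs2[n1]; q2 <- cs2[n] - q1
    sse <- (q1 - s1^2 / n1) + (q2 - s2^2 / n2)
    if (sse < best) { best <- sse; best_s <- s }
  }
  switch_frame <- fr[best_s]
  list(switch_frame = switch_frame,
       switch_time_h = switch_frame * dtm / 60,
       persistence = data.frame(frame = fr, persistence = pers))
}
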