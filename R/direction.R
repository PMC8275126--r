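# Radial directionality of tracks relative to the organoid centre:
# inward/outward classification, cohort fractions and angular histograms.

#' Estimate the organoid centre trajectory from detections
#'
#' Per-frame centroid of all detections, smoothed with a centered moving
#' average; a frame without detections carries the previous centre
#' forward with a warning. With `constant = TRUE` a single time-invariant
#' centre (the centroid of everything) is used.
#'
#' @param detections detection table (`frame`, `x_um`, `y_um`, `z_um`).
#' @param smooth_frames moving-average window in frames.
#' @param constant use one constant centre instead of a trajectory.
#' @return data.frame `frame`, `cx_um`, `cy_um`, `cz_um` covering the
#'   full frame range.
#' @export
estimate_center <- function(detections, smooth_frames = 5L, constant = FALSE) {
  stopifnot(is.data.frame(detections), nrow(detections) >= 1L)
  frames <- min(detections$frame):max(detections$frame)
  if (constant) {
    c0 <- colMeans(detections[, c("x_um", "y_um", "z_um")])
    return(data.frame(frame = frames, cx_um = c0[1], cy_um = c0[2], cz_um = c0[3]))
  }
  fac <- factor(detections$frame, levels = frames)
  cnt <- as.integer(table(fac))
  sums <- rowsum(as.matrix(detections[, c("x_um", "y_um", "z_um")]), fac)
  cen <- matrix(NA_real_, length(frames), 3)
  cen[match(as.integer(rownames(sums)), frames), ] <- sums
  cen[cnt > 0, ] <- cen[cnt > 0, , drop = FALSE] / cnt[cnt > 0]
  if (any(cnt == 0)) {
    warning("frame(s) without detections: carrying previous centre forward")
    for (i in which(cnt == 0)) {
      cen[i, ] <- if (i > 1) cen[i - 1, ] else cen[which(cnt > 0)[1], ]
    }
  }
  sm <- matrix(apply(cen, 2, moving_average, window = smooth_frames), ncol = 3)
  data.frame(frame = frames, cx_um = sm[, 1], cy_um = sm[, 2], cz_um = sm[, 3])
}

centre_at <- function(centre, frames) {
  if (is.numeric(centre) && length(centre) == 3L)
    return(matrix(centre, length(frames), 3, byrow = TRUE))
  i <- match(frames, centre$frame)
  i[is.na(i)] <- 1L
  as.matrix(centre[i, c("cx_um", "cy_um", "cz_um")])
}

#' Classify one track as outward, inward or static
#'
#' The net radial displacement is the change in distance to the organoid
#' centre between the track's first and last detections; tracks whose
#' net displacement does not exceed the deadband are `static`.
#'
#' @param track track data.frame.
#' @param centre centre trajectory from [estimate_center()] or a fixed
#'   3-vector (um).
#' @param deadband_um magnitude below which a track counts as static.
#' @return list: `class`, `net_radial_um`.
#' @export
classify_track <- function(track, centre, deadband_um = 2) {
  stopifnot(nrow(track) >= 2L)
  p <- track_positions(track)
  cen <- centre_at(centre, track$frame[c(1, nrow(track))])
  r1 <- sqrt(sum((p[1, ] - cen[1, ])^2))
  r2 <- sqrt(sum((p[nrow(p), ] - cen[2, ])^2))
  net <- r2 - r1
  cls <- if (net > deadband_um) "outward" else if (net < -deadband_um) "inward" else "static"
  list(class = cls, net_radial_um = net)
}

# per-step angle (deg) between displacement and the outward radial unit
# vector at the step start; returns the per-track mean angle
track_mean_angle <- function(track, centre) {
  p <- track_positions(track)
  if (nrow(p) < 2L) return(NA_real_)
  cen <- centre_at(centre, track$frame)
  rel <- p - cen
  disp <- diff(p)
  radial <- rel[-nrow(rel), , drop = FALSE]
  rn <- sqrt(rowSums(radial^2))
  dn <- sqrt(rowSums(disp^2))
  ok <- rn > 0 & dn > 0
  if (!any(ok)) return(NA_real_)
  cosang <- rowSums(disp[ok, , drop = FALSE] * radial[ok, , drop = FALSE]) /
    (dn[ok] * rn[ok])
  mean(acos(pmin(pmax(cosang, -1), 1))) * 180 / pi
}

#' Classify all tracks and report per-track directionality
#'
#' @param tracks an `ov_tracks` object.
#' @param centre centre trajectory or fixed 3-vector.
#' @param deadband_um static deadband in micrometres.
#' @return data.frame: `id`, `net_radial_um`, `class`, `mean_angle_deg`.
#' @export
classify_tracks <- function(tracks, centre, deadband_um = 2) {
  keep <- vapply(tracks, nrow, 1L) >= 2L
  tracks <- tracks[keep]
  net <- vapply(tracks, function(tr)
    classify_track(tr, centre, deadband_um)$net_radial_um, numeric(1))
  ang <- vapply(tracks, track_mean_angle, numeric(1), centre = centre)
  cls <- ifelse(net > deadband_um, "outward",
                ifelse(net < -deadband_um, "inward", "static"))
  data.frame(id = names(tracks), net_radial_um = net, class = cls,
             mean_angle_deg = ang, row.names = NULL)
}

#' Summarize outward/inward/static fractions
#'
#' @param classes character vector of classes (or a [classify_tracks()]
#'   result).
#' @return list with `n`, per-class fractions and binomial 95% CIs.
#' @export
summarize_fractions <- function(classes) {
  if (is.data.frame(classes)) classes <- classes$class
  stopifnot(length(classes) >= 1L)
  n <- length(classes)
  out <- list(n = n)
  for (cl in c("outward", "inward", "static")) {
    k <- sum(classes == cl)
    ci <- binom.test(k, n)$conf.int
    out[[paste0(cl, "_fraction")]] <- k / n
    out[[paste0(cl, "_ci95")]] <- as.numeric(ci)
  }
  out
}

#' Angular histogram of track directions, split by class
#'
#' Each track contributes its mean per-step angle to the outward radial
#' direction (0 deg = straight outward, 180 deg = straight inward),
#' binned over `[0, 180]`; separate counts are reported for outward- and
#' inward-classified tracks.
#'
#' @param tracks an `ov_tracks` object.
#' @param centre centre trajectory or fixed 3-vector.
#' @param n_bins number of angular bins (>= 4).
#' @param deadband_um classification deadband.
#' @return data.frame: `bin_start_deg`, `bin_end_deg`, `count_outward`,
#'   `count_inward`.
#' @export
direction_histogram <- function(tracks, centre, n_bins = 18L, deadband_um = 2) {
  if (n_bins < 4L) stop("n_bins must be at least 4")
  cls <- classify_tracks(tracks, centre, deadband_um)
  edges <- seq(0, 180, length.out = n_bins + 1L)
  bin_of <- function(a) pmin(pmax(findInterval(a, edges, rightmost.closed = TRUE), 1L), n_bins)
  out <- data.frame(bin_start_deg = edges[-length(edges)], bin_end_deg = edges[-1])
  for (side in c("outward", "inward")) {
    ang <- cls$mean_angle_deg[cls$class == side & !is.na(cls$mean_angle_deg)]
    out[[paste0("count_", side)]] <- tabulate(bin_of(ang), n_bins)
  }
  out
}
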