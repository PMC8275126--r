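# Simple linear tracker: gated greedy mutual-nearest-neighbour linking of
# detections between consecutive frames. No gap closing, no merging or
# splitting.

# candidate pairs (i in A, j in B) with distance <= gate, computed in
# column chunks to bound memory on large frames
candidate_pairs <- function(A, B, gate, chunk = 1024L) {
  ci <- integer(0); cj <- integer(0); cd <- numeric(0)
  nB <- nrow(B)
  for (start in seq(1L, nB, by = chunk)) {
    cols <- start:min(start + chunk - 1L, nB)
    d2 <- outer(rowSums(A^2), rowSums(B[cols, , drop = FALSE]^2), `+`) -
      2 * A %*% t(B[cols, , drop = FALSE])
    hit <- which(d2 <= gate^2, arr.ind = TRUE)
    if (nrow(hit)) {
      ci <- c(ci, hit[, 1])
      cj <- c(cj, cols[hit[, 2]])
      cd <- c(cd, sqrt(pmax(d2[hit], 0)))
    }
  }
  list(i = ci, j = cj, d = cd)
}

# greedy matching by ascending distance, realised as iterated mutual
# nearest-neighbour acceptance (identical result: the closest remaining
# pair is always mutual-NN, and a mutual-NN pair stays mutual-NN as
# competitors are removed). Deterministic tie-break by (distance, i, j).
greedy_match <- function(A, B, gate) {
  match_ij <- rep(NA_integer_, nrow(A))
  if (!nrow(A) || !nrow(B)) return(match_ij)
  cp <- candidate_pairs(A, B, gate)
  if (!length(cp$i)) return(match_ij)
  ord <- order(cp$d, cp$i, cp$j)
  ci <- cp$i[ord]; cj <- cp$j[ord]
  while (length(ci)) {
    best_i <- !duplicated(ci)
    best_j <- !duplicated(cj)
    acc <- which(best_i & best_j)
    match_ij[ci[acc]] <- cj[acc]
    used_i <- ci[acc]; used_j <- cj[acc]
    keep <- !(ci %in% used_i) & !(cj %in% used_j)
    ci <- ci[keep]; cj <- cj[keep]
  }
  match_ij
}

#' Link detections into tracks (simple linear tracker)
#'
#' Frame-to-frame greedy assignment: candidate pairs within
#' `max_disp_um` are taken in order of increasing distance and accepted
#' when both endpoints are still unassigned (mutual nearest neighbours).
#' Unmatched detections start new tracks; there is no gap closing and no
#' merging/splitting, so a missed detection terminates its track.
#' Tracks with fewer than two detections are dropped.
#'
#' @param detections data.frame with columns `frame` (0-based integer),
#'   `x_um`, `y_um`, `z_um` and optionally `t_h`.
#' @param max_disp_um linking gate: maximum displacement per frame.
#' @param dt_min frame interval (minutes), used to fill `t_h` when absent.
#' @return an [as_ov_tracks()] object.
#' @export
link_tracks <- function(detections, max_disp_um, dt_min = NULL) {
  stopifnot(is.data.frame(detections),
            all(c("frame", "x_um", "y_um", "z_um") %in% names(detections)))
  if (!is.numeric(max_disp_um) || max_disp_um <= 0)
    stop("max_disp_um must be strictly positive")
  if (is.null(detections$t_h)) {
    if (is.null(dt_min)) stop("need t_h column or dt_min to time detections")
    detections$t_h <- detections$frame * dt_min / 60
  }
  if (is.null(dt_min)) {
    fr <- sort(unique(detections$frame))
    dt_min <- if (length(fr) > 1)
      (detections$t_h[match(fr[2], detections$frame)] -
         detections$t_h[match(fr[1], detections$frame)]) * 60 / (fr[2] - fr[1])
    else NA_real_
  }
  frames <- sort(unique(detections$frame))
  by_frame <- split(seq_len(nrow(detections)), detections$frame)
  coords <- as.matrix(detections[, c("x_um", "y_um", "z_um")])

  track_of <- integer(0)       # track id of each detection in current frame
  tracks_rows <- list()        # per-track detection row indices
  new_track <- function(row) {
    tracks_rows[[length(tracks_rows) + 1L]] <<- row
    length(tracks_rows)
  }
  prev_rows <- by_frame[[as.character(frames[1])]]
  prev_tracks <- vapply(prev_rows, new_track, integer(1))
  if (length(frames) > 1) for (k in 2:length(frames)) {
    rows <- by_frame[[as.character(frames[k])]]
    if (frames[k] == frames[k - 1] + 1L) {
      m <- greedy_match(coords[prev_rows, , drop = FALSE],
                        coords[rows, , drop = FALSE], max_disp_um)
    } else {
      m <- rep(NA_integer_, length(prev_rows))  # gap in the frame grid
    }
    cur_tracks <- rep(NA_integer_, length(rows))
    linked <- which(!is.na(m))
    for (ii in linked) {
      tid <- prev_tracks[ii]
      tracks_rows[[tid]] <- c(tracks_rows[[tid]], rows[m[ii]])
      cur_tracks[m[ii]] <- tid
    }
    for (jj in which(is.na(cur_tracks)))
      cur_tracks[jj] <- new_track(rows[jj])
    prev_rows <- rows
    prev_tracks <- cur_tracks
  }
  keep <- vapply(tracks_rows, length, 1L) >= 2L
  tracks <- lapply(tracks_rows[keep], function(r)
    data.frame(frame = as.integer(detections$frame[r]), t_h = detections$t_h[r],
               x_um = detections$x_um[r], y_um = detections$y_um[r],
               z_um = detections$z_um[r]))
  names(tracks) <- as.character(seq_along(tracks))
  as_ov_tracks(tracks, dt_min)
}

#' Select representative tracks
#'
#' Tracks are scored by the product of two ranks: total path length
#' (distance travelled) and duration; the top `n` are returned,
#' deterministic ties broken by track name.
#'
#' @param tracks an `ov_tracks` object.
#' @param n number of tracks wanted.
#' @return an `ov_tracks` subset.
#' @export
select_representative_tracks <- function(tracks, n) {
  stopifnot(inherits(tracks, "ov_tracks"), n >= 1)
  if (n > length(tracks)) {
    warning("asked for ", n, " tracks but only ", length(tracks), " available")
    n <- length(tracks)
  }
  len <- vapply(tracks, track_path_length, numeric(1))
  dur <- vapply(tracks, track_duration_h, numeric(1))
  score <- rank(len, ties.method = "average") * rank(dur, ties.method = "average")
  ord <- order(-score, names(tracks))
  tracks[ord[seq_len(n)]]
}
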