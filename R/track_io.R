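# Track-table CSV interchange in the TrackMate dialect:
# TRACK_ID, FRAME, POSITION_X, POSITION_Y, POSITION_Z, POSITION_T, QUALITY
# (positions in um, POSITION_T in hours). Extra columns are preserved.

TRACK_COLS <- c("TRACK_ID", "FRAME", "POSITION_X", "POSITION_Y",
                "POSITION_Z", "POSITION_T")

#' Write tracks to a track-table CSV
#'
#' @param tracks an `ov_tracks` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(tracks, path) {
  stopifnot(inherits(tracks, "ov_tracks"))
  det <- as_detections(tracks)
  num <- function(x) formatC(x, digits = 17, format = "g")
  df <- data.frame(
    TRACK_ID = det$id,
    FRAME = det$frame,
    POSITION_X = num(det$x_um),
    POSITION_Y = num(det$y_um),
    POSITION_Z = num(det$z_um),
    POSITION_T = num(det$t_h),
    QUALITY = if (!is.null(det$quality)) num(det$quality) else 1,
    stringsAsFactors = FALSE
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a track-table CSV
#'
#' Rows are grouped by `TRACK_ID` and sorted by `FRAME`; row order in the
#' file is irrelevant. Duplicate `(TRACK_ID, FRAME)` pairs are refused
#' with their row numbers.
#'
#' @param path CSV path.
#' @return an `ov_tracks` object; extra columns are kept on each track.
#' @export
read_track_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRACK_COLS, names(df))
  if (length(missing))
    stop("track CSV missing column(s): ", paste(missing, collapse = ", "))
  key <- paste(df$TRACK_ID, df$FRAME)
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("duplicate (TRACK_ID, FRAME) rows: ", paste(bad, collapse = ", "))
  }
  extra <- setdiff(names(df), c(TRACK_COLS, "QUALITY"))
  ids <- unique(df$TRACK_ID)
  groups <- split(seq_len(nrow(df)), factor(df$TRACK_ID, levels = ids))
  tracks <- lapply(groups, function(rows) {
    g <- df[rows, , drop = FALSE]
    g <- g[order(g$FRAME), , drop = FALSE]
    out <- data.frame(frame = as.integer(g$FRAME), t_h = g$POSITION_T,
                      x_um = g$POSITION_X, y_um = g$POSITION_Y,
                      z_um = g$POSITION_Z)
    if (!is.null(g$QUALITY)) out$quality <- g$QUALITY
    for (cc in extra) out[[cc]] <- g[[cc]]
    out
  })
  names(tracks) <- as.character(ids)
  # frame interval from the first consecutive-frame step found
  dt_min <- NA_real_
  for (tr in tracks) {
    i <- which(diff(tr$frame) == 1L)[1]
    if (!is.na(i)) { dt_min <- (tr$t_h[i + 1] - tr$t_h[i]) * 60; break }
  }
  as_ov_tracks(tracks, dt_min)
}

#' Read a detection table CSV (track dialect, track ids ignored)
#'
#' @param path CSV path.
#' @return detection data.frame (`frame`, `t_h`, `x_um`, `y_um`, `z_um`).
#' @export
read_detection_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(setdiff(TRACK_COLS, "TRACK_ID"), names(df))
  if (length(missing))
    stop("detection CSV missing column(s): ", paste(missing, collapse = ", "))
  data.frame(frame = as.integer(df$FRAME), t_h = df$POSITION_T,
             x_um = df$POSITION_X, y_um = df$POSITION_Y, z_um = df$POSITION_Z)
}
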