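#' Track containers
#'
#' A track is one cell's time-ordered chain of detections: a data.frame
#' with columns `frame` (0-based, strictly increasing), `t_h` (hours),
#' `x_um`, `y_um`, `z_um` (micrometres). A set of tracks is a named list
#' of such data.frames of class `ov_tracks`, carrying the frame interval
#' `dt_min` as an attribute.
#'
#' @param tracks named list of track data.frames.
#' @param dt_min frame interval in minutes.
#' @return an `ov_tracks` object.
#' @export
as_ov_tracks <- function(tracks, dt_min) {
  stopifnot(is.list(tracks))
  for (tr in tracks) {
    stopifnot(is.data.frame(tr),
              all(c("frame", "t_h", "x_um", "y_um", "z_um") %in% names(tr)))
    if (is.unsorted(tr$frame, strictly = TRUE))
      stop("track frames must be strictly increasing")
  }
  if (is.null(names(tracks))) names(tracks) <- as.character(seq_along(tracks))
  structure(tracks, dt_min = dt_min, class = "ov_tracks")
}

#' @export
print.ov_tracks <- function(x, ...) {
  len <- vapply(x, nrow, 1L)
  cat("<ov_tracks>", length(x), "tracks,", sum(len), "detections, dt =",
      attr(x, "dt_min"), "min\n")
  invisible(x)
}

#' @export
`[.ov_tracks` <- function(x, i) {
  as_ov_tracks(unclass(x)[i], attr(x, "dt_min"))
}

track_positions <- function(track) {
  as.matrix(track[, c("x_um", "y_um", "z_um"), drop = FALSE])
}

#' Total path length of a track (sum of step lengths, um)
#' @param track a track data.frame.
#' @return numeric scalar.
#' @export
track_path_length <- function(track) {
  p <- track_positions(track)
  if (nrow(p) < 2L) return(0)
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Duration of a track in hours
#' @param track a track data.frame.
#' @return numeric scalar.
#' @export
track_duration_h <- function(track) {
  diff(range(track$t_h))
}

#' Flatten tracks into a detection table
#' @param tracks an `ov_tracks` object.
#' @return data.frame with columns `id`, `frame`, `t_h`, `x_um`, `y_um`, `z_um`.
#' @export
as_detections <- function(tracks) {
  n <- vapply(tracks, nrow, 1L)
  pull <- function(col) unlist(lapply(tracks, `[[`, col), use.names = FALSE)
  data.frame(id = rep(names(tracks), n),
             frame = pull("frame"), t_h = pull("t_h"),
             x_um = pull("x_um"), y_um = pull("y_um"), z_um = pull("z_um"))
}
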