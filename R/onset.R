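#' Summarize a fluorescence stack into an intensity trace
#'
#' Per frame, the maximum intensity projection over z (identity for 2D
#' frames) is summed over all pixels, giving the raw fluorescence time
#' course of one aggregate.
#'
#' @param stack an [image_stack()] with frame-interval calibration.
#' @param id trace identifier.
#' @return an [intensity_trace()] with raw intensities.
#' @export
summarize_frame <- function(stack, id = "stack") {
  stopifnot(inherits(stack, "image_stack"))
  interval <- attr(stack, "frame_interval_min")
  if (is.null(interval) || !is.finite(interval))
    stop("stack has no frame_interval_min calibration")
  if (length(stack$frames) < 5L) stop("need at least 5 frames")
  raw <- vapply(stack$frames, function(f) {
    if (length(dim(f)) == 3L) f <- apply(f, c(1, 2), max)  # max projection over z
    sum(f)
  }, numeric(1))
  times <- (seq_along(raw) - 1) * interval / 60
  intensity_trace(id, times, raw)
}

#' Normalize an intensity trace to [0, 1]
#'
#' Min-max normalization `(x - min) / (max - min)`; any affine transform
#' of the raw intensities yields the same normalized trace.
#'
#' @param trace an [intensity_trace()].
#' @return the trace with `intensity_norm` filled in.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "intensity_trace"))
  x <- trace$intensity_raw
  rng <- range(x)
  if (diff(rng) == 0) stop("constant trace cannot be normalized")
  trace$intensity_norm <- (x - rng[1]) / diff(rng)
  trace
}

# centered moving average; window shrinks symmetrically at the edges
moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  h <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    k <- min(h, i - 1L, n - i)
    mean(x[(i - k):(i + k)])
  }, numeric(1))
}

# first derivative on a uniform grid: central differences inside,
# one-sided at the ends
first_derivative <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  if (n > 2) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d
}

#' Detect reporter-expression onset in a normalized trace
#'
#' The onset is the time of the global maximum of the first derivative of
#' the (optionally smoothed) normalized intensity: the steepest rise of
#' the sigmoidal expression curve. Smoothing is a centered moving average
#' over `smooth_window` frames; the derivative uses central differences
#' (one-sided at the ends). Ties are broken by the earliest time. If the
#' maximum falls on the final frame the result is flagged `censored`,
#' since the true onset may lie beyond the movie.
#'
#' @param trace a normalized [intensity_trace()].
#' @param smooth_window odd window length in frames (1 = no smoothing).
#' @return list of class `onset_result`: `onset_h`, `derivative_peak`
#'   (normalized units per hour), `smoothed`, `window`, `censored`.
#' @export
detect_onset <- function(trace, smooth_window = 3L) {
  stopifnot(inherits(trace, "intensity_trace"))
  if (is.null(trace$intensity_norm))
    stop("trace must be normalized first (see normalize_trace)")
  smooth_window <- as.integer(smooth_window)
  if (smooth_window < 1L || smooth_window %% 2L == 0L)
    stop("smooth_window must be odd and >= 1")
  dt <- trace$times_h[2] - trace$times_h[1]
  y <- moving_average(trace$intensity_norm, smooth_window)
  d <- first_derivative(y, dt)
  i <- which.max(d)  # which.max takes the earliest of tied maxima
  structure(
    list(onset_h = trace$times_h[i], derivative_peak = d[i],
         smoothed = smooth_window > 1L, window = smooth_window,
         censored = i == length(d)),
    class = "onset_result")
}

#' @export
print.onset_result <- function(x, ...) {
  cat(sprintf("<onset_result> onset = %.2f h (peak slope %.3f /h%s)\n",
              x$onset_h, x$derivative_peak,
              if (x$censored) ", CENSORED" else ""))
  invisible(x)
}

#' Summarize a cohort of onset results
#'
#' Mean and standard error (sd / sqrt(n)) of the non-censored onset
#' times. With a single onset the SEM is reported as 0 with a warning.
#'
#' @param results list of [detect_onset()] results.
#' @return list with `mean_h`, `sem_h`, `n`.
#' @export
summarize_onsets <- function(results) {
  stopifnot(length(results) >= 1L)
  censored <- vapply(results, function(r) isTRUE(r$censored), logical(1))
  onsets <- vapply(results[!censored], function(r) r$onset_h, numeric(1))
  if (!length(onsets)) stop("all onsets are censored")
  sem <- if (length(onsets) == 1L) {
    warning("single onset: SEM undefined, reported as 0")
    0
  } else sd(onsets) / sqrt(length(onsets))
  list(mean_h = mean(onsets), sem_h = sem, n = length(onsets))
}
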