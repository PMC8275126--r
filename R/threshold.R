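#' Minimum-method automatic threshold
#'
#' The classic bimodal-valley threshold: the 256-bin histogram of the
#' image is repeatedly smoothed with a 3-bin mean filter until exactly
#' two local maxima remain; the threshold is the grey value of the
#' (first) minimum between them. Used on the bright-field channel to
#' delineate the organoid and on the fluorescence channel to delineate
#' expression domains.
#'
#' @param image an [image_frame()] or numeric vector/matrix of grey levels.
#' @param max_iter iteration cap for the smoothing loop; a histogram that
#'   has not become bimodal by then is rejected as unimodal.
#' @return threshold grey value (on the image's own intensity scale) with
#'   attributes `histogram` (the converged smoothed histogram),
#'   `iterations`, and `peaks` (bin indices of the two surviving maxima).
#' @export
minimum_threshold <- function(image, max_iter = 10000L) {
  x <- as.numeric(image)
  rng <- range(x)
  if (diff(rng) == 0) stop("unimodal image: constant intensities")
  nbins <- 256L
  bin <- pmin(floor((x - rng[1]) / diff(rng) * nbins) + 1L, nbins)
  h <- as.numeric(tabulate(bin, nbins))
  # plateau-aware local maxima: a maximal run of equal counts is one peak
  # when both flanking runs are strictly lower (image ends count as -Inf)
  count_peaks <- function(h) {
    r <- rle(h)
    v <- c(-Inf, r$values, -Inf)
    is_pk <- r$values > v[seq_along(r$values)] & r$values > v[seq_along(r$values) + 2]
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    # representative bin: centre of the plateau
    as.integer(floor((starts[is_pk] + ends[is_pk]) / 2))
  }
  iter <- 0L
  peaks <- count_peaks(h)
  while (length(peaks) != 2L) {
    if (length(peaks) < 2L || iter >= max_iter)
      stop("unimodal image: histogram never reached bimodality")
    # 3-bin mean filter, edges replicated
    h <- (c(h[1], h[-nbins]) + h + c(h[-1], h[nbins])) / 3
    iter <- iter + 1L
    peaks <- count_peaks(h)
  }
  between <- h[peaks[1]:peaks[2]]
  valley <- peaks[1] + which.min(between) - 1L  # first minimum on ties
  thr <- rng[1] + (valley - 0.5) / nbins * diff(rng)
  structure(thr, histogram = h, iterations = iter, peaks = peaks)
}
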