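# Laplacian-of-Gaussian blob detection on calibrated 2D/3D frames.

# shift an array by `by` (one entry per dimension), replicating edges
shift_array <- function(a, by) {
  d <- dim(a)
  idx <- lapply(seq_along(d), function(k) {
    i <- seq_len(d[k]) - by[k]
    pmin(pmax(i, 1L), d[k])
  })
  do.call(`[`, c(list(a), idx))
}

# FFT Gaussian smoothing with zero padding (input should be background
# subtracted so the padding is neutral)
gaussian_smooth <- function(a, sigma_px) {
  sigma_px <- sigma_px[1]
  d <- dim(a)
  w <- ceiling(4 * sigma_px)
  dp <- d + 2L * w
  ap <- array(0, dp)
  idx <- lapply(seq_along(d), function(k) seq_len(d[k]) + w)
  ap <- do.call(`[<-`, c(list(ap), idx, list(a)))
  # separable kernel, wrapped around the origin of the padded grid
  kern1 <- function(n) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    g <- exp(-x^2 / (2 * sigma_px^2))
    g / sum(g)
  }
  kf <- lapply(dp, kern1)
  K <- Reduce(function(u, v) outer(u, v), kf)
  dim(K) <- dp
  out <- Re(fft(fft(ap) * fft(K), inverse = TRUE)) / prod(dp)
  do.call(`[`, c(list(out), idx))
}

#' Detect nuclear spots in one calibrated frame volume
#'
#' Scale-normalized Laplacian-of-Gaussian response at scale `sigma_um`;
#' strict local maxima (8 neighbours in 2D, 26 in 3D) above `quality_min`
#' are kept and refined to sub-pixel position by the centre of mass of
#' the response in a 3x3(x3) neighbourhood.
#'
#' @param vol numeric matrix (2D) or 3D array `[y, x, z]`.
#' @param pixel_size_um micrometres per pixel.
#' @param sigma_um blob scale; must be at least one pixel.
#' @param quality_min minimum LoG response retained.
#' @param origin_px 0-based pixel coordinates `(y, x[, z])` of the
#'   physical origin; defaults to the volume corner.
#' @return data.frame with `x_um`, `y_um`, `z_um` (0 for 2D input) and
#'   `quality`.
#' @export
detect_spots <- function(vol, pixel_size_um, sigma_um, quality_min = 0,
                         origin_px = NULL) {
  sigma_px <- sigma_um / pixel_size_um
  if (sigma_px < 1) stop("sigma_um below one pixel: undetectable scale")
  is2d <- is.matrix(vol)
  a <- if (is2d) array(vol, c(dim(vol), 1L)) else vol
  nd <- if (is2d) 2L else 3L
  a <- a - median(a)
  sm <- if (is2d) {
    m <- gaussian_smooth(a[, , 1], rep(sigma_px, 2))
    array(m, dim(a))
  } else gaussian_smooth(a, rep(sigma_px, 3))
  # discrete Laplacian over the spatial dimensions
  lap <- array(0, dim(a))
  for (k in seq_len(nd)) {
    by <- integer(3)
    by[k] <- 1L
    lap <- lap + shift_array(sm, by) + shift_array(sm, -by) - 2 * sm
  }
  resp <- -sigma_px^2 * lap
  # strict local maxima over all 3^nd - 1 neighbours
  neigh <- expand.grid(dy = -1:1, dx = -1:1, dz = if (is2d) 0 else -1:1)
  neigh <- neigh[rowSums(neigh != 0) > 0, , drop = FALSE]
  ismax <- array(TRUE, dim(resp))
  for (r in seq_len(nrow(neigh)))
    ismax <- ismax & resp > shift_array(resp, as.integer(neigh[r, ]))
  # exclude the border voxels where shifts replicate
  d <- dim(resp)
  brd <- array(FALSE, d)
  brd[c(1, d[1]), , ] <- TRUE
  brd[, c(1, d[2]), ] <- TRUE
  if (!is2d) brd[, , c(1, d[3])] <- TRUE
  ismax[brd] <- FALSE
  idx <- which(ismax & resp > quality_min, arr.ind = TRUE)
  if (is.null(origin_px)) origin_px <- rep(0, 3)
  if (length(origin_px) == 2L) origin_px <- c(origin_px, 0)
  if (!nrow(idx))
    return(data.frame(x_um = numeric(), y_um = numeric(), z_um = numeric(),
                      quality = numeric()))
  out <- lapply(seq_len(nrow(idx)), function(r) {
    p <- idx[r, ]
    rng <- lapply(1:3, function(k) max(1, p[k] - 1):min(d[k], p[k] + 1))
    nb <- do.call(`[`, c(list(resp), rng))
    w <- nb - min(nb)
    tw <- sum(w)
    com <- vapply(1:3, function(k) {
      g <- slice.index(array(0, dim(nb)), k)
      sum(w * (rng[[k]][g])) / max(tw, .Machine$double.eps)
    }, numeric(1))
    if (tw == 0) com <- p
    data.frame(x_um = (com[2] - 1 - origin_px[2]) * pixel_size_um,
               y_um = (com[1] - 1 - origin_px[1]) * pixel_size_um,
               z_um = if (is2d) 0 else (com[3] - 1 - origin_px[3]) * pixel_size_um,
               quality = resp[p[1], p[2], p[3]])
  })
  do.call(rbind, out)
}

#' Detect spots in every frame of an image stack
#'
#' @param stack an [image_stack()].
#' @param sigma_um blob scale in micrometres.
#' @param quality_min minimum LoG response.
#' @return detection table with `frame` (0-based), `t_h`, `x_um`, `y_um`,
#'   `z_um`, `quality`; coordinates are relative to the stack's physical
#'   origin.
#' @export
detect_spots_stack <- function(stack, sigma_um, quality_min = 0) {
  stopifnot(inherits(stack, "image_stack"))
  ps <- attr(stack, "pixel_size_um")
  dtm <- attr(stack, "frame_interval_min")
  org <- attr(stack, "origin_px")
  out <- lapply(seq_along(stack$frames), function(i) {
    det <- detect_spots(stack$frames[[i]], ps, sigma_um, quality_min, org)
    if (!nrow(det)) return(NULL)
    cbind(frame = i - 1L, t_h = (i - 1) * dtm / 60, det)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(frame = integer(), t_h = numeric(), x_um = numeric(),
                      y_um = numeric(), z_um = numeric(), quality = numeric())
  out
}
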