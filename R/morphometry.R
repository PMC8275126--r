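# Connected-component labelling, hole filling and sub-pixel contour
# measurement on binary masks, plus the organoid morphometry built on them.

#' Label connected components of a binary mask
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default, diagonal neighbours connect) or 4.
#' @return integer matrix, 0 = background, components labelled 1..k in
#'   scan order.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  ny <- nrow(mask); nx <- ncol(mask)
  np <- ny + 2L
  mp <- matrix(FALSE, np, nx + 2L)
  mp[2:(ny + 1L), 2:(nx + 1L)] <- mask
  lab <- matrix(0L, np, nx + 2L)
  offs <- c(-1L, 1L, -np, np)
  if (connectivity == 8L) offs <- c(offs, -np - 1L, -np + 1L, np - 1L, np + 1L)
  seeds <- which(mp)
  k <- 0L
  for (s in seeds) {
    if (lab[s] != 0L) next
    k <- k + 1L
    frontier <- s
    lab[s] <- k
    while (length(frontier)) {
      nb <- rep(frontier, each = length(offs)) + offs
      nb <- nb[mp[nb] & lab[nb] == 0L]
      if (!length(nb)) break
      nb <- unique(nb)
      lab[nb] <- k
      frontier <- nb
    }
  }
  lab[2:(ny + 1L), 2:(nx + 1L), drop = FALSE]
}

#' Fill interior holes of a binary mask
#'
#' Background regions not connected (4-connectivity) to the image border
#' are considered holes and set to foreground.
#'
#' @param mask logical matrix.
#' @return logical matrix.
#' @export
fill_holes <- function(mask) {
  bg <- label_components(!mask, connectivity = 4L)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0L]
  mask | (bg > 0L & !(bg %in% border))
}

# sub-pixel contour length of a binary mask (in pixels): the mask is
# lightly smoothed (3x3 mean) so that the 0.5-level marching-squares
# contour interpolates the boundary at sub-pixel positions, then all
# iso-segment lengths are summed. Holes should be filled beforehand if
# only the outer contour is wanted.
contour_length_px <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  f <- matrix(0, ny + 4L, nx + 4L)
  f[3:(ny + 2L), 3:(nx + 2L)] <- as.numeric(mask)
  # 3x3 mean filter
  sh <- function(m, dy, dx) {
    out <- matrix(0, nrow(m), ncol(m))
    ys <- max(1, 1 + dy):min(nrow(m), nrow(m) + dy)
    xs <- max(1, 1 + dx):min(ncol(m), ncol(m) + dx)
    out[ys, xs] <- m[ys - dy, xs - dx]
    out
  }
  g <- Reduce(`+`, lapply(c(-1, 0, 1), function(dy)
    Reduce(`+`, lapply(c(-1, 0, 1), function(dx) sh(f, dy, dx))))) / 9
  marching_squares_length(g, level = 0.5)
}

# total length of the iso-contour of field f at `level` by marching
# squares with linear interpolation; saddle cells resolved by the cell
# centre's mean value.
marching_squares_length <- function(f, level = 0.5) {
  ny <- nrow(f); nx <- ncol(f)
  i <- rep(seq_len(ny - 1L), nx - 1L)          # cell top row
  j <- rep(seq_len(nx - 1L), each = ny - 1L)   # cell left column
  a <- f[cbind(i, j)]; b <- f[cbind(i, j + 1L)]
  c_ <- f[cbind(i + 1L, j + 1L)]; d <- f[cbind(i + 1L, j)]
  code <- (a > level) + 2L * (b > level) + 4L * (c_ > level) + 8L * (d > level)
  active <- code != 0L & code != 15L
  if (!any(active)) return(0)
  i <- i[active]; j <- j[active]
  a <- a[active]; b <- b[active]; c_ <- c_[active]; d <- d[active]
  code <- code[active]
  itp <- function(v1, v2) (level - v1) / (v2 - v1)
  # edge crossing coordinates (x = column, y = row, continuous)
  tx <- j + itp(a, b);      ty <- rep(0, length(a)) + i   # top edge
  rx <- j + 1;              ry <- i + itp(b, c_)          # right edge
  bx <- j + itp(d, c_);     by <- i + 1                   # bottom edge
  lx <- j + 0;              ly <- i + itp(a, d)           # left edge
  seg <- function(sel, x1, y1, x2, y2)
    sum(sqrt((x1[sel] - x2[sel])^2 + (y1[sel] - y2[sel])^2))
  total <- 0
  total <- total + seg(code %in% c(1L, 14L), tx, ty, lx, ly)   # top-left corner
  total <- total + seg(code %in% c(2L, 13L), tx, ty, rx, ry)   # top-right corner
  total <- total + seg(code %in% c(4L, 11L), rx, ry, bx, by)   # bottom-right
  total <- total + seg(code %in% c(8L, 7L), bx, by, lx, ly)    # bottom-left
  total <- total + seg(code %in% c(3L, 12L), lx, ly, rx, ry)   # horizontal pass
  total <- total + seg(code %in% c(6L, 9L), tx, ty, bx, by)    # vertical pass
  # saddles: disambiguate by the cell-centre mean
  for (cd in c(5L, 10L)) {
    sel <- which(code == cd)
    if (!length(sel)) next
    centre_above <- (a[sel] + b[sel] + c_[sel] + d[sel]) / 4 > level
    join_tr <- if (cd == 5L) centre_above else !centre_above
    s1 <- sel[join_tr]    # top-right + bottom-left pairing
    s2 <- sel[!join_tr]   # top-left + bottom-right pairing
    total <- total +
      seg(s1, tx, ty, rx, ry) + seg(s1, bx, by, lx, ly) +
      seg(s2, tx, ty, lx, ly) + seg(s2, rx, ry, bx, by)
  }
  total
}

#' Segment the organoid in a bright-field frame
#'
#' Thresholds the frame with [minimum_threshold()], keeps the largest
#' connected component on the dark side (organoids image dark on a bright
#' background), fills interior holes and reports the calibrated area.
#'
#' @param bf bright-field [image_frame()].
#' @param dark_object set `FALSE` if the object is brighter than the
#'   background.
#' @return list with `mask` (logical matrix), `area_um2`, `threshold`.
#' @export
organoid_mask <- function(bf, dark_object = TRUE) {
  ps <- pixel_size(bf)
  thr <- as.numeric(minimum_threshold(bf))
  mask <- if (dark_object) unclass(bf) <= thr else unclass(bf) > thr
  if (!any(mask)) stop("empty foreground after thresholding")
  lab <- label_components(mask, 8L)
  sizes <- tabulate(lab[lab > 0L])
  mask <- lab == which.max(sizes)
  mask <- fill_holes(mask)
  list(mask = mask, area_um2 = sum(mask) * ps^2, threshold = thr)
}

#' Expression-area fraction within the organoid
#'
#' The fluorescence frame is thresholded with [minimum_threshold()]
#' computed from the pixels inside the organoid mask (falling back to the
#' whole frame, and finally to a mean comparison, when a histogram is
#' unimodal or separates two phases by less than four standard
#' deviations: an organoid either fully covered or fully devoid of
#' expression has no meaningful bimodal in-mask histogram). The fraction
#' is `100 * expression pixels / organoid pixels`.
#'
#' @param fluor fluorescence [image_frame()].
#' @param mask logical organoid mask of the same shape.
#' @return percentage in `[0, 100]`, with attribute `threshold`.
#' @export
expression_fraction <- function(fluor, mask) {
  stopifnot(identical(dim(fluor), dim(mask)))
  if (!any(mask)) stop("empty organoid mask")
  px <- unclass(fluor)
  # a threshold is only meaningful when the two phases it separates are
  # further apart than their spread; pure-noise histograms can drift
  # through a spuriously "bimodal" state during smoothing
  meaningful <- function(thr, values) {
    lo <- values[values <= thr]; hi <- values[values > thr]
    min(length(lo), length(hi)) > max(2, 0.002 * length(values)) &&
      (mean(hi) - mean(lo)) > 4 * max(sd(lo), sd(hi), 1e-12)
  }
  try_thr <- function(values) {
    thr <- tryCatch(as.numeric(minimum_threshold(values)),
                    error = function(e) NULL)
    if (!is.null(thr) && meaningful(thr, values)) thr else NULL
  }
  thr <- try_thr(px[mask])
  if (is.null(thr)) thr <- try_thr(px)
  if (is.null(thr)) {
    # everywhere-unimodal image: all-or-nothing call by mean comparison
    m_in <- mean(px[mask]); m_out <- mean(px[!mask]); s <- sd(px[!mask])
    frac <- if (is.finite(m_out) && m_in > m_out + 3 * max(s, 1e-12)) 100 else 0
    return(structure(frac, threshold = NA_real_))
  }
  frac <- 100 * sum(px > thr & mask) / sum(mask)
  structure(frac, threshold = thr)
}

#' Count expression domains in a binary mask
#'
#' 8-connected components of the expression mask; components smaller than
#' `min_area_um2` are discarded as specks. Per-region area, sub-pixel
#' outer-contour perimeter and centroid are reported.
#'
#' @param mask logical expression mask.
#' @param pixel_size_um micrometres per pixel.
#' @param min_area_um2 minimum region area retained.
#' @return object of class `region_set`: `label_image` (labels dense
#'   1..k), `regions` data.frame (`label`, `area_um2`, `perimeter_um`,
#'   `centroid_x_px`, `centroid_y_px`), `pixel_size_um`.
#' @export
count_domains <- function(mask, pixel_size_um, min_area_um2 = 100) {
  stopifnot(is.matrix(mask))
  lab <- label_components(mask, 8L)
  k <- max(lab)
  keep <- which(tabulate(lab[lab > 0L], k) * pixel_size_um^2 >= min_area_um2)
  out <- matrix(0L, nrow(lab), ncol(lab))
  regions <- list()
  for (newlab in seq_along(keep)) {
    sel <- lab == keep[newlab]
    out[sel] <- newlab
    idx <- which(sel, arr.ind = TRUE)
    regions[[newlab]] <- data.frame(
      label = newlab,
      area_um2 = nrow(idx) * pixel_size_um^2,
      perimeter_um = contour_length_px(fill_holes(sel)) * pixel_size_um,
      centroid_x_px = mean(idx[, 2]) - 1,
      centroid_y_px = mean(idx[, 1]) - 1
    )
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(label = integer(), area_um2 = numeric(), perimeter_um = numeric(),
               centroid_x_px = numeric(), centroid_y_px = numeric())
  structure(list(label_image = out, regions = regions,
                 pixel_size_um = pixel_size_um),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("<region_set>", nrow(x$regions), "region(s)\n")
  if (nrow(x$regions)) print(x$regions)
  invisible(x)
}

#' Largest circumference among regions
#'
#' The maximum outer-contour perimeter over all regions: the "size,
#' measured as largest circumference" statistic used for optic-vesicle
#' cross-sections.
#'
#' @param regions a [count_domains()] result.
#' @return micrometres.
#' @export
largest_circumference <- function(regions) {
  stopifnot(inherits(regions, "region_set"))
  if (!nrow(regions$regions)) stop("no regions to measure")
  max(regions$regions$perimeter_um)
}
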