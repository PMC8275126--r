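#' Construct a calibrated 2D image frame
#'
#' @param pixels numeric matrix of grey levels (rows = y, columns = x).
#' @param pixel_size_um physical pixel size, micrometres per pixel.
#' @param channel `"bright_field"` or `"fluorescence"`.
#' @return object of class `image_frame` (a matrix with attributes).
#' @export
image_frame <- function(pixels, pixel_size_um, channel = c("bright_field", "fluorescence")) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels) || !length(pixels)) stop("pixels must be a non-empty matrix")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be strictly positive")
  structure(pixels, pixel_size_um = pixel_size_um, channel = channel,
            class = c("image_frame", "matrix", "array"))
}

#' @export
print.image_frame <- function(x, ...) {
  cat("<image_frame>", attr(x, "channel"), paste(dim(x), collapse = "x"), "px,",
      attr(x, "pixel_size_um"), "um/px\n")
  invisible(x)
}

pixel_size <- function(img) {
  ps <- attr(img, "pixel_size_um")
  if (is.null(ps)) stop("image has no pixel_size_um calibration")
  ps
}

# squared distance (um^2) of every pixel centre to a point (px coordinates,
# 0-based, pixel centre at integer coordinates)
pixel_dist2 <- function(size_px, cx_px, cy_px, pixel_size_um) {
  xs <- (seq_len(size_px) - 1 - cx_px) * pixel_size_um
  ys <- (seq_len(size_px) - 1 - cy_px) * pixel_size_um
  outer(ys^2, xs^2, `+`)
}

#' Simulate a day-2 organoid image pair with retinal expression domains
#'
#' Produces a bright-field frame (dark organoid disk on a bright
#' background) and a fluorescence frame with `n_domains` bright circular
#' expression domains placed inside the organoid by rejection sampling so
#' that domain edges keep a pairwise gap of at least `min_domain_gap_um`.
#' Ground truth carries the label image (labels dense from 1, in placement
#' order) and each domain's analytic area and perimeter.
#'
#' @param cfg a [sim_config()]; the `image` block is used.
#' @param max_attempts rejection-sampling cap for domain placement.
#' @return list with `bright_field`, `fluorescence` (both [image_frame()])
#'   and `truth` (label image, per-domain table, organoid geometry).
#' @export
simulate_organoid_image <- function(cfg, max_attempts = 10000L) {
  validate_sim_config(cfg)
  im <- cfg$image
  set.seed(cfg$seed)
  n <- im$size_px
  ps <- im$pixel_size_um
  centre <- (n - 1) / 2   # px
  R <- im$organoid_radius_um
  r <- im$domain_radius_um
  if (R + 2 * ps > (n - 1) / 2 * ps)
    stop("organoid does not fit in the field of view")
  if (r > R) stop("domain_radius_um exceeds organoid_radius_um")

  # place domain centres: uniform in the disk of radius R - r, pairwise
  # centre distance >= 2 r + gap
  placed <- matrix(numeric(0), ncol = 2)
  attempts <- 0L
  while (nrow(placed) < im$n_domains) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not place ", im$n_domains, " domains with gap ",
           im$min_domain_gap_um, " um after ", max_attempts, " attempts")
    rad <- (R - r) * sqrt(runif(1))
    ang <- runif(1, 0, 2 * pi)
    cand <- c(rad * cos(ang), rad * sin(ang))
    ok <- !nrow(placed) ||
      all(sqrt(colSums((t(placed) - cand)^2)) >= 2 * r + im$min_domain_gap_um)
    if (ok) placed <- rbind(placed, cand)
  }

  d2_org <- pixel_dist2(n, centre, centre, ps)
  inside_org <- d2_org <= R^2
  bf <- matrix(im$fg_intensity, n, n)
  bf[inside_org] <- im$bg_intensity
  fl <- matrix(im$bg_intensity, n, n)
  label <- matrix(0L, n, n)
  for (i in seq_len(nrow(placed))) {
    cx <- centre + placed[i, 1] / ps
    cy <- centre + placed[i, 2] / ps
    inside <- pixel_dist2(n, cx, cy, ps) <= r^2
    fl[inside] <- im$fg_intensity
    label[inside] <- i
  }
  if (im$noise_sd > 0) {
    bf <- bf + matrix(rnorm(n * n, 0, im$noise_sd), n, n)
    fl <- fl + matrix(rnorm(n * n, 0, im$noise_sd), n, n)
  }
  domains <- data.frame(
    label = seq_len(nrow(placed)),
    cx_px = centre + placed[, 1] / ps,
    cy_px = centre + placed[, 2] / ps,
    radius_um = r,
    area_um2 = pi * r^2,
    perimeter_um = 2 * pi * r
  )
  list(
    bright_field = image_frame(bf, ps, "bright_field"),
    fluorescence = image_frame(fl, ps, "fluorescence"),
    truth = list(
      label_image = label,
      domains = domains,
      organoid = list(center_px = c(centre, centre), radius_um = R,
                      area_um2 = pi * R^2)
    )
  )
}
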