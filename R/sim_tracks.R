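#' Simulate 3D nuclear tracks switching from diffusion to radial migration
#'
#' Cells start uniformly distributed in a sphere of radius
#' `aggregate_radius_um` centred at the origin. While `t < t_switch_h`
#' each cell performs isotropic Brownian motion (per-axis step variance
#' `2 * D * dt`); from `t >= t_switch_h` it moves radially at constant
#' speed `v_um_per_min`, outward with probability `p_outward` (the sign is
#' drawn once per cell and recorded as its class). Inward-moving cells
#' stop just short of the centre rather than tunnelling through it, so a
#' track's net radial displacement sign always matches its class when
#' localization noise is zero. Observed positions are the true positions
#' plus isotropic Gaussian localization noise; observations are dropped
#' independently with probability `miss_rate`.
#'
#' @param cfg a [sim_config()]; the `tracks` block is used.
#' @return list with `tracks` (an [as_ov_tracks()] list) and `truth`
#'   (per-cell class table, switch time/frame, generative parameters).
#' @export
simulate_tracks <- function(cfg) {
  validate_sim_config(cfg)
  tr <- cfg$tracks
  if (tr$t_switch_h >= tr$duration_h)
    stop("t_switch_h must be smaller than duration_h")
  set.seed(cfg$seed)
  n <- tr$n_cells
  dt_h <- tr$dt_min / 60
  times <- seq(0, tr$duration_h, by = dt_h)
  T_ <- length(times)

  # uniform in sphere: direction from normalized Gaussians, radius ~ R u^(1/3)
  dir0 <- matrix(rnorm(3 * n), n, 3)
  dir0 <- dir0 / sqrt(rowSums(dir0^2))
  pos <- dir0 * tr$aggregate_radius_um * runif(n)^(1 / 3)
  r0 <- sqrt(rowSums(pos^2))

  sign_out <- ifelse(runif(n) < tr$p_outward, 1, -1)
  step_len <- tr$v_um_per_min * tr$dt_min
  sd_brown <- sqrt(2 * tr$D_um2_per_min * tr$dt_min)

  X <- array(NA_real_, c(n, T_, 3))
  X[, 1, ] <- pos
  for (i in seq_len(T_ - 1)) {
    if (times[i] < tr$t_switch_h) {
      pos <- pos + matrix(rnorm(3 * n, 0, sd_brown), n, 3)
    } else {
      rad <- sqrt(rowSums(pos^2))
      rad <- pmax(rad, 1e-9)
      new_rad <- pmax(rad + sign_out * step_len, 0.5)  # inward cells halt at centre
      pos <- pos * (new_rad / rad)
    }
    X[, i + 1, ] <- pos
  }

  obs <- X
  if (tr$loc_noise_um > 0)
    obs <- obs + array(rnorm(length(X), 0, tr$loc_noise_um), dim(X))
  keep <- matrix(runif(n * T_) >= tr$miss_rate, n, T_)

  tracks <- lapply(seq_len(n), function(j) {
    k <- which(keep[j, ])
    data.frame(frame = k - 1L, t_h = times[k],
               x_um = obs[j, k, 1], y_um = obs[j, k, 2], z_um = obs[j, k, 3])
  })
  names(tracks) <- sprintf("cell_%04d", seq_len(n))
  switch_frame <- which(times >= tr$t_switch_h)[1] - 1L  # 0-based
  list(
    tracks = as_ov_tracks(tracks, tr$dt_min),
    truth = list(
      cells = data.frame(id = names(tracks),
                         class = ifelse(sign_out > 0, "outward", "inward"),
                         r0_um = r0),
      switch_time_h = tr$t_switch_h,
      switch_frame = switch_frame,
      v_um_per_min = tr$v_um_per_min,
      D_um2_per_min = tr$D_um2_per_min
    )
  )
}

#' Construct a calibrated image stack
#'
#' @param frames list of matrices (2D time lapse) or 3D arrays (volumes),
#'   all of identical dimensions.
#' @param pixel_size_um micrometres per pixel.
#' @param frame_interval_min minutes between frames.
#' @param origin_px physical-origin position in 0-based pixel coordinates
#'   (defaults to the stack centre).
#' @return object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size_um, frame_interval_min, origin_px = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  d <- dim(frames[[1]])
  for (f in frames) stopifnot(identical(dim(f), d))
  if (is.null(origin_px)) origin_px <- (d - 1) / 2
  structure(list(frames = frames),
            pixel_size_um = pixel_size_um,
            frame_interval_min = frame_interval_min,
            origin_px = origin_px,
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat("<image_stack>", length(x$frames), "frames of",
      paste(dim(x$frames[[1]]), collapse = "x"), "px,",
      attr(x, "pixel_size_um"), "um/px,",
      attr(x, "frame_interval_min"), "min/frame\n")
  invisible(x)
}

#' Render tracks as a synthetic nuclear-reporter movie
#'
#' Every observation becomes an isotropic 3D Gaussian spot of standard
#' deviation `spot_sigma_um` and amplitude `fg_intensity` on a constant
#' background with additive Gaussian noise (both from the image block).
#' The physical origin (aggregate centre) maps to the stack centre.
#'
#' @param tracks an `ov_tracks` object (3D positions in um).
#' @param cfg a [sim_config()]; image block supplies size, calibration,
#'   intensities and noise.
#' @param spot_sigma_um Gaussian spot sigma in micrometres; must be at
#'   least one pixel.
#' @param n_z number of z planes (defaults to `size_px`).
#' @param n_frames number of frames to render (defaults to covering all
#'   observations; required if `tracks` is empty).
#' @return an [image_stack()] of 3D arrays indexed `[y, x, z]`.
#' @export
render_track_movie <- function(tracks, cfg, spot_sigma_um = 2 * cfg$image$pixel_size_um,
                               n_z = cfg$image$size_px, n_frames = NULL) {
  validate_sim_config(cfg)
  im <- cfg$image
  ps <- im$pixel_size_um
  sigma_px <- spot_sigma_um / ps
  if (sigma_px < 1) stop("spot sigma below 1 px is undetectable; increase spot_sigma_um")
  nx <- im$size_px; ny <- im$size_px; nz <- n_z
  origin <- c((ny - 1) / 2, (nx - 1) / 2, (nz - 1) / 2)  # y, x, z
  det <- if (length(tracks)) as_detections(tracks) else NULL
  if (is.null(n_frames)) {
    if (is.null(det)) stop("n_frames is required for an empty track list")
    n_frames <- max(det$frame) + 1L
  }
  set.seed(cfg$seed)
  half <- ceiling(4 * sigma_px)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames) - 1L) {
    vol <- array(im$bg_intensity, c(ny, nx, nz))
    if (im$noise_sd > 0)
      vol <- vol + array(rnorm(length(vol), 0, im$noise_sd), dim(vol))
    if (!is.null(det)) {
      d <- det[det$frame == f, , drop = FALSE]
      for (j in seq_len(nrow(d))) {
        # physical um -> 0-based px
        cy <- d$y_um[j] / ps + origin[1]
        cx <- d$x_um[j] / ps + origin[2]
        cz <- d$z_um[j] / ps + origin[3]
        if (cy < 0 || cy > ny - 1 || cx < 0 || cx > nx - 1 || cz < 0 || cz > nz - 1)
          stop("track observation outside the rendered field of view")
        iy <- max(0, floor(cy) - half):min(ny - 1, ceiling(cy) + half)
        ix <- max(0, floor(cx) - half):min(nx - 1, ceiling(cx) + half)
        iz <- max(0, floor(cz) - half):min(nz - 1, ceiling(cz) + half)
        gy <- exp(-((iy - cy)^2) / (2 * sigma_px^2))
        gx <- exp(-((ix - cx)^2) / (2 * sigma_px^2))
        gz <- exp(-((iz - cz)^2) / (2 * sigma_px^2))
        spot <- im$fg_intensity * outer(outer(gy, gx), gz)
        vol[iy + 1, ix + 1, iz + 1] <- vol[iy + 1, ix + 1, iz + 1] + spot
      }
    }
    frames[[f + 1L]] <- vol
  }
  image_stack(frames, ps, attr(tracks, "dt_min") %||% NA_real_, origin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
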