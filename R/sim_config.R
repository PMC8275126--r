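#' Simulation configuration for synthetic organoid experiments
#'
#' A `sim_config` bundles every generative parameter of one synthetic
#' experiment: the onset cohort block, the organoid image block and the
#' 3D track block, plus the random seed. Identical configurations
#' (including the seed) produce bit-identical output from every
#' `simulate_*` function.
#'
#' Defaults describe the experiments the package emulates: medaka
#' organoid onset cohorts imaged every 30 min over 20 h, day-2 organoid
#' images with 1-4 fluorescent retinal domains, and 4600 nuclear tracks
#' in a 150 um aggregate sampled every 15 min that switch from Brownian
#' diffusion to radial migration at 0.45 um/min, 51% of cells outward.
#'
#' @param seed integer random seed.
#' @param cohort named list overriding cohort defaults:
#'   `n_traces`, `onset_mean_h`, `onset_sd_h`, `frame_interval_min`,
#'   `duration_h`, `rise_time_h` (10-90% rise of the logistic),
#'   `noise_sd` (fraction of plateau), `baseline` (fraction of plateau).
#' @param image named list overriding image defaults:
#'   `size_px`, `pixel_size_um`, `organoid_radius_um`, `n_domains` (1-4),
#'   `domain_radius_um`, `fg_intensity`, `bg_intensity`, `noise_sd` (grey
#'   levels), `min_domain_gap_um`.
#' @param tracks named list overriding track defaults:
#'   `n_cells`, `aggregate_radius_um`, `D_um2_per_min`, `v_um_per_min`,
#'   `p_outward`, `t_switch_h`, `duration_h`, `dt_min`, `loc_noise_um`,
#'   `miss_rate`.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, cohort = list(), image = list(), tracks = list()) {
  defaults <- list(
    seed = as.integer(seed),
    cohort = list(
      n_traces = 17L, onset_mean_h = 15.5, onset_sd_h = 0.36,
      frame_interval_min = 30, duration_h = 22, rise_time_h = 2,
      noise_sd = 0.02, baseline = 0.05
    ),
    image = list(
      size_px = 256L, pixel_size_um = 2, organoid_radius_um = 150,
      n_domains = 1L, domain_radius_um = 26, fg_intensity = 200,
      bg_intensity = 40, noise_sd = 4, min_domain_gap_um = 10
    ),
    tracks = list(
      n_cells = 4600L, aggregate_radius_um = 150, D_um2_per_min = 0.5,
      v_um_per_min = 0.45, p_outward = 0.51, t_switch_h = 10,
      duration_h = 16, dt_min = 15, loc_noise_um = 0.5, miss_rate = 0
    )
  )
  cfg <- defaults
  for (block in c("cohort", "image", "tracks")) {
    override <- get(block)
    if (length(override)) {
      unknown <- setdiff(names(override), names(defaults[[block]]))
      if (length(unknown))
        stop("unknown ", block, " parameter(s): ", paste(unknown, collapse = ", "))
      cfg[[block]] <- modifyList(cfg[[block]], override)
    }
  }
  cfg <- structure(cfg, class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.finite(cfg$seed)) stop("seed must be a finite integer")
  co <- cfg$cohort
  pos <- function(block, keys) {
    for (k in keys) {
      v <- block[[k]]
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
        stop("parameter '", k, "' must be a single strictly positive number")
    }
  }
  nonneg <- function(block, keys) {
    for (k in keys) {
      v <- block[[k]]
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
        stop("parameter '", k, "' must be a single non-negative number")
    }
  }
  prob <- function(block, keys) {
    for (k in keys) {
      v <- block[[k]]
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
        stop("parameter '", k, "' must lie in [0, 1]")
    }
  }
  pos(co, c("n_traces", "onset_mean_h", "frame_interval_min", "duration_h", "rise_time_h"))
  nonneg(co, c("onset_sd_h", "noise_sd"))
  prob(co, "baseline")
  im <- cfg$image
  pos(im, c("size_px", "pixel_size_um", "organoid_radius_um", "domain_radius_um",
            "fg_intensity"))
  nonneg(im, c("bg_intensity", "noise_sd", "min_domain_gap_um"))
  if (!im$n_domains %in% 1:4) stop("parameter 'n_domains' must be in {1, 2, 3, 4}")
  tr <- cfg$tracks
  pos(tr, c("n_cells", "aggregate_radius_um", "duration_h", "dt_min"))
  nonneg(tr, c("D_um2_per_min", "v_um_per_min", "t_switch_h", "loc_noise_um"))
  prob(tr, c("p_outward", "miss_rate"))
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed =", x$seed, "\n")
  for (block in c("cohort", "image", "tracks")) {
    vals <- unlist(x[[block]])
    cat("  ", block, ": ", paste(names(vals), vals, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Named presets mirroring the emulated acquisitions
#'
#' `"medaka-onset"` / `"zebrafish-onset"`: onset cohorts on a 30-min frame
#' grid (organoid means 15.5 h / 9.75 h; the matching embryo reference
#' cohorts are reachable through the `cohort` override).
#' `"fig4-morphometry"`: day-2 organoid image with fluorescent retinal
#' domains sized like embryonic optic vesicles.
#' `"fig5-migration"`: 4600 tracks, 15-min frames, 16 h of imaging starting
#' at 24 hpa with the diffusive-to-directed switch 10 h in (34 hpa).
#'
#' @param name preset name.
#' @param seed integer seed.
#' @return a [sim_config()].
#' @export
preset_config <- function(name, seed = 1L) {
  switch(name,
    "medaka-onset" = sim_config(seed, cohort = list(
      n_traces = 17L, onset_mean_h = 15.5, onset_sd_h = 0.36,
      frame_interval_min = 30, duration_h = 22)),
    "medaka-embryo-onset" = sim_config(seed, cohort = list(
      n_traces = 6L, onset_mean_h = 13.5, onset_sd_h = 1.03,
      frame_interval_min = 30, duration_h = 22)),
    "zebrafish-onset" = sim_config(seed, cohort = list(
      n_traces = 15L, onset_mean_h = 9.75, onset_sd_h = 0.21,
      frame_interval_min = 30, duration_h = 18)),
    "zebrafish-embryo-onset" = sim_config(seed, cohort = list(
      n_traces = 6L, onset_mean_h = 7.88, onset_sd_h = 0.77,
      frame_interval_min = 30, duration_h = 18)),
    "fig4-morphometry" = sim_config(seed, image = list(
      size_px = 256L, pixel_size_um = 2, organoid_radius_um = 150,
      n_domains = 2L, domain_radius_um = 26, min_domain_gap_um = 20)),
    "fig5-migration" = sim_config(seed, tracks = list(
      n_cells = 4600L, aggregate_radius_um = 150, D_um2_per_min = 0.5,
      v_um_per_min = 0.45, p_outward = 0.51, t_switch_h = 10,
      duration_h = 16, dt_min = 15, loc_noise_um = 0.5, miss_rate = 0.02)),
    stop("unknown preset: ", name)
  )
}

#' @rdname preset_config
#' @export
preset_names <- function() {
  c("medaka-onset", "medaka-embryo-onset", "zebrafish-onset",
    "zebrafish-embryo-onset", "fig4-morphometry", "fig5-migration")
}

# hours-post-aggregation offset of the migration movie's first frame:
# the emulated acquisition starts at day 1 (24 hpa).
FIG5_T0_HPA <- 24
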