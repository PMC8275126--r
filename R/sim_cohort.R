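#' Construct an intensity trace
#'
#' One aggregate's fluorescence time course: strictly increasing, uniformly
#' spaced times in hours and the per-frame sum of fluorescence intensity
#' (of the maximum projection, for volumetric data).
#'
#' @param id trace identifier.
#' @param times_h numeric vector of hours, strictly increasing and uniform.
#' @param intensity_raw per-frame summed intensity, arbitrary units.
#' @param intensity_norm optional normalized intensity in `[0, 1]`.
#' @return object of class `intensity_trace`.
#' @export
intensity_trace <- function(id, times_h, intensity_raw, intensity_norm = NULL) {
  times_h <- as.numeric(times_h)
  intensity_raw <- as.numeric(intensity_raw)
  if (length(times_h) < 5L) stop("intensity trace needs at least 5 frames")
  if (length(times_h) != length(intensity_raw))
    stop("times and intensities differ in length")
  dt <- diff(times_h)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  if (diff(range(dt)) > 1e-6) stop("frame spacing must be uniform")
  if (!is.null(intensity_norm)) {
    if (length(intensity_norm) != length(times_h))
      stop("normalized intensity has wrong length")
    if (min(intensity_norm) < -1e-9 || max(intensity_norm) > 1 + 1e-9)
      stop("normalized intensity must lie in [0, 1]")
  }
  structure(
    list(id = as.character(id), times_h = times_h,
         intensity_raw = intensity_raw, intensity_norm = intensity_norm),
    class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat("<intensity_trace>", x$id, ":", length(x$times_h), "frames,",
      sprintf("%.2f-%.2f h", x$times_h[1], x$times_h[length(x$times_h)]),
      if (is.null(x$intensity_norm)) "(raw)" else "(normalized)", "\n")
  invisible(x)
}

# logistic rate constant for a stated 10-90% rise time
logistic_rate <- function(rise_time_h) log(81) / rise_time_h

#' Simulate a cohort of reporter-onset intensity traces
#'
#' Each trace is `baseline + (1 - baseline) * plogis(k * (t - onset))` with
#' the 10-90% rise time `rise_time_h` fixing `k`, plus i.i.d. Gaussian noise
#' (`noise_sd`, in units of the plateau). Per-trace onsets are drawn from
#' `Normal(onset_mean_h, onset_sd_h)`; the noiseless curve's steepest point
#' (its inflection) sits exactly at the drawn onset, which is what
#' [detect_onset()] estimates.
#'
#' @param cfg a [sim_config()]; the `cohort` block is used.
#' @return list with `traces` (list of [intensity_trace()]) and `truth`
#'   (list with `true_onsets_h`).
#' @export
simulate_intensity_cohort <- function(cfg) {
  validate_sim_config(cfg)
  co <- cfg$cohort
  if (co$duration_h < co$onset_mean_h + 3 * co$rise_time_h)
    stop("duration_h too short: onset near ", co$onset_mean_h,
         " h would be censored (need >= onset_mean_h + 3 * rise_time_h)")
  set.seed(cfg$seed)
  times <- seq(0, co$duration_h, by = co$frame_interval_min / 60)
  k <- logistic_rate(co$rise_time_h)
  onsets <- rnorm(co$n_traces, co$onset_mean_h, co$onset_sd_h)
  traces <- lapply(seq_len(co$n_traces), function(i) {
    clean <- co$baseline + (1 - co$baseline) / (1 + exp(-k * (times - onsets[i])))
    raw <- clean + rnorm(length(times), 0, co$noise_sd)
    intensity_trace(sprintf("trace_%02d", i), times, raw)
  })
  list(traces = traces, truth = list(true_onsets_h = onsets))
}
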