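# Run configuration: YAML/JSON files with per-stage parameter blocks.
# Unknown keys are rejected so typos cannot silently fall back to
# defaults; every defaulted value is echoed into the report.

run_config_defaults <- function() {
  list(
    seed = 1L,
    preset = NULL,
    out_dir = ".",
    simulate = list(kind = NULL, cohort = list(), image = list(), tracks = list()),
    onset = list(smooth_window = 3L),
    quantify = list(min_area_um2 = 100, dark_object = TRUE, pixel_size_um = NULL),
    track = list(max_disp_um = NULL),
    motility = list(max_lag_fraction = 0.25, dim = 3, share_lo = 0.25,
                    share_hi = 0.75),
    direction = list(deadband_um = 2, n_bins = 18L, smooth_frames = 5L,
                     constant_center = FALSE)
  )
}

merge_checked <- function(defaults, override, where = "config") {
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    stop("unknown ", where, " key(s): ", paste(unknown, collapse = ", "))
  for (k in names(override)) {
    if (is.list(defaults[[k]]) && is.list(override[[k]]) &&
        k %in% c("simulate", "onset", "quantify", "track", "motility", "direction")) {
      defaults[[k]] <- merge_checked(defaults[[k]], override[[k]], paste0(where, "$", k))
    } else defaults[[k]] <- override[[k]]
  }
  defaults
}

#' Read and validate a run configuration (YAML or JSON)
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return full configuration list with defaults filled in; unknown keys
#'   raise an error naming the key.
#' @export
read_run_config <- function(path) {
  raw_cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else stop("config must be .yaml/.yml or .json")
  if (is.null(raw_cfg)) raw_cfg <- list()
  merge_checked(run_config_defaults(), raw_cfg)
}

write_config_echo <- function(cfg, path) {
  cfg$config_hash <- config_hash(cfg)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
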