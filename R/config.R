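#' Pipeline configuration
#'
#' All tunable thresholds of the detection pipeline in one list, with the
#' published defaults: 50 lx daylight rule, 20 s bout/gap pruning, 5 min
#' efficiency stabilisation window, civil-twilight night flag at -6 deg sun
#' elevation, 0.2 Hz / 2 Hz median-filter cut-offs, 30 min edge trim, 65 g
#' feathered-chick mass threshold.
#'
#' @param ... Named overrides of individual defaults; unknown names error.
#'
#' @return A named list of class `brood_config`.
#' @export
#'
#' @examples
#' cfg <- brood_config(lx_thresh = 40)
#' cfg$lx_thresh
brood_config <- function(...) {
  cfg <- list(
    # preprocessing
    fs_accel       = 25,     # Hz, accelerometer sampling rate
    fs_slow        = 1,      # Hz, temperature / light sampling rate
    fc_highpass    = 0.2,    # Hz, gravity-removal median filter cut-off
    fc_lowpass     = 2,      # Hz, noise-smoothing median filter cut-off
    bin_s          = 5,      # s, aggregation bin width
    trim_s         = 1800,   # s, removed from each end of a deployment
    static_win_s   = 10,     # s, window for static-period search
    static_sd_g    = 0.013,  # g, rolling-SD threshold for static periods
    autocalibrate  = TRUE,
    # solar
    night_elev_deg = -6,     # deg, sun elevation below which it is night
    # hmm
    log_odba_eps   = 1e-4,   # g, offset inside log(odba + eps)
    hmm_tol        = 1e-6,   # Baum-Welch loglik convergence tolerance
    hmm_max_iter   = 200,
    # postprocess
    lx_thresh      = 50,     # lx, daylight brooding light threshold
    min_dark_bins  = 1,      # bins < lx_thresh required in a daylight bout
    min_bout_s     = 20,     # s, bouts and gaps up to this length are pruned
    search_s       = 600,    # s, cap on the boundary-adjustment search window
    min_adjust_diff = 0.05,  # degC per 5-s bin, magnitude floor for boundary moves
    break_rule     = "falls_below", # or "rises_above": break-onset direction
    min_state_bins = 10,     # bins per state needed for temp-diff stats
    mass_thresh_g  = 65,     # g, feathered-chick exclusion threshold
    # summaries
    min_eff_bout_s = 300,    # s, efficiency uses bouts longer than this
    eff_exclude_s  = 300,    # s, excluded from the start of each bout
    round_minutes  = FALSE   # round binomial numerators at export
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
    }
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = c("brood_config", "list"))
}

#' Read a YAML configuration file
#'
#' Keys present in the file override the defaults of [brood_config()];
#' unknown keys raise an error so typos do not silently fall back.
#'
#' @param path Path to a YAML file.
#' @return A `brood_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(brood_config, vals)
}

#' Write a configuration to YAML
#'
#' @param cfg A `brood_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
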