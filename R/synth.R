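# Synthetic multichannel datalogger recordings with ground-truth
# behavioural states. The generator emulates the statistical structure the
# detection pipeline relies on: a diel ambient-temperature cycle, an
# alternating semi-Markov behaviour sequence whose rest-type choice
# follows a logistic in ambient temperature and night, first-order
# relaxation of on-body temperature toward a species-specific brooding
# equilibrium, sun-driven light with a plant-shade confounder, and
# state-dependent dynamic acceleration on a slowly re-orienting gravity
# vector, distorted by a configurable sensor miscalibration.

SIM_SITES <- list(
  NL = list(lat = 48.99, lon = 14.38, start_utc = "2019-05-20T00:00:00Z"),
  RWL = list(lat = 24.83, lon = 55.36, start_utc = "2019-04-01T00:00:00Z"))

#' Simulator configuration
#'
#' Species presets: `NL` (Northern lapwing: ambient mean 15 degC,
#' brooding equilibrium 37.2 degC, temperate-site coordinates) and `RWL`
#' (Red-wattled lapwing: ambient mean 32 degC, equilibrium 35.0 degC,
#' desert-site coordinates). Ambient means/amplitudes are plausible
#' testing defaults, not field estimates; the equilibria match the
#' species' observed bout-median brooding temperatures.
#'
#' @param species `"NL"` or `"RWL"`.
#' @param ... Named overrides of any default listed below.
#'
#' @return A list of class `brood_sim_config`. Key fields: `duration_h`;
#'   ambient model (`ambient_mean`, `ambient_amp`, `ambient_noise_sd`,
#'   `ambient_ar`, `ambient_peak_h`); brooding-choice logistic
#'   (`brood_intercept`, `brood_temp_slope` per degC about `tamb_ref`,
#'   `brood_night_effect`); lognormal bout-duration parameters per state
#'   (`dur_brooding`, `dur_active`, `dur_shade`, `dur_other_rest`, each
#'   `c(meanlog, sdlog)` in seconds); thermal model (`tau_s`, `t_eq`,
#'   `active_excess`, `tbody_noise_sd`); activity model (`odba_sd_active`,
#'   `odba_sd_rest`, `odba_ar`); light model (`shade_prob`, `shade_light`,
#'   `brood_light`, `day_light_base`); sensor miscalibration (`offset`,
#'   `gain`); `pre_contact_still_s` (still lag inserted before each
#'   brooding bout); site (`lat`, `lon`, `start_utc`); `seed`.
#' @export
sim_config <- function(species = c("NL", "RWL"), ...) {
  species <- match.arg(species)
  site <- SIM_SITES[[species]]
  cfg <- list(
    species = species,
    duration_h = 48,
    fs_accel = 25,
    ambient_mean = if (species == "NL") 15 else 32,
    ambient_amp = 8,
    ambient_noise_sd = 0.15,
    ambient_ar = 0.95,      # per-minute AR(1) coefficient
    ambient_peak_h = 15,    # local hour of the diel maximum
    brood_intercept = 0.5,
    brood_temp_slope = -0.12,  # per degC, <= 0
    brood_night_effect = 2.2,  # >= 0
    tamb_ref = 20,
    dur_brooding = c(meanlog = log(900), sdlog = 0.5),
    dur_active = c(meanlog = log(600), sdlog = 0.6),
    dur_shade = c(meanlog = log(480), sdlog = 0.5),
    dur_other_rest = c(meanlog = log(300), sdlog = 0.5),
    tau_s = 120,
    t_eq = if (species == "NL") 37.2 else 35.0,
    active_excess = 1,      # degC above ambient when not brooded
    tbody_noise_sd = 0.02,
    odba_sd_active = 0.15,  # g per axis
    odba_sd_rest = 0.006,
    odba_ar = 0.7,          # 25 Hz AR(1) coefficient of dynamic accel
    shade_prob = 0.7,       # P(shade-rest | daytime non-brooding rest)
    shade_light = c(200, 2000),
    brood_light = c(0, 20),
    day_light_base = c(1e4, 1e5),
    offset = c(0.02, -0.015, 0.01),
    gain = c(1.01, 0.99, 1.005),
    pre_contact_still_s = 0,
    lat = site$lat,
    lon = site$lon,
    start_utc = site$start_utc,
    seed = 1)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) abort(paste0("unknown sim_config key(s): ", paste(bad, collapse = ", ")))
    cfg[names(dots)] <- dots
  }
  validate_sim_config(structure(cfg, class = c("brood_sim_config", "list")))
}

validate_sim_config <- function(cfg) {
  if (cfg$brood_temp_slope > 0) abort("brood_temp_slope must be <= 0")
  if (cfg$brood_night_effect < 0) abort("brood_night_effect must be >= 0")
  if (cfg$tau_s <= 0) abort("tau_s must be positive")
  if (cfg$duration_h <= 0) abort("duration_h must be positive")
  for (nm in c("ambient_noise_sd", "tbody_noise_sd", "odba_sd_active",
               "odba_sd_rest")) {
    if (cfg[[nm]] < 0) abort(paste0(nm, " must be non-negative"))
  }
  for (nm in c("dur_brooding", "dur_active", "dur_shade", "dur_other_rest")) {
    if (length(cfg[[nm]]) != 2 || cfg[[nm]][2] < 0) {
      abort(paste0(nm, " must be c(meanlog, sdlog >= 0)"))
    }
  }
  cfg
}

SIM_STATES <- c("brooding", "foraging", "shade_rest", "other_rest")

# diel sinusoid + AR(1) noise on a 60-s grid
sim_ambient <- function(cfg, n_s) {
  n_min <- ceiling(n_s / 60) + 1
  t_min <- (seq_len(n_min) - 1) * 60
  start <- parse_utc(cfg$start_utc)
  h_local <- ((as.numeric(start) %% 86400) + t_min) / 3600 +
    tz_offset_hours(cfg$species)
  base <- cfg$ambient_mean +
    cfg$ambient_amp * cos(2 * pi * (h_local - cfg$ambient_peak_h) / 24)
  e <- rnorm(n_min, 0, cfg$ambient_noise_sd * sqrt(1 - cfg$ambient_ar^2))
  noise <- as.numeric(stats::filter(e, cfg$ambient_ar, method = "recursive"))
  tibble::tibble(t = start + t_min, tamb = base + noise)
}

# alternating semi-Markov state sequence at 1 Hz
sim_states <- function(cfg, n_s, tamb_1hz, elev_1hz) {
  draw <- function(p) max(5, round(rlnorm(1, p[1], p[2])))
  t <- 0
  st <- character(0); s0 <- numeric(0); s1 <- numeric(0)
  push <- function(state, dur) {
    st <<- c(st, state); s0 <<- c(s0, t); s1 <<- c(s1, min(t + dur, n_s))
    t <<- t + dur
  }
  while (t < n_s) {
    push("foraging", draw(cfg$dur_active))
    if (t >= n_s) break
    i <- min(t + 1, n_s)
    night <- night_flag(elev_1hz[i])
    p_brood <- plogis(cfg$brood_intercept +
                        cfg$brood_temp_slope * (tamb_1hz[i] - cfg$tamb_ref) +
                        cfg$brood_night_effect * night)
    if (runif(1) < p_brood) {
      if (cfg$pre_contact_still_s > 0) {
        push("other_rest", cfg$pre_contact_still_s)
      }
      push("brooding", draw(cfg$dur_brooding))
    } else if (!night && elev_1hz[i] > 0 && runif(1) < cfg$shade_prob) {
      push("shade_rest", draw(cfg$dur_shade))
    } else {
      push("other_rest", draw(cfg$dur_other_rest))
    }
  }
  bouts <- tibble::tibble(state = st, start_s = s0, end_s = s1)
  bouts <- bouts[bouts$end_s > bouts$start_s, ]
  states <- rep(bouts$state, times = bouts$end_s - bouts$start_s)
  list(states = factor(states, levels = SIM_STATES), bouts = bouts)
}

#' Simulate one chick's datalogger recording
#'
#' @param cfg A [sim_config()].
#' @param chick_id Identifier for the generated chick.
#' @param family_id Family identifier (defaults to one family per chick).
#' @param ambient Optional precomputed ambient tibble (shared across a
#'   cohort); generated from `cfg` when `NULL`.
#' @return A list: `raw` ([raw_trace()]), `ambient` (60-s tibble `t`,
#'   `tamb`), `truth` (`sim_truth`: 1 Hz `states`, true `bouts`,
#'   `brooding_prop`, `config`), `chick` (one-row metadata tibble).
#' @export
simulate_chick <- function(cfg, chick_id = "sim01", family_id = NULL,
                           ambient = NULL) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n_s <- as.integer(round(cfg$duration_h * 3600))
  start <- parse_utc(cfg$start_utc)
  if (is.null(ambient)) ambient <- sim_ambient(cfg, n_s)

  tsec <- seq_len(n_s) - 1
  tamb_1hz <- approx(as.numeric(ambient$t) - as.numeric(start), ambient$tamb,
                     xout = tsec, rule = 2)$y
  elev_1hz <- sun_elevation(start + tsec, cfg$lat, cfg$lon)

  ss <- sim_states(cfg, n_s, tamb_1hz, elev_1hz)
  states <- ss$states

  # on-body temperature: dT/dt = (T_target - T) / tau
  target <- ifelse(states == "brooding", cfg$t_eq,
                   tamb_1hz + cfg$active_excess)
  tb <- numeric(n_s)
  tb[1] <- target[1]
  a <- 1 / cfg$tau_s
  for (i in 2:n_s) tb[i] <- tb[i - 1] + a * (target[i] - tb[i - 1])
  tbody <- tb + rnorm(n_s, 0, cfg$tbody_noise_sd)

  # light: per-bout clear-sky base, shade and brooding overrides
  u_bout <- 10^runif(nrow(ss$bouts), log10(cfg$day_light_base[1]),
                     log10(cfg$day_light_base[2]))
  u_1hz <- rep(u_bout, times = ss$bouts$end_s - ss$bouts$start_s)
  light <- u_1hz * pmax(sin(elev_1hz * pi / 180), 0) + 600 * 10^(elev_1hz / 8)
  ib <- which(states == "brooding")
  light[ib] <- runif(length(ib), cfg$brood_light[1], cfg$brood_light[2])
  ish <- which(states == "shade_rest")
  light[ish] <- runif(length(ish), cfg$shade_light[1], cfg$shade_light[2])

  # acceleration: per-bout gravity orientation + AR(1) dynamic noise
  n25 <- n_s * cfg$fs_accel
  ori <- matrix(rnorm(nrow(ss$bouts) * 3), ncol = 3)
  ori <- ori / sqrt(rowSums(ori^2))
  ori_1hz <- ori[rep(seq_len(nrow(ss$bouts)),
                     times = ss$bouts$end_s - ss$bouts$start_s), , drop = FALSE]
  # smooth posture changes over ~5 s, keep unit norm
  ori_s <- apply(ori_1hz, 2, function(v) running_median(v, 5))
  nrm <- sqrt(rowSums(ori_s^2)); nrm[nrm < 1e-9] <- 1
  ori_s <- ori_s / nrm
  amp_1hz <- ifelse(states == "foraging", cfg$odba_sd_active, cfg$odba_sd_rest)
  amp25 <- rep(amp_1hz, each = cfg$fs_accel)
  ar_scale <- sqrt(1 - cfg$odba_ar^2)
  axis_sig <- function(j) {
    g <- rep(ori_s[, j], each = cfg$fs_accel)
    dyn <- as.numeric(stats::filter(rnorm(n25, 0, ar_scale), cfg$odba_ar,
                                    method = "recursive")) * amp25
    cfg$gain[j] * (g + dyn) + cfg$offset[j]
  }
  accel <- tibble::tibble(t = (seq_len(n25) - 1) / cfg$fs_accel,
                          ax = axis_sig(1), ay = axis_sig(2), az = axis_sig(3))

  raw <- structure(list(accel = accel,
                        slow = tibble::tibble(t = seq_len(n_s) - 1,
                                              tbody = tbody, light = light),
                        start_utc = start, chick_id = chick_id,
                        fs_accel = cfg$fs_accel, fs_slow = 1),
                   class = "raw_trace")

  truth <- structure(list(states = states, bouts = ss$bouts,
                          brooding_prop = mean(states == "brooding"),
                          config = cfg),
                     class = "sim_truth")
  chick <- tibble::tibble(
    chick_id = chick_id,
    family_id = family_id %||% paste0("F_", chick_id),
    species = cfg$species,
    head_length = round(runif(1, 20, 35), 1),
    mass_start = round(runif(1, 15, 55), 1),
    mass_end = NA_real_,
    deploy_start = start,
    deploy_end = start + n_s,
    lat = cfg$lat, lon = cfg$lon)
  chick$mass_end <- round(min(chick$mass_start + runif(1, 1, 6), 64), 1)
  list(raw = raw, ambient = ambient, truth = truth, chick = chick)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %s preset, %.0f h, %d true bouts, brooding proportion %.3f\n",
              x$config$species, x$config$duration_h, nrow(x$bouts),
              x$brooding_prop))
  invisible(x)
}

#' True brooding intervals of a simulation
#'
#' @param truth A `sim_truth`.
#' @param chick_id Identifier for the returned bout tibble.
#' @return Bout tibble of the true brooding intervals.
#' @export
truth_bouts <- function(truth, chick_id = "chick") {
  bb <- truth$bouts[truth$bouts$state == "brooding", ]
  tibble::tibble(chick_id = chick_id, start_s = bb$start_s,
                 end_s = bb$end_s, label = "brooding",
                 provenance = "truth")
}

#' Simulate a cohort of chicks
#'
#' Per-chick seeds are derived deterministically from `seed`; all chicks
#' share one ambient-temperature realisation (one site). With `dir` the
#' on-disk layout is written: `<chick>_accel.csv`, `<chick>_slow.csv`,
#' `chicks.csv`, `ambient.csv` and `truth.csv` (true bout intervals plus
#' per-chick true brooding proportions).
#'
#' @param cfg_base A [sim_config()]; per-chick seeds override its `seed`.
#' @param n_chicks Number of chicks (>= 1).
#' @param seed Master seed.
#' @param dir Optional output directory.
#' @param force Overwrite an existing non-empty `dir`.
#' @return A list: `sims` (per-chick lists as from [simulate_chick()]),
#'   `chicks` (metadata tibble), `ambient`.
#' @export
simulate_cohort <- function(cfg_base, n_chicks, seed = 1, dir = NULL,
                            force = FALSE) {
  if (n_chicks < 1) abort("n_chicks must be >= 1")
  if (!is.null(dir) && dir.exists(dir) && length(dir(dir)) && !force) {
    abort(paste0("output directory not empty: ", dir, " (use force = TRUE)"))
  }
  cfg0 <- cfg_base
  cfg0$seed <- seed
  set.seed(seed)
  n_s <- as.integer(round(cfg_base$duration_h * 3600))
  ambient <- sim_ambient(cfg0, n_s)
  sims <- purrr::map(seq_len(n_chicks), function(i) {
    cfg <- cfg_base
    cfg$seed <- (seed + 7919L * i) %% .Machine$integer.max
    id <- sprintf("%s%02d", cfg$species, i)
    simulate_chick(cfg, chick_id = id,
                   family_id = sprintf("F%s%02d", cfg$species, (i + 1) %/% 2),
                   ambient = ambient)
  })
  chicks <- dplyr::bind_rows(purrr::map(sims, "chick"))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    purrr::walk(sims, function(s) write_raw_trace(s$raw, dir))
    write_chicks(chicks, file.path(dir, "chicks.csv"))
    write_ambient(ambient, file.path(dir, "ambient.csv"))
    tb <- purrr::map2(sims, chicks$chick_id, function(s, id) {
      dplyr::mutate(s$truth$bouts, chick_id = id, .before = 1)
    }) |> dplyr::bind_rows()
    readr::write_csv(tb, file.path(dir, "truth.csv"))
  }
  list(sims = sims, chicks = chicks, ambient = ambient)
}
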