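# Model-ready summary tables. Mixed-model fitting itself (binomial GLMM of
# hourly rates, Gaussian LMM of efficiency) is deliberately left to the
# user's downstream tooling; these builders emit schema-stable tibbles with
# the response, predictors and weights already constructed.

# local standard time offsets of the two study regions (no DST)
tz_offset_hours <- function(species) {
  c(NL = 1, RWL = 4)[[species]]
}

# exact seconds of overlap between intervals [s, e) and each local clock hour
overlap_per_hour <- function(s, e) {
  if (!length(s)) return(tibble::tibble(hour_id = numeric(), seconds = numeric()))
  pieces <- purrr::map2(s, e, function(a, b) {
    hrs <- seq(floor(a / 3600), ceiling(b / 3600) - 1)
    lo <- pmax(a, hrs * 3600)
    hi <- pmin(b, (hrs + 1) * 3600)
    tibble::tibble(hour_id = hrs[hi > lo], seconds = (hi - lo)[hi > lo])
  })
  dplyr::bind_rows(pieces) |>
    dplyr::group_by(.data$hour_id) |>
    dplyr::summarise(seconds = sum(.data$seconds), .groups = "drop")
}

#' Hourly brooding-rate table
#'
#' One row per local clock hour with any observed coverage: brooded and
#' non-brooded minutes (the binomial numerator and complement), the
#' previous hour's brooding proportion, the civil-twilight night flag at
#' the hour midpoint, mean ambient temperature, the sine/cosine diel
#' transform of the clock hour, and the square-root-of-minutes model
#' weight. Local time is the site's standard time (UTC+1 for NL, UTC+4
#' for RWL, no DST). Partial hours are kept with reduced weight; minutes
#' are exact interval coverage (fractional) unless `config$round_minutes`.
#'
#' @param bouts Finalised bout tibble for one chick.
#' @param trace Trimmed 5-s trace tibble for the same chick.
#' @param chick One-row chick tibble.
#' @param config A [brood_config()].
#' @return Tibble with one row per observed hour.
#' @export
hourly_table <- function(bouts, trace, chick, config = brood_config()) {
  tid <- attr(trace, "chick_id")
  if (!is.null(tid) && nrow(bouts) > 0 &&
      !all(bouts$chick_id == tid)) {
    abort("bout table and trace belong to different chicks")
  }
  start_utc <- attr(trace, "start_utc") %||% chick$deploy_start[1]
  off_s <- tz_offset_hours(chick$species[1]) * 3600
  t0_local <- as.numeric(start_utc) + off_s
  bin_s <- config$bin_s

  obs <- overlap_per_hour(t0_local + trace$t5, t0_local + trace$t5 + bin_s)
  bb <- bouts[bouts$label == "brooding", ]
  brood <- overlap_per_hour(t0_local + bb$start_s, t0_local + bb$end_s)

  hour_of_bin <- floor((t0_local + trace$t5 + bin_s / 2) / 3600)
  tamb_by_hour <- tibble::tibble(hour_id = hour_of_bin, tamb = trace$tamb5) |>
    dplyr::group_by(.data$hour_id) |>
    dplyr::summarise(tamb_mean = mean(.data$tamb, na.rm = TRUE), .groups = "drop")

  out <- obs |>
    dplyr::left_join(brood, by = "hour_id", suffix = c("_obs", "_brood")) |>
    dplyr::mutate(seconds_brood = dplyr::coalesce(.data$seconds_brood, 0)) |>
    dplyr::left_join(tamb_by_hour, by = "hour_id") |>
    dplyr::arrange(.data$hour_id)

  mid_utc <- as.POSIXct((out$hour_id + 0.5) * 3600 - off_s,
                        origin = "1970-01-01", tz = "UTC")
  hour_clock <- out$hour_id %% 24
  dt <- diel_transform(hour_clock)
  min_b <- out$seconds_brood / 60
  min_o <- out$seconds_obs / 60
  if (isTRUE(config$round_minutes)) {
    min_b <- round(min_b)
    min_o <- round(min_o)
  }
  res <- tibble::tibble(
    chick_id = chick$chick_id[1],
    family_id = chick$family_id[1],
    species = chick$species[1],
    hour_id = out$hour_id,
    hour_start = hour_clock,
    min_brooded = min_b,
    min_not_brooded = pmax(min_o - min_b, 0),
    prop_brooded = ifelse(min_o > 0, min_b / min_o, NA_real_),
    night = night_flag(sun_elevation(mid_utc, chick$lat[1], chick$lon[1])),
    tamb_mean = out$tamb_mean,
    head_length = chick$head_length[1],
    sin_t = dt$sin_t,
    cos_t = dt$cos_t,
    weight = sqrt(min_o))
  res$prev_hour_prop <- dplyr::lag(res$prop_brooded)
  res$prev_hour_prop[c(TRUE, diff(res$hour_id) != 1)] <- NA_real_
  res
}

#' Brooding-efficiency table
#'
#' One row per brooding bout longer than 5 min: the median on-body
#' temperature over the bins starting at least 5 min after bout onset
#' (the stabilisation window is excluded), with night flag, mean ambient
#' temperature over the same bins and the chick's age proxy.
#'
#' @inheritParams hourly_table
#' @return Tibble with one row per qualifying bout.
#' @export
efficiency_table <- function(bouts, trace, chick, config = brood_config()) {
  bb <- bouts[bouts$label == "brooding" &
                bouts$end_s - bouts$start_s > config$min_eff_bout_s, ]
  rows <- purrr::pmap(list(bb$start_s, bb$end_s), function(s, e) {
    idx <- bins_in(trace, s + config$eff_exclude_s, e)
    if (!length(idx)) return(NULL)
    tibble::tibble(
      chick_id = chick$chick_id[1],
      family_id = chick$family_id[1],
      species = chick$species[1],
      bout_start_s = s,
      bout_dur_s = e - s,
      median_temp = median(trace$tbody5[idx], na.rm = TRUE),
      night = mean(night_flag(trace$sun_elev[idx])) > 0.5,
      tamb_mean = mean(trace$tamb5[idx], na.rm = TRUE),
      head_length = chick$head_length[1])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(chick_id = character(), family_id = character(),
                          species = character(), bout_start_s = numeric(),
                          bout_dur_s = numeric(), median_temp = numeric(),
                          night = logical(), tamb_mean = numeric(),
                          head_length = numeric())
  }
  out
}

#' Overall brooding rate across a cohort
#'
#' Per-chick proportion of observed time labelled brooding, with the
#' cohort median and 25-75th quantiles.
#'
#' @param bouts Bout tibble covering one or more chicks.
#' @param traces A single trace tibble or a named list of trace tibbles
#'   keyed by chick id (defines the observed time per chick).
#' @param bin_s Bin width of the traces, s.
#' @return A list: `per_chick` tibble (`chick_id`, `brooded_s`,
#'   `observed_s`, `proportion`), `median`, `q25`, `q75`.
#' @export
overall_rate <- function(bouts, traces, bin_s = 5) {
  if (is.data.frame(traces)) {
    traces <- stats::setNames(list(traces),
                              attr(traces, "chick_id") %||%
                                (bouts$chick_id[1] %||% "chick"))
  }
  per <- purrr::imap(traces, function(tr, id) {
    bb <- bouts[bouts$chick_id == id & bouts$label == "brooding", ]
    tibble::tibble(chick_id = id,
                   brooded_s = sum(bb$end_s - bb$start_s),
                   observed_s = nrow(tr) * bin_s)
  }) |> dplyr::bind_rows()
  per$proportion <- ifelse(per$observed_s > 0,
                           per$brooded_s / per$observed_s, NA_real_)
  qs <- quantile(per$proportion, c(0.25, 0.5, 0.75), na.rm = TRUE)
  list(per_chick = per, median = unname(qs[2]),
       q25 = unname(qs[1]), q75 = unname(qs[3]))
}

#' Diel sine/cosine transform of clock time
#'
#' Hours are mapped to an angle `theta = 2 * pi * hour / 24`; the sine and
#' cosine enter diel models as a smooth circular predictor pair.
#'
#' @param hour Local clock time in hours, in `[0, 24)`.
#' @return Tibble with `sin_t`, `cos_t` (`sin_t^2 + cos_t^2 = 1`).
#' @export
#'
#' @examples
#' diel_transform(c(0, 6, 12, 18))
diel_transform <- function(hour) {
  if (any(hour < 0 | hour >= 24)) abort("hour must lie in [0, 24)")
  theta <- 2 * pi * hour / 24
  tibble::tibble(sin_t = sin(theta), cos_t = cos(theta))
}

#' z-transform a numeric column
#'
#' Mean-centring and division by the sample SD (n - 1 denominator), with
#' the constants kept for back-transformation of model coefficients.
#'
#' @param x Numeric vector with positive SD.
#' @return A list: `z` (standardised values), `mean`, `sd`.
#' @export
ztransform <- function(x) {
  m <- mean(x, na.rm = TRUE)
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) abort("cannot z-transform a constant column")
  list(z = (x - m) / s, mean = m, sd = s)
}
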