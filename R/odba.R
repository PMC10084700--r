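#' Overall dynamic body acceleration (ODBA)
#'
#' Per axis, the gravitational component is estimated by a 0.2 Hz moving
#' median and subtracted (high-pass); the dynamic residual is then smoothed
#' by a 2 Hz moving median (low-pass) to suppress sensor noise. ODBA is the
#' sum of the absolute smoothed dynamic components of the three axes.
#'
#' @param raw_cal A calibrated [raw_trace()].
#' @param fc_highpass,fc_lowpass Median-filter cut-offs, Hz.
#' @return Tibble `t`, `odba` on the 25 Hz grid; `odba >= 0` everywhere.
#' @export
compute_odba <- function(raw_cal, fc_highpass = 0.2, fc_lowpass = 2) {
  fs <- raw_cal$fs_accel
  dyn <- function(v) {
    d <- v - median_filter(v, fc_highpass, fs)
    median_filter(d, fc_lowpass, fs)
  }
  odba <- abs(dyn(raw_cal$accel$ax)) +
    abs(dyn(raw_cal$accel$ay)) +
    abs(dyn(raw_cal$accel$az))
  tibble::tibble(t = raw_cal$accel$t, odba = odba)
}

#' Aggregate channels onto the 5-s analysis grid
#'
#' ODBA, on-body temperature and light are averaged over consecutive 5-s
#' bins anchored at t = 0; ambient temperature is interpolated to bin
#' centres and the sun elevation is computed there from the deployment
#' start time and site coordinates. Bins holding no accelerometer samples
#' are dropped; missing slow samples propagate as `NA`.
#'
#' @param odba ODBA tibble from [compute_odba()].
#' @param raw The (calibrated) [raw_trace()] supplying the slow channels.
#' @param ambient Ambient tibble (`t` `POSIXct`, `tamb` degC), or `NULL`.
#' @param chick One-row chick tibble with `lat`, `lon` (or `NULL` to skip
#'   the solar column).
#' @param bin_s Bin width, s.
#' @param ambient_gap_s Ambient gaps longer than this spanning a bin centre
#'   leave `tamb5` missing for the affected bins, with a warning.
#' @return Trace tibble `t5, odba5, tbody5, light5, tamb5, sun_elev,
#'   n_valid` with attributes `chick_id` and `start_utc`.
#' @export
aggregate_trace <- function(odba, raw, ambient = NULL, chick = NULL,
                            bin_s = 5, ambient_gap_s = 3600) {
  bin_of <- function(t) floor(t / bin_s) * bin_s
  fast <- tibble::tibble(b = bin_of(odba$t), odba = odba$odba) |>
    dplyr::group_by(.data$b) |>
    dplyr::summarise(odba5 = mean(.data$odba), n_valid = dplyr::n(),
                     .groups = "drop")
  slow <- tibble::tibble(b = bin_of(raw$slow$t),
                         tbody = raw$slow$tbody, light = raw$slow$light) |>
    dplyr::group_by(.data$b) |>
    dplyr::summarise(tbody5 = mean(.data$tbody), light5 = mean(.data$light),
                     .groups = "drop")
  out <- fast |>
    dplyr::left_join(slow, by = "b") |>
    dplyr::rename(t5 = "b") |>
    dplyr::arrange(.data$t5)

  centre <- out$t5 + bin_s / 2
  if (!is.null(ambient) && nrow(ambient) >= 2) {
    ta <- as.numeric(ambient$t) - as.numeric(raw$start_utc)
    out$tamb5 <- approx(ta, ambient$tamb, xout = centre, rule = 2)$y
    # mask bins whose centre falls inside (or beyond) a gap longer than 1 h
    idx <- findInterval(centre, ta)
    gap_before <- idx >= 1 & idx < length(ta) & (ta[pmin(idx + 1, length(ta))] - ta[pmax(idx, 1)]) > ambient_gap_s
    outside <- (centre < ta[1] - ambient_gap_s) | (centre > ta[length(ta)] + ambient_gap_s)
    mask <- (gap_before | outside)
    if (any(mask)) {
      warn(sprintf("ambient gap > %.0f s overlaps the trace: %d bins left without tamb5",
                   ambient_gap_s, sum(mask)))
      out$tamb5[mask] <- NA_real_
    }
  } else {
    out$tamb5 <- NA_real_
  }
  if (!is.null(chick)) {
    out$sun_elev <- sun_elevation(raw$start_utc + centre,
                                  chick$lat[1], chick$lon[1])
  } else {
    out$sun_elev <- NA_real_
  }
  out <- out[, c("t5", "odba5", "tbody5", "light5", "tamb5", "sun_elev", "n_valid")]
  attr(out, "chick_id") <- raw$chick_id
  attr(out, "start_utc") <- raw$start_utc
  out
}

#' Trim the deployment edges
#'
#' Removes the first and last `trim_s` seconds (default 30 min) so that
#' handling disturbance around logger attachment and retrieval, and the
#' truncated filter windows at the series ends, never enter the analysis.
#'
#' @param trace A 5-s trace tibble.
#' @param trim_s Seconds removed from each end.
#' @return The trimmed trace; empty (with a warning) when the trace is not
#'   longer than `2 * trim_s`.
#' @export
trim_edges <- function(trace, trim_s = 1800) {
  if (nrow(trace) == 0) return(trace)
  bin_s <- if (nrow(trace) > 1) min(diff(trace$t5)) else 5
  t_lo <- min(trace$t5)
  t_hi <- max(trace$t5) + bin_s
  if (t_hi - t_lo <= 2 * trim_s) {
    warn(sprintf("trace of %.0f s not longer than twice the %.0f s trim: empty result",
                 t_hi - t_lo, trim_s))
    out <- trace[0, ]
  } else {
    out <- trace[trace$t5 >= t_lo + trim_s & (trace$t5 + bin_s) <= t_hi - trim_s, ]
  }
  attributes(out)$chick_id <- attr(trace, "chick_id")
  attributes(out)$start_utc <- attr(trace, "start_utc")
  out
}

#' Preprocess one chick end to end
#'
#' Autocalibration (optional), ODBA, 5-s aggregation with ambient and solar
#' columns, and the 30-min edge trim.
#'
#' @param raw A [raw_trace()].
#' @param ambient Ambient tibble or `NULL`.
#' @param chick One-row chick tibble or `NULL`.
#' @param config A [brood_config()].
#' @return A trimmed 5-s trace tibble; the calibration used is attached as
#'   attribute `"calibration"`.
#' @export
preprocess_chick <- function(raw, ambient = NULL, chick = NULL,
                             config = brood_config()) {
  cal <- if (isTRUE(config$autocalibrate)) {
    sw <- find_static_windows(raw, config$static_win_s, config$static_sd_g)
    autocalibrate(sw[, c("mx", "my", "mz")])
  } else {
    structure(list(offset = c(0, 0, 0), gain = c(1, 1, 1),
                   n_static_windows = 0L, n_orientations = 0L,
                   converged = FALSE), class = "calibration")
  }
  raw_cal <- apply_calibration(raw, cal)
  odba <- compute_odba(raw_cal, config$fc_highpass, config$fc_lowpass)
  trace <- aggregate_trace(odba, raw_cal, ambient, chick, config$bin_s)
  trace <- trim_edges(trace, config$trim_s)
  attr(trace, "calibration") <- cal
  trace
}
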