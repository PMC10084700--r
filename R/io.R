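# On-disk layout
# --------------
# <chick>_accel.csv  : t,ax,ay,az           (25 Hz; t = seconds since start)
# <chick>_slow.csv   : t,tbody,light        (1 Hz)
# <chick>_trace5.csv : t5,odba5,tbody5,light5,tamb5,sun_elev,n_valid
# chicks.csv         : one row per chick (metadata)
# ambient.csv        : t (ISO-8601 UTC), tamb
# bout tables        : chick_id,start_s,end_s,label[,provenance]
# Trace files carry sidecar comment lines ("# key=value") with chick_id and
# the ISO-8601 UTC timestamp of sample 0; all other times are relative seconds.

BOUT_LABELS <- c("brooding", "active", "other_inactive")

fmt_utc <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

parse_utc <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                   "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"))
  if (anyNA(out)) abort(paste0("unparseable UTC timestamp: ", x[which(is.na(out))[1]]))
  out
}

read_sidecar <- function(path, n_max = 10) {
  lines <- readLines(path, n = n_max)
  meta <- grep("^#", lines, value = TRUE)
  kv <- sub("^#\\s*", "", meta)
  kv <- kv[grepl("=", kv, fixed = TRUE)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(as.list(trimws(vals)), trimws(keys))
}

write_channel_csv <- function(df, path, chick_id, start_utc) {
  writeLines(c(paste0("# chick_id=", chick_id),
               paste0("# start_utc=", fmt_utc(start_utc))), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_channel_csv <- function(path, required_cols) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (nrow(df) == 0) abort(paste0("empty file: ", path))
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    abort(paste0("missing column(s) ", paste(missing, collapse = ", "),
                 " in ", path))
  }
  df
}

check_monotone <- function(t, what, path) {
  bad <- which(diff(t) <= 0)
  if (length(bad)) {
    abort(paste0("non-monotone ", what, " time at data row ", bad[1] + 1L,
                 " of ", path))
  }
}

#' Assemble and validate a raw dual-rate datalogger trace
#'
#' @param accel Tibble with columns `t`, `ax`, `ay`, `az` (25 Hz grid, g).
#' @param slow Tibble with columns `t`, `tbody` (degC), `light` (lx) on a
#'   1 Hz grid. Missing slow samples may be `NA` (never zero-filled).
#' @param start_utc `POSIXct` timestamp of sample 0.
#' @param chick_id Identifier string.
#' @param fs_accel,fs_slow Nominal sampling rates (Hz).
#'
#' @return An object of class `raw_trace`: a list with elements `accel`,
#'   `slow`, `start_utc`, `chick_id`.
#' @export
raw_trace <- function(accel, slow, start_utc, chick_id = "chick",
                      fs_accel = 25, fs_slow = 1) {
  accel <- tibble::as_tibble(accel)
  slow <- tibble::as_tibble(slow)
  x <- structure(list(accel = accel, slow = slow,
                      start_utc = parse_utc(fmt_utc(start_utc)),
                      chick_id = chick_id,
                      fs_accel = fs_accel, fs_slow = fs_slow),
                 class = "raw_trace")
  validate_raw_trace(x)
}

validate_raw_trace <- function(x, path = "<memory>") {
  for (nm in c("t", "ax", "ay", "az")) {
    if (!nm %in% names(x$accel)) abort(paste0("accel channel lacks column ", nm))
  }
  for (nm in c("t", "tbody", "light")) {
    if (!nm %in% names(x$slow)) abort(paste0("slow channel lacks column ", nm))
  }
  check_monotone(x$accel$t, "accelerometer", path)
  check_monotone(x$slow$t, "slow-channel", path)
  step <- median(diff(x$accel$t))
  if (abs(step - 1 / x$fs_accel) > 0.01 / x$fs_accel) {
    abort(sprintf("accelerometer sampling interval %.5f s deviates > 1%% from nominal %.5f s",
                  step, 1 / x$fs_accel))
  }
  step_s <- median(diff(x$slow$t))
  if (abs(step_s - 1 / x$fs_slow) > 0.01 / x$fs_slow) {
    abort(sprintf("slow-channel sampling interval %.3f s deviates > 1%% from nominal %.3f s",
                  step_s, 1 / x$fs_slow))
  }
  if (any(x$slow$light < 0, na.rm = TRUE)) {
    abort("negative light level in slow channel")
  }
  # both channels must span the same interval, within one slow sample
  tol <- 1 / x$fs_slow + 1e-9
  if (abs(min(x$accel$t) - min(x$slow$t)) > tol ||
      abs(max(x$accel$t) - max(x$slow$t)) > tol) {
    abort("accelerometer and slow channels cover different intervals")
  }
  x
}

#' Read a raw dual-rate trace from its CSV pair
#'
#' @param accel_path Path to `<chick_id>_accel.csv`; the slow channel is read
#'   from the sibling `<chick_id>_slow.csv` unless `slow_path` is given.
#' @param slow_path Optional explicit path to the slow-channel file.
#' @return A validated [raw_trace()] object.
#' @export
read_raw_trace <- function(accel_path, slow_path = NULL) {
  if (is.null(slow_path)) {
    slow_path <- sub("_accel\\.csv$", "_slow.csv", accel_path)
  }
  accel <- read_channel_csv(accel_path, c("t", "ax", "ay", "az"))
  slow <- read_channel_csv(slow_path, c("t", "tbody", "light"))
  meta <- read_sidecar(accel_path)
  if (is.null(meta$start_utc)) abort(paste0("no start_utc sidecar line in ", accel_path))
  x <- structure(list(accel = accel, slow = slow,
                      start_utc = parse_utc(meta$start_utc),
                      chick_id = meta$chick_id %||% "chick",
                      fs_accel = 25, fs_slow = 1),
                 class = "raw_trace")
  validate_raw_trace(x, accel_path)
}

#' Write a raw trace to its CSV pair
#'
#' @param raw A [raw_trace()] object.
#' @param dir Output directory (created if needed).
#' @return The accel-file path, invisibly.
#' @export
write_raw_trace <- function(raw, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ap <- file.path(dir, paste0(raw$chick_id, "_accel.csv"))
  sp <- file.path(dir, paste0(raw$chick_id, "_slow.csv"))
  write_channel_csv(raw$accel, ap, raw$chick_id, raw$start_utc)
  write_channel_csv(raw$slow, sp, raw$chick_id, raw$start_utc)
  invisible(ap)
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("<raw_trace> %s: %d accel samples (%.0f Hz), %d slow samples, start %s\n",
              x$chick_id, nrow(x$accel), x$fs_accel, nrow(x$slow),
              fmt_utc(x$start_utc)))
  invisible(x)
}

#' Validate a bout table
#'
#' Bout tables are tibbles with columns `chick_id`, `start_s`, `end_s`,
#' `label` (one of brooding / active / other_inactive) and optionally
#' `provenance`. Intervals must be positive-length, sorted and
#' non-overlapping within each chick.
#'
#' @param bouts A bout tibble.
#' @return `bouts`, invisibly, or an error.
#' @export
validate_bouts <- function(bouts) {
  req <- c("chick_id", "start_s", "end_s", "label")
  missing <- setdiff(req, names(bouts))
  if (length(missing)) {
    abort(paste0("bout table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(bouts) == 0) return(invisible(bouts))
  bad_lab <- setdiff(unique(bouts$label), BOUT_LABELS)
  if (length(bad_lab)) abort(paste0("unknown bout label(s): ", paste(bad_lab, collapse = ", ")))
  if (any(bouts$end_s <= bouts$start_s)) abort("bout with end_s <= start_s")
  overl <- bouts |>
    dplyr::group_by(.data$chick_id) |>
    dplyr::arrange(.data$start_s, .by_group = TRUE) |>
    dplyr::summarise(
      bad = dplyr::n() > 1 &&
        any(.data$start_s[-1] < .data$end_s[-dplyr::n()] - 1e-9),
      .groups = "drop")
  if (any(overl$bad)) abort("overlapping bout intervals within a chick")
  invisible(bouts)
}

#' Write / read a bout table
#'
#' Interval endpoints survive the round trip to at least 1 ms precision
#' (full double precision is written).
#'
#' @param bouts A valid bout tibble (see [validate_bouts()]).
#' @param path CSV path.
#' @return `write_bouts()` returns `path` invisibly; `read_bouts()` the
#'   validated tibble.
#' @export
write_bouts <- function(bouts, path) {
  validate_bouts(bouts)
  cols <- intersect(c("chick_id", "start_s", "end_s", "label", "provenance"),
                    names(bouts))
  readr::write_csv(bouts[cols], path)
  invisible(path)
}

#' @rdname write_bouts
#' @export
read_bouts <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          chick_id = readr::col_character(),
                          start_s = readr::col_double(),
                          end_s = readr::col_double(),
                          label = readr::col_character()))
  validate_bouts(df)
  tibble::as_tibble(df)
}

#' Write / read chick metadata
#'
#' One row per chick: identity, family, species (NL = Northern lapwing,
#' RWL = Red-wattled lapwing), head length (mm, age proxy), start and end
#' body mass (g), deployment window (UTC) and site coordinates.
#'
#' @param chicks Tibble of chick records.
#' @param path CSV path.
#' @return The tibble (read) or `path` invisibly (write).
#' @export
write_chicks <- function(chicks, path) {
  validate_chicks(chicks)
  out <- chicks |>
    dplyr::mutate(deploy_start = fmt_utc(.data$deploy_start),
                  deploy_end = fmt_utc(.data$deploy_end))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_chicks
#' @export
read_chicks <- function(path) {
  df <- read_channel_csv(path, c("chick_id", "family_id", "species",
                                 "head_length", "mass_start", "mass_end",
                                 "deploy_start", "deploy_end", "lat", "lon"))
  df <- df |>
    dplyr::mutate(chick_id = as.character(.data$chick_id),
                  family_id = as.character(.data$family_id),
                  deploy_start = parse_utc(.data$deploy_start),
                  deploy_end = parse_utc(.data$deploy_end))
  validate_chicks(df)
  tibble::as_tibble(df)
}

validate_chicks <- function(chicks) {
  bad_sp <- setdiff(unique(chicks$species), c("NL", "RWL"))
  if (length(bad_sp)) abort(paste0("unknown species code(s): ", paste(bad_sp, collapse = ", ")))
  if (any(chicks$deploy_end <= chicks$deploy_start)) abort("deploy_end <= deploy_start")
  if (any(chicks$head_length <= 0)) abort("non-positive head length")
  if (any(chicks$mass_start < 14)) abort("chick below the 14 g deployment minimum")
  if (any(abs(chicks$lat) > 90)) abort("latitude outside [-90, 90]")
  invisible(chicks)
}

#' Write / read an ambient near-ground temperature series
#'
#' Timestamps are absolute (ISO-8601 UTC); gaps are permitted. On read,
#' gaps longer than `gap_warn_s` are attached as attribute `"gaps"`.
#'
#' @param ambient Tibble with `t` (`POSIXct`) and `tamb` (degC).
#' @param path CSV path.
#' @param gap_warn_s Gap length (s) above which a gap is flagged.
#' @return The tibble (read) or `path` invisibly (write).
#' @export
write_ambient <- function(ambient, path) {
  out <- dplyr::mutate(ambient, t = fmt_utc(.data$t))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_ambient
#' @export
read_ambient <- function(path, gap_warn_s = 3600) {
  df <- read_channel_csv(path, c("t", "tamb"))
  df <- dplyr::mutate(df, t = parse_utc(.data$t))
  check_monotone(as.numeric(df$t), "ambient", path)
  d <- diff(as.numeric(df$t))
  gap_idx <- which(d > gap_warn_s)
  gaps <- tibble::tibble(from = df$t[gap_idx], to = df$t[gap_idx + 1L])
  attr(df, "gaps") <- gaps
  tibble::as_tibble(df)
}

#' Write / read an aggregated 5-s sensor trace
#'
#' @param trace A trace tibble as produced by [aggregate_trace()].
#' @param path CSV path.
#' @param chick_id,start_utc Sidecar metadata (taken from attributes when
#'   present).
#' @return The tibble (read, with `chick_id`/`start_utc` attributes) or
#'   `path` invisibly (write).
#' @export
write_trace5 <- function(trace, path,
                         chick_id = attr(trace, "chick_id"),
                         start_utc = attr(trace, "start_utc")) {
  write_channel_csv(trace, path, chick_id %||% "chick",
                    start_utc %||% parse_utc("1970-01-01T00:00:00Z"))
}

#' @rdname write_trace5
#' @export
read_trace5 <- function(path) {
  df <- read_channel_csv(path, c("t5", "odba5", "tbody5", "light5",
                                 "tamb5", "sun_elev", "n_valid"))
  meta <- read_sidecar(path)
  attr(df, "chick_id") <- meta$chick_id
  attr(df, "start_utc") <- parse_utc(meta$start_utc)
  tibble::as_tibble(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
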