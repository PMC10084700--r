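# Accelerometer autocalibration from static periods, after the
# iterative closest-point sphere-fitting idea of van Hees et al.:
# during true rest the measured vector should lie on the unit (1 g) sphere,
# so per-axis offsets and gains are re-estimated by regressing the raw
# static vectors on their closest points on the sphere.

#' Find static windows in a raw trace
#'
#' Non-overlapping windows of `win_s` seconds in which the per-axis rolling
#' standard deviation is below `sd_thresh` on all three axes. Their mean
#' acceleration vectors are the input to [autocalibrate()].
#'
#' @param raw A [raw_trace()] object.
#' @param win_s Window length in seconds (default 10 s).
#' @param sd_thresh Per-axis SD threshold in g (default 0.013 g, the van
#'   Hees convention).
#' @return Tibble with one row per static window: `start_s`, `end_s`,
#'   `mx`, `my`, `mz` (mean vector, g). Zero rows when none qualify.
#' @export
find_static_windows <- function(raw, win_s = 10, sd_thresh = 0.013) {
  fs <- raw$fs_accel
  n_per <- as.integer(round(win_s * fs))
  n <- nrow(raw$accel)
  n_win <- n %/% n_per
  if (n_win == 0) {
    return(tibble::tibble(start_s = numeric(), end_s = numeric(),
                          mx = numeric(), my = numeric(), mz = numeric()))
  }
  used <- seq_len(n_win * n_per)
  per_axis <- function(v) {
    m <- matrix(v[used], nrow = n_per)
    list(sd = col_sds(m), mean = colMeans(m))
  }
  ax <- per_axis(raw$accel$ax)
  ay <- per_axis(raw$accel$ay)
  az <- per_axis(raw$accel$az)
  ok <- ax$sd < sd_thresh & ay$sd < sd_thresh & az$sd < sd_thresh
  t0 <- raw$accel$t[seq(1L, n_win * n_per, by = n_per)]
  tibble::tibble(start_s = t0[ok], end_s = t0[ok] + win_s,
                 mx = ax$mean[ok], my = ay$mean[ok], mz = az$mean[ok])
}

# column SDs without an extra dependency
col_sds <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  sqrt(pmax(0, (colMeans(m * m) - mu^2) * n / (n - 1)))
}

#' Autocalibrate an accelerometer from static-window means
#'
#' Iteratively re-weighted least squares: each static mean vector is
#' projected onto the unit sphere and per-axis gain/offset are re-estimated
#' so the calibrated vectors `(raw - offset) / gain` approach unit norm.
#' Requires at least `min_windows` windows spanning at least 3 distinct
#' orientations (pairwise angle > 15 degrees); otherwise the identity
#' calibration is returned with `converged = FALSE` — the failure is
#' non-fatal because traces of highly active chicks may lack orientation
#' diversity, and the downstream high-pass filter removes static offsets
#' anyway.
#'
#' @param static_means Matrix or data frame with three columns (mean static
#'   vectors in g), e.g. columns `mx`, `my`, `mz` of
#'   [find_static_windows()] output.
#' @param min_windows Minimum number of static windows (default 10).
#' @param max_iter,tol IRLS iteration cap and convergence tolerance.
#' @return A list of class `calibration`: `offset` (3-vector, g), `gain`
#'   (3-vector), `n_static_windows`, `n_orientations`, `converged`.
#' @export
autocalibrate <- function(static_means, min_windows = 10,
                          max_iter = 200, tol = 1e-10) {
  identity_cal <- function(n, k) {
    structure(list(offset = c(0, 0, 0), gain = c(1, 1, 1),
                   n_static_windows = n, n_orientations = k,
                   converged = FALSE),
              class = "calibration")
  }
  m <- as.matrix(static_means)
  if (ncol(m) >= 5 && all(c("mx", "my", "mz") %in% colnames(m))) {
    m <- m[, c("mx", "my", "mz"), drop = FALSE]
  }
  if (ncol(m) != 3) abort("static_means must have three columns")
  n <- nrow(m)
  k <- if (n) count_orientations(m) else 0L
  if (n < min_windows || k < 3) return(identity_cal(n, k))

  offset <- c(0, 0, 0)
  gain <- c(1, 1, 1)
  for (it in seq_len(max_iter)) {
    cal <- sweep(sweep(m, 2, offset, "-"), 2, gain, "/")
    nrm <- sqrt(rowSums(cal^2))
    nrm[nrm < 1e-12] <- 1e-12
    target <- cal / nrm
    new_offset <- offset
    new_gain <- gain
    for (j in 1:3) {
      # raw_j ~ gain_j * target_j + offset_j
      fit <- stats::lm.fit(cbind(1, target[, j]), m[, j])
      new_offset[j] <- fit$coefficients[1]
      new_gain[j] <- fit$coefficients[2]
    }
    delta <- max(abs(new_offset - offset), abs(new_gain - gain))
    offset <- new_offset
    gain <- new_gain
    if (delta < tol) break
  }
  bad <- any(gain <= 0.5 | gain >= 2) || any(abs(offset) >= 0.5)
  if (bad) return(identity_cal(n, k))
  structure(list(offset = offset, gain = gain,
                 n_static_windows = n, n_orientations = k,
                 converged = TRUE),
            class = "calibration")
}

# greedy count of orientations pairwise more than 15 degrees apart
count_orientations <- function(m, min_angle_deg = 15) {
  nrm <- sqrt(rowSums(m^2))
  keep <- nrm > 1e-9
  u <- m[keep, , drop = FALSE] / nrm[keep]
  picked <- matrix(numeric(0), ncol = 3)
  cosmax <- cos(min_angle_deg * pi / 180)
  for (i in seq_len(nrow(u))) {
    if (nrow(picked) == 0 || all(picked %*% u[i, ] < cosmax)) {
      picked <- rbind(picked, u[i, ])
    }
  }
  nrow(picked)
}

#' Apply a calibration to a raw trace
#'
#' @param raw A [raw_trace()] object.
#' @param cal A `calibration` from [autocalibrate()].
#' @return The trace with `ax`, `ay`, `az` replaced by
#'   `(raw - offset) / gain`.
#' @export
apply_calibration <- function(raw, cal) {
  raw$accel$ax <- (raw$accel$ax - cal$offset[1]) / cal$gain[1]
  raw$accel$ay <- (raw$accel$ay - cal$offset[2]) / cal$gain[2]
  raw$accel$az <- (raw$accel$az - cal$offset[3]) / cal$gain[3]
  raw
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> offset (%.4f, %.4f, %.4f) g, gain (%.4f, %.4f, %.4f), %d static windows, %d orientations, converged: %s\n",
              x$offset[1], x$offset[2], x$offset[3],
              x$gain[1], x$gain[2], x$gain[3],
              x$n_static_windows, x$n_orientations, x$converged))
  invisible(x)
}
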