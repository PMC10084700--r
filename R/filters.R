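#' Moving median filter with a frequency-style cut-off
#'
#' The cut-off frequency `fc` is mapped to a centred moving-median window of
#' `w = round(fs / fc)` samples, forced odd (a window of duration `1/fc`
#' suppresses variation faster than `fc`). Edges are handled by window
#' truncation: near the series ends the median is taken over the available
#' part of the centred window, so no reflection or padding values are
#' invented. The 30-min edge trim of the pipeline removes these bins anyway.
#'
#' @param x Numeric series.
#' @param fc Cut-off frequency, Hz; must satisfy `fc < fs / 2`.
#' @param fs Sampling rate, Hz.
#' @return Filtered series, same length as `x`.
#' @export
#'
#' @examples
#' median_filter(c(1, 1, 9, 1, 1), fc = 5, fs = 25)  # spike removed
median_filter <- function(x, fc, fs) {
  if (fc >= fs / 2) abort("median filter cut-off must be below fs/2")
  w <- round(fs / fc)
  if (w %% 2 == 0) w <- w + 1L
  running_median(x, w)
}

# centred running median, odd window w, truncated at the edges
running_median <- function(x, w) {
  n <- length(x)
  h <- (w - 1L) / 2L
  if (n == 0) return(x)
  if (n <= w) {
    # whole series shorter than the window: every window is truncated
    return(vapply(seq_len(n), function(i) {
      median(x[max(1L, i - h):min(n, i + h)])
    }, numeric(1)))
  }
  out <- stats::runmed(x, w, endrule = "keep", algorithm = "Turlach")
  out <- as.numeric(out)
  for (i in seq_len(h)) {
    out[i] <- median(x[1L:(i + h)])
    out[n - i + 1L] <- median(x[(n - i + 1L - h):n])
  }
  out
}
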