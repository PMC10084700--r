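# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (O(n*w) loops, exhaustive enumeration) so they cannot
# share a defect with the implementation paths they check.

naive_running_median <- function(x, w) {
  n <- length(x)
  h <- (w - 1) / 2
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

naive_median_filter <- function(x, fc, fs) {
  w <- round(fs / fc)
  if (w %% 2 == 0) w <- w + 1
  naive_running_median(x, w)
}

naive_odba <- function(ax, ay, az, fs = 25) {
  dyn <- function(v) {
    d <- v - naive_median_filter(v, 0.2, fs)
    naive_median_filter(d, 2, fs)
  }
  abs(dyn(ax)) + abs(dyn(ay)) + abs(dyn(az))
}

# exhaustive most-probable-path search over all 2^T state sequences
viterbi_brute <- function(y, mu, sigma, trans, init) {
  T_ <- length(y)
  best <- -Inf
  best_path <- NULL
  for (code in 0:(2^T_ - 1)) {
    s <- as.integer(intToBits(code)[1:T_]) + 1L
    lp <- log(init[s[1]]) + dnorm(y[1], mu[s[1]], sigma[s[1]], log = TRUE)
    if (T_ > 1) {
      for (t in 2:T_) {
        lp <- lp + log(trans[s[t - 1], s[t]]) +
          dnorm(y[t], mu[s[t]], sigma[s[t]], log = TRUE)
      }
    }
    if (lp > best) {
      best <- lp
      best_path <- s
    }
  }
  list(path = best_path, logp = best)
}

# sample an observation sequence from a 2-state Gaussian HMM
sim_hmm_series <- function(n, mu, sigma, trans, init = c(0.5, 0.5)) {
  s <- integer(n)
  s[1] <- sample(1:2, 1, prob = init)
  for (t in 2:n) s[t] <- sample(1:2, 1, prob = trans[s[t - 1], ])
  list(states = s, y = rnorm(n, mu[s], sigma[s]))
}

random_unit_vectors <- function(n) {
  m <- matrix(rnorm(n * 3), ncol = 3)
  m / sqrt(rowSums(m^2))
}

# constant-gravity motionless raw trace
still_raw <- function(dur_s = 60, g = c(0, 0, 1), fs = 25) {
  n <- dur_s * fs
  raw_trace(
    accel = tibble::tibble(t = (seq_len(n) - 1) / fs,
                           ax = g[1], ay = g[2], az = g[3]),
    slow = tibble::tibble(t = seq_len(dur_s) - 1, tbody = 20, light = 100),
    start_utc = as.POSIXct("2019-06-01 00:00:00", tz = "UTC"),
    chick_id = "still")
}

# hand-built 5-s trace with attributes expected by the summary builders
make_trace <- function(t5, odba5 = 0.01, tbody5 = 30, light5 = 10,
                       tamb5 = 15, sun_elev = -20, chick_id = "chick",
                       start_utc = as.POSIXct("2019-06-01 00:00:00", tz = "UTC")) {
  tr <- tibble::tibble(t5 = t5,
                       odba5 = rep_len(odba5, length(t5)),
                       tbody5 = rep_len(tbody5, length(t5)),
                       light5 = rep_len(light5, length(t5)),
                       tamb5 = rep_len(tamb5, length(t5)),
                       sun_elev = rep_len(sun_elev, length(t5)),
                       n_valid = 125L)
  attr(tr, "chick_id") <- chick_id
  attr(tr, "start_utc") <- start_utc
  tr
}

make_bouts <- function(start_s, end_s, label, chick_id = "chick") {
  tibble::tibble(chick_id = chick_id, start_s = start_s, end_s = end_s,
                 label = label, provenance = "test")
}

# one shared medium-sized simulation, computed once per test run
shared_sim_env <- new.env()
shared_sim <- function() {
  if (is.null(shared_sim_env$sim)) {
    cfg <- sim_config("NL", duration_h = 6, seed = 42)
    shared_sim_env$sim <- simulate_chick(cfg, "NLShared")
    shared_sim_env$trace <- preprocess_chick(shared_sim_env$sim$raw,
                                             shared_sim_env$sim$ambient,
                                             shared_sim_env$sim$chick)
  }
  list(sim = shared_sim_env$sim, trace = shared_sim_env$trace)
}
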