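# Two-state segmentation of the 5-s ODBA series. The emission model is a
# univariate Gaussian on log(ODBA + eps): ODBA is right-skewed with
# near-zero values during brooding, so the log scale gives two roughly
# symmetric activity modes. Fitting is per chick; states are unsupervised
# and the one with the lower emission mean is labelled "nonactive".

#' Fit a two-state Gaussian HMM to a 5-s ODBA series
#'
#' Baum-Welch (EM) on `y = log(odba5 + eps)` with deterministic
#' initialisation: state means at the 20th and 80th percentiles of `y`,
#' both SDs at `sd(y)`, self-transition 0.95, uniform initial
#' probabilities. `seed` is used only for the fallback re-initialisation
#' after a degenerate fit (state occupancy below 1%).
#'
#' @param odba5 Numeric ODBA series (g), or a trace tibble with an
#'   `odba5` column.
#' @param seed Integer seed for the fallback re-initialisation.
#' @param config A [brood_config()] (supplies `log_odba_eps`, `hmm_tol`,
#'   `hmm_max_iter`).
#' @param min_bins Minimum series length (default 500 bins).
#' @return An object of class `brood_hmm`: `init_prob`, `trans`,
#'   `emis_mean`, `emis_sd` (state order: nonactive, active),
#'   `loglik_trace`, `n_iter`, `occupancy`, `eps`, `n_obs`.
#' @export
fit_two_state <- function(odba5, seed = 1, config = brood_config(),
                          min_bins = 500) {
  if (is.data.frame(odba5)) odba5 <- odba5$odba5
  if (length(odba5) < min_bins) {
    abort(sprintf("need at least %d bins to fit the HMM, got %d",
                  min_bins, length(odba5)))
  }
  if (any(odba5 < 0, na.rm = TRUE)) abort("negative ODBA values")
  eps <- config$log_odba_eps
  y <- log(odba5 + eps)
  if (!all(is.finite(y))) abort("non-finite log-ODBA values")
  if (sd(y) < 1e-10) abort("no two-state structure: constant ODBA series")

  init_default <- list(mu = unname(quantile(y, c(0.2, 0.8))),
                       sigma = rep(max(sd(y), 1e-6), 2))
  fit <- bw_run(y, init_default, config)
  if (min(fit$occupancy) < 0.01) {
    set.seed(seed)
    init_alt <- list(mu = unname(quantile(y, c(0.1, 0.9))) +
                       rnorm(2, 0, 0.1 * sd(y)),
                     sigma = rep(max(sd(y), 1e-6), 2))
    fit <- bw_run(y, init_alt, config)
    if (min(fit$occupancy) < 0.01) {
      abort("no two-state structure: degenerate fit from both initialisations")
    }
  }
  # canonical state order: lower emission mean first ("nonactive")
  ord <- order(fit$mu)
  structure(list(init_prob = fit$init[ord],
                 trans = fit$trans[ord, ord, drop = FALSE],
                 emis_mean = fit$mu[ord],
                 emis_sd = fit$sigma[ord],
                 loglik_trace = fit$loglik_trace,
                 n_iter = fit$n_iter,
                 occupancy = fit$occupancy[ord],
                 eps = eps,
                 states = c("nonactive", "active"),
                 n_obs = length(y)),
            class = "brood_hmm")
}

bw_run <- function(y, init, config) {
  mu <- init$mu
  sigma <- init$sigma
  trans <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2, byrow = TRUE)
  p0 <- c(0.5, 0.5)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(config$hmm_max_iter)) {
    e <- fb_estep(y, mu, sigma, trans, p0)
    ll_trace <- c(ll_trace, e$loglik)
    gamma <- e$gamma
    occ <- colSums(gamma)
    p0 <- pmax(gamma[1, ], 1e-12)
    p0 <- p0 / sum(p0)
    trans <- e$xi_sum / pmax(rowSums(e$xi_sum), 1e-300)
    trans <- pmax(trans, 1e-12)
    trans <- trans / rowSums(trans)
    mu <- colSums(gamma * y) / pmax(occ, 1e-300)
    sigma <- sqrt(colSums(gamma * (outer(y, mu, "-"))^2) / pmax(occ, 1e-300))
    sigma <- pmax(sigma, 1e-6)
    if (is.finite(ll_old) && e$loglik - ll_old < config$hmm_tol) break
    ll_old <- e$loglik
  }
  list(mu = mu, sigma = sigma, trans = trans, init = p0,
       loglik_trace = ll_trace, n_iter = length(ll_trace),
       occupancy = colMeans(gamma))
}

#' Viterbi decoding of a 5-s ODBA series
#'
#' Globally most probable state sequence under the fitted parameters;
#' ties are broken deterministically toward the first (nonactive) state.
#'
#' @param params A `brood_hmm` from [fit_two_state()].
#' @param odba5 Numeric ODBA series (g) or a trace tibble with `odba5`
#'   (and then `t5` is carried through).
#' @param t5 Optional bin start times; defaults to a 5-s grid.
#' @return Tibble `t5`, `state` (factor nonactive/active).
#' @export
viterbi_decode <- function(params, odba5, t5 = NULL) {
  if (is.data.frame(odba5)) {
    if (is.null(t5)) t5 <- odba5$t5
    odba5 <- odba5$odba5
  }
  if (!inherits(params, "brood_hmm")) abort("params must be a brood_hmm")
  if (length(odba5) == 0) abort("empty ODBA series")
  if (!is.null(t5) && length(t5) != length(odba5)) {
    abort("t5 and odba5 have different lengths")
  }
  y <- log(odba5 + params$eps)
  idx <- viterbi_path(y, params$emis_mean, params$emis_sd,
                      params$trans, params$init_prob)
  if (is.null(t5)) t5 <- (seq_along(odba5) - 1) * 5
  tibble::tibble(t5 = t5,
                 state = factor(params$states[idx], levels = params$states))
}

#' Convert a decoded state path to candidate bouts
#'
#' Maximal constant-state runs become intervals `[run start, run end +
#' bin_s)`. Runs of "nonactive" become candidate brooding bouts; "active"
#' runs are kept so the intervals partition the trace. Non-contiguous bins
#' (gaps in `t5`) split runs.
#'
#' @param path Tibble `t5`, `state` from [viterbi_decode()].
#' @param bin_s Bin width, s.
#' @param chick_id Identifier copied into the bout table.
#' @return A bout tibble (`chick_id`, `start_s`, `end_s`, `label`,
#'   `provenance`); candidate brooding bouts carry label `"brooding"`.
#' @export
states_to_bouts <- function(path, bin_s = 5, chick_id = "chick") {
  if (nrow(path) == 0) {
    return(tibble::tibble(chick_id = character(), start_s = numeric(),
                          end_s = numeric(), label = character(),
                          provenance = character()))
  }
  st <- as.character(path$state)
  contig <- c(TRUE, diff(path$t5) <= bin_s + 1e-9)
  run_id <- cumsum(c(TRUE, st[-1] != st[-length(st)]) | !contig)
  runs <- tibble::tibble(t5 = path$t5, st = st, run = run_id) |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(start_s = min(.data$t5), end_s = max(.data$t5) + bin_s,
                     label = .data$st[1], .groups = "drop")
  tibble::tibble(chick_id = chick_id,
                 start_s = runs$start_s,
                 end_s = runs$end_s,
                 label = ifelse(runs$label == "nonactive", "brooding", "active"),
                 provenance = "hmm")
}

#' @export
print.brood_hmm <- function(x, ...) {
  cat(sprintf("<brood_hmm> 2 states on log(ODBA + %g), %d bins, %d EM iterations, loglik %.2f\n",
              x$eps, x$n_obs, x$n_iter,
              x$loglik_trace[length(x$loglik_trace)]))
  cat(sprintf("  nonactive: mean %.3f sd %.3f (occupancy %.2f); active: mean %.3f sd %.3f (occupancy %.2f)\n",
              x$emis_mean[1], x$emis_sd[1], x$occupancy[1],
              x$emis_mean[2], x$emis_sd[2], x$occupancy[2]))
  invisible(x)
}

#' Tidy a fitted two-state HMM
#'
#' @param x A `brood_hmm`.
#' @param ... Unused.
#' @return One row per state: emission mean and SD on the log-ODBA scale,
#'   stationary occupancy, self-transition probability and initial
#'   probability.
#' @method tidy brood_hmm
#' @export
tidy.brood_hmm <- function(x, ...) {
  tibble::tibble(state = x$states,
                 emis_mean = x$emis_mean,
                 emis_sd = x$emis_sd,
                 occupancy = x$occupancy,
                 self_trans = diag(x$trans),
                 init_prob = x$init_prob)
}

#' Glance at a fitted two-state HMM
#'
#' @param x A `brood_hmm`.
#' @param ... Unused.
#' @return One-row tibble: final log-likelihood, iteration count, number
#'   of observations and whether EM stopped before the iteration cap.
#' @method glance brood_hmm
#' @export
glance.brood_hmm <- function(x, ...) {
  tibble::tibble(loglik = x$loglik_trace[length(x$loglik_trace)],
                 n_iter = x$n_iter,
                 n_obs = x$n_obs,
                 converged = x$n_iter < brood_config()$hmm_max_iter)
}
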