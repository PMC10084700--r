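# Scoring of pipeline output against simulator ground truth, on the 5-s
# analysis grid (detection cannot be finer). Truth states are downsampled
# by majority within each bin, ties counting as brooding (conservative
# for recall).

# per-bin brooding coverage (s) of a set of intervals, on the trace grid
bin_coverage <- function(t5, bin_s, start_s, end_s) {
  cov <- numeric(length(t5))
  if (!length(start_s)) return(cov)
  t0 <- t5[1]
  for (k in seq_along(start_s)) {
    lo <- max(start_s[k], t0)
    hi <- min(end_s[k], t5[length(t5)] + bin_s)
    if (hi <= lo) next
    i1 <- findInterval(lo + 1e-9, t5)
    i2 <- findInterval(hi - 1e-9, t5)
    for (i in max(i1, 1):i2) {
      cov[i] <- cov[i] + max(0, min(hi, t5[i] + bin_s) - max(lo, t5[i]))
    }
  }
  cov
}

# majority-brooding flag of the truth per trace bin (ties -> brooding)
truth_bin_flags <- function(truth, t5, bin_s = 5) {
  n_s <- length(truth$states)
  if (max(t5) + bin_s > n_s + 1e-9) {
    abort("timeline mismatch: trace extends beyond the simulated states")
  }
  brood <- as.integer(truth$states == "brooding")
  cs <- c(0, cumsum(brood))
  i0 <- pmax(1, round(t5) + 1)
  i1 <- pmin(n_s, round(t5) + bin_s)
  n_brood <- cs[i1 + 1] - cs[i0]
  n_brood * 2 >= (i1 - i0 + 1)
}

#' Per-bin confusion counts against simulator truth
#'
#' Binary brooding-vs-not comparison on the trace's 5-s bins (already
#' edge-trimmed); a bin counts as predicted brooding when brooding
#' intervals cover more than half of it.
#'
#' @param pred Finalised bout tibble.
#' @param truth A `sim_truth`.
#' @param trace Trimmed 5-s trace tibble defining the scored bins.
#' @param bin_s Bin width, s.
#' @return One-row tibble: `tp`, `fp`, `fn`, `tn`, `accuracy`,
#'   `balanced_accuracy`, `precision`, `recall`, `specificity`.
#' @export
sample_confusion <- function(pred, truth, trace, bin_s = 5) {
  bb <- pred[pred$label == "brooding", ]
  cov <- bin_coverage(trace$t5, bin_s, bb$start_s, bb$end_s)
  p <- cov > bin_s / 2
  a <- truth_bin_flags(truth, trace$t5, bin_s)
  tp <- sum(p & a); fp <- sum(p & !a); fn <- sum(!p & a); tn <- sum(!p & !a)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    accuracy = (tp + tn) / max(1, tp + tn + fp + fn),
    balanced_accuracy = mean(c(sens, spec)),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = sens,
    specificity = spec)
}

#' Bout-level precision, recall and F1
#'
#' A predicted brooding bout matches a true one when their intersection
#' over union is at least `min_overlap`; matching is one-to-one, greedy by
#' descending overlap.
#'
#' @param pred Finalised bout tibble (brooding rows used).
#' @param truth A `sim_truth` or a bout tibble of true brooding intervals.
#' @param min_overlap Minimum intersection/union for a match.
#' @return A list: `precision`, `recall`, `f1`, `n_pred`, `n_truth`,
#'   `matches` (tibble `pred_start`, `pred_end`, `truth_start`,
#'   `truth_end`, `iou`).
#' @export
bout_f1 <- function(pred, truth, min_overlap = 0.5) {
  pb <- pred[pred$label == "brooding", ]
  tb <- if (inherits(truth, "sim_truth")) truth_bouts(truth) else
    truth[truth$label == "brooding", ]
  np <- nrow(pb); nt <- nrow(tb)
  empty <- tibble::tibble(pred_start = numeric(), pred_end = numeric(),
                          truth_start = numeric(), truth_end = numeric(),
                          iou = numeric())
  if (np == 0 || nt == 0) {
    return(list(precision = if (np == 0) NA_real_ else 0,
                recall = if (nt == 0) NA_real_ else 0,
                f1 = 0, n_pred = np, n_truth = nt, matches = empty))
  }
  inter <- outer(seq_len(np), seq_len(nt), function(i, j) {
    pmax(0, pmin(pb$end_s[i], tb$end_s[j]) - pmax(pb$start_s[i], tb$start_s[j]))
  })
  uni <- outer(seq_len(np), seq_len(nt), function(i, j) {
    pmax(pb$end_s[i], tb$end_s[j]) - pmin(pb$start_s[i], tb$start_s[j])
  })
  iou <- inter / uni
  cand <- which(iou >= min_overlap, arr.ind = TRUE)
  matches <- empty
  if (nrow(cand)) {
    ord <- order(iou[cand], decreasing = TRUE)
    used_p <- logical(np); used_t <- logical(nt)
    for (k in ord) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (used_p[i] || used_t[j]) next
      used_p[i] <- TRUE; used_t[j] <- TRUE
      matches <- dplyr::bind_rows(matches, tibble::tibble(
        pred_start = pb$start_s[i], pred_end = pb$end_s[i],
        truth_start = tb$start_s[j], truth_end = tb$end_s[j],
        iou = iou[i, j]))
    }
  }
  m <- nrow(matches)
  precision <- m / np
  recall <- m / nt
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       n_pred = np, n_truth = nt, matches = matches)
}

#' Boundary errors of matched bouts
#'
#' @param matches Match tibble from [bout_f1()].
#' @return A list: `median_start_error_s`, `median_end_error_s`,
#'   `n_matched`, `available`.
#' @export
boundary_error <- function(matches) {
  if (nrow(matches) == 0) {
    return(list(median_start_error_s = NA_real_,
                median_end_error_s = NA_real_,
                n_matched = 0L, available = FALSE))
  }
  list(median_start_error_s = median(abs(matches$pred_start - matches$truth_start)),
       median_end_error_s = median(abs(matches$pred_end - matches$truth_end)),
       n_matched = nrow(matches), available = TRUE)
}

#' Full evaluation of one chick's detection
#'
#' @param pred Finalised bout tibble.
#' @param truth A `sim_truth`.
#' @param trace Trimmed 5-s trace tibble.
#' @param min_overlap Bout-match threshold (intersection over union).
#' @return One-row tibble: confusion-derived rates, bout-level
#'   precision/recall/F1, median boundary errors and the signed rate error
#'   (estimated minus true brooding proportion over the scored bins).
#' @export
evaluate_detection <- function(pred, truth, trace, min_overlap = 0.5) {
  conf <- sample_confusion(pred, truth, trace)
  f <- bout_f1(pred, truth, min_overlap)
  be <- boundary_error(f$matches)
  est_prop <- (conf$tp + conf$fp) / max(1, conf$tp + conf$fp + conf$fn + conf$tn)
  true_prop <- (conf$tp + conf$fn) / max(1, conf$tp + conf$fp + conf$fn + conf$tn)
  tibble::tibble(
    chick_id = pred$chick_id[1] %||% NA_character_,
    accuracy = conf$accuracy,
    balanced_accuracy = conf$balanced_accuracy,
    precision = conf$precision,
    recall = conf$recall,
    specificity = conf$specificity,
    bout_precision = f$precision,
    bout_recall = f$recall,
    bout_f1 = f$f1,
    median_start_error_s = be$median_start_error_s,
    median_end_error_s = be$median_end_error_s,
    rate_error = est_prop - true_prop)
}
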