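# Rule chain turning candidate non-active bouts into brooding bouts:
# 50 lx daylight rule -> per-chick temperature-difference statistics ->
# boundary adjustment at warming/cooling onsets -> pruning of bouts and
# gaps up to 20 s. run_postprocess() iterates the chain to a fixed point
# so the result is idempotent.

bins_in <- function(trace, start_s, end_s) {
  which(trace$t5 >= start_s - 1e-9 & trace$t5 < end_s - 1e-9)
}

#' Daylight 50 lx rule
#'
#' A candidate brooding bout that overlaps daylight (any bin with sun
#' elevation at or above -6 degrees) is kept only if at least
#' `min_dark_bins` of its 5-s bins have a mean light level below
#' `lx_thresh`; otherwise it is relabelled `other_inactive` (low-activity
#' rest in plant shade or open ground, not brooding). Bouts lying entirely
#' in night are exempt: light is uninformative there.
#'
#' @param cands Bout tibble (partition with candidate `brooding` bouts).
#' @param trace 5-s trace tibble with `light5` and `sun_elev`.
#' @param lx_thresh Light threshold, lx.
#' @param night_elev_deg Sun elevation defining night, degrees.
#' @param min_dark_bins Bins below threshold required in a daylight bout.
#' @return The bout tibble with demoted bouts relabelled.
#' @export
apply_light_rule <- function(cands, trace, lx_thresh = 50,
                             night_elev_deg = -6, min_dark_bins = 1) {
  if (!"light5" %in% names(trace) || all(is.na(trace$light5))) {
    abort("light channel missing: the daylight rule cannot be evaluated")
  }
  if (!"sun_elev" %in% names(trace) || all(is.na(trace$sun_elev))) {
    abort("sun elevation missing: the daylight rule cannot be evaluated")
  }
  out <- cands
  for (i in which(cands$label == "brooding")) {
    idx <- bins_in(trace, cands$start_s[i], cands$end_s[i])
    if (!length(idx)) next
    in_daylight <- any(trace$sun_elev[idx] >= night_elev_deg, na.rm = TRUE)
    if (!in_daylight) next
    dark <- sum(trace$light5[idx] < lx_thresh, na.rm = TRUE)
    if (dark < min_dark_bins) {
      out$label[i] <- "other_inactive"
      if ("provenance" %in% names(out)) out$provenance[i] <- "light_rule"
    }
  }
  out
}

#' Per-chick temperature-difference statistics
#'
#' First differences of the 5-s on-body temperature (degC per bin,
#' consecutive bins only) pooled within the bins covered by brooding and by
#' active intervals; the two medians drive the boundary adjustment. With
#' fewer than `min_state_bins` difference values in either state the
#' statistics are marked unavailable and boundary adjustment is skipped
#' for that chick.
#'
#' @param cands Bout tibble after the light rule.
#' @param trace 5-s trace tibble with `tbody5`.
#' @param min_state_bins Minimum difference values per state.
#' @return A list: `chick_id`, `median_diff_brooding`,
#'   `median_diff_active`, `n_brooding`, `n_active`, `available`.
#' @export
temp_diff_stats <- function(cands, trace, min_state_bins = 10) {
  d <- c(NA_real_, diff(trace$tbody5))
  contig <- c(FALSE, diff(trace$t5) <= min(diff(trace$t5)) + 1e-9)
  d[!contig] <- NA_real_
  lab <- rep(NA_character_, nrow(trace))
  for (i in seq_len(nrow(cands))) {
    idx <- bins_in(trace, cands$start_s[i], cands$end_s[i])
    lab[idx] <- cands$label[i]
  }
  db <- d[!is.na(d) & !is.na(lab) & lab == "brooding"]
  da <- d[!is.na(d) & !is.na(lab) & lab == "active"]
  ok <- length(db) >= min_state_bins && length(da) >= min_state_bins
  list(chick_id = cands$chick_id[1] %||% NA_character_,
       median_diff_brooding = if (ok) median(db) else NA_real_,
       median_diff_active = if (ok) median(da) else NA_real_,
       n_brooding = length(db), n_active = length(da),
       available = ok)
}

#' Temperature-guided boundary adjustment
#'
#' Chicks often fall still shortly before parental contact and resume
#' activity around departure, so the activity-defined bout edges can be
#' off by a few bins. For each brooding bout the start is moved to the
#' earliest bin — inside a search window from the midpoint of the
#' preceding interval (capped at `search_s` before the bout) to the bout
#' midpoint — whose temperature difference exceeds
#' `max(median_diff_brooding, min_adjust_diff)` (warming onset). The
#' following break's start (the bout end) is moved to the first bin after
#' the bout, up to the midpoint of the following interval, whose
#' difference crosses the active-state median: below
#' `min(median_diff_active, -min_adjust_diff)` under the default
#' `"falls_below"` rule (cooling onset), or above the mirrored threshold
#' under `"rises_above"`. The magnitude floor `min_adjust_diff` keeps
#' sensor noise and diel drift (both well below 0.05 degC per bin) from
#' triggering spurious moves. Neighbouring intervals absorb the moved
#' time, so the partition stays well formed; without a qualifying bin a
#' boundary is left unchanged.
#'
#' @param cands Bout tibble (partition) after the light rule.
#' @param trace 5-s trace tibble with `tbody5`.
#' @param stats Output of [temp_diff_stats()].
#' @param config A [brood_config()] (`search_s`, `min_adjust_diff`,
#'   `break_rule`).
#' @return The adjusted bout tibble.
#' @export
adjust_boundaries <- function(cands, trace, stats, config = brood_config()) {
  if (!isTRUE(stats$available)) return(cands)
  if (nrow(cands) == 0) return(cands)
  out <- cands[order(cands$start_s), ]
  d <- c(NA_real_, diff(trace$tbody5))
  contig <- c(FALSE, diff(trace$t5) <= min(diff(trace$t5)) + 1e-9)
  d[!contig] <- NA_real_
  thr_start <- max(stats$median_diff_brooding, config$min_adjust_diff)
  thr_end <- if (identical(config$break_rule, "rises_above")) {
    max(stats$median_diff_active, config$min_adjust_diff)
  } else {
    min(stats$median_diff_active, -config$min_adjust_diff)
  }
  n <- nrow(out)
  for (i in which(out$label == "brooding")) {
    s <- out$start_s[i]; e <- out$end_s[i]
    mid_bout <- (s + e) / 2
    # start: earliest warming-onset bin in the search window
    win_lo <- if (i > 1) max((out$start_s[i - 1] + out$end_s[i - 1]) / 2,
                             s - config$search_s) else s
    idx <- which(trace$t5 >= win_lo - 1e-9 & trace$t5 < mid_bout - 1e-9 &
                   !is.na(d) & d > thr_start)
    if (length(idx)) {
      new_s <- trace$t5[idx[1]]
      lo_clip <- if (i > 1) out$start_s[i - 1] + 1e-6 else -Inf
      new_s <- max(new_s, lo_clip)
      if (new_s < e && abs(new_s - s) > 1e-9) {
        out$start_s[i] <- new_s
        if (i > 1) out$end_s[i - 1] <- new_s
        if ("provenance" %in% names(out)) out$provenance[i] <- "boundary"
      }
    }
    # end: first crossing after the bout, up to the next interval's midpoint
    s <- out$start_s[i]; e <- out$end_s[i]
    if (i < n) {
      win_hi <- (out$start_s[i + 1] + out$end_s[i + 1]) / 2
      cross <- if (identical(config$break_rule, "rises_above")) {
        !is.na(d) & d > thr_end
      } else {
        !is.na(d) & d < thr_end
      }
      jdx <- which(trace$t5 >= e - 1e-9 & trace$t5 < win_hi - 1e-9 & cross)
      if (length(jdx)) {
        new_e <- trace$t5[jdx[1]]
        new_e <- min(new_e, out$end_s[i + 1] - 1e-6)
        if (new_e > s && abs(new_e - e) > 1e-9) {
          out$end_s[i] <- new_e
          out$start_s[i + 1] <- new_e
          if ("provenance" %in% names(out)) out$provenance[i] <- "boundary"
        }
      }
    }
  }
  out[out$end_s - out$start_s > 1e-9, ]
}

#' Prune short brooding bouts and short breaks
#'
#' Breaks in brooding of up to `min_s` seconds (inclusive) are merged into
#' the surrounding bout, then brooding bouts of up to `min_s` are removed
#' (relabelled to the flanking label); both steps repeat to a fixed point,
#' merges first. Such short events are usually position shifts during an
#' uninterrupted bout, not real brooding transitions.
#'
#' @param bouts Bout tibble (partition).
#' @param min_s Duration threshold, s (bouts/gaps `<= min_s` are pruned).
#' @return The pruned bout tibble.
#' @export
drop_short <- function(bouts, min_s = 20) {
  if (nrow(bouts) == 0) return(bouts)
  b <- bouts[order(bouts$start_s), ]
  for (pass in seq_len(100)) {
    before <- b
    # merge short gaps between consecutive brooding bouts
    bi <- which(b$label == "brooding")
    if (length(bi) >= 2) {
      for (k in seq_len(length(bi) - 1)) {
        i1 <- bi[k]; i2 <- bi[k + 1]
        gap <- b$start_s[i2] - b$end_s[i1]
        if (i2 > i1 + 1 && gap > 1e-9 && gap <= min_s + 1e-9 &&
            abs(gap - sum(b$end_s[(i1 + 1):(i2 - 1)] -
                            b$start_s[(i1 + 1):(i2 - 1)])) < 1e-6) {
          b$label[(i1 + 1):(i2 - 1)] <- "brooding"
          if ("provenance" %in% names(b)) b$provenance[(i1 + 1):(i2 - 1)] <- "merge_gap"
        }
      }
    }
    b <- coalesce_bouts(b)
    # drop short brooding bouts
    short <- which(b$label == "brooding" &
                     b$end_s - b$start_s <= min_s + 1e-9)
    if (length(short)) {
      for (i in short) {
        new_lab <- if (i > 1) b$label[i - 1]
          else if (i < nrow(b)) b$label[i + 1] else "active"
        b$label[i] <- new_lab
        if ("provenance" %in% names(b)) b$provenance[i] <- "drop_short"
      }
      b <- coalesce_bouts(b)
    }
    if (nrow(b) == nrow(before) &&
        all(b$label == before$label) &&
        all(abs(b$start_s - before$start_s) < 1e-9)) break
  }
  b
}

# merge touching intervals with identical labels
coalesce_bouts <- function(b) {
  if (nrow(b) <= 1) return(b)
  b <- b[order(b$start_s), ]
  same <- b$label[-1] == b$label[-nrow(b)] &
    abs(b$start_s[-1] - b$end_s[-nrow(b)]) < 1e-6
  grp <- cumsum(c(TRUE, !same))
  b |>
    dplyr::mutate(.grp = grp) |>
    dplyr::group_by(.data$.grp) |>
    dplyr::summarise(chick_id = .data$chick_id[1],
                     start_s = min(.data$start_s),
                     end_s = max(.data$end_s),
                     label = .data$label[1],
                     provenance = if ("provenance" %in% names(b))
                       .data$provenance[dplyr::n()] else NA_character_,
                     .groups = "drop") |>
    dplyr::select(!".grp")
}

#' Feathered-chick exclusion flag
#'
#' Once growing feathers cover the light sensor (around 65 g body mass)
#' daytime brooding becomes undetectable; such chicks are flagged and
#' excluded from summaries.
#'
#' @param chick One-row chick tibble with `mass_start`, `mass_end`.
#' @param mass_thresh Mass threshold, g (strict: 64.9 g is not flagged).
#' @return Logical flag.
#' @export
flag_feathered <- function(chick, mass_thresh = 65) {
  isTRUE(chick$mass_start[1] >= mass_thresh) ||
    isTRUE(chick$mass_end[1] >= mass_thresh)
}

#' Run the full post-processing rule chain
#'
#' Light rule, temperature-difference statistics, boundary adjustment and
#' short-bout pruning, iterated to a fixed point (so re-running the chain
#' on its own output changes nothing). When the temperature statistics are
#' unavailable the boundary adjustment is skipped with a warning.
#'
#' @param cands Candidate bout partition from [states_to_bouts()].
#' @param trace 5-s trace tibble.
#' @param chick Optional one-row chick tibble; used for the feathered
#'   flag, attached as attribute `"feathered"`.
#' @param config A [brood_config()].
#' @return Finalised bout tibble; no brooding bout or within-brooding gap
#'   of 20 s or less remains.
#' @export
run_postprocess <- function(cands, trace, chick = NULL,
                            config = brood_config()) {
  b <- cands[order(cands$start_s), ]
  warned <- FALSE
  for (pass in seq_len(20)) {
    before <- b
    b <- apply_light_rule(b, trace, config$lx_thresh,
                          config$night_elev_deg, config$min_dark_bins)
    st <- temp_diff_stats(b, trace, config$min_state_bins)
    if (st$available) {
      b <- adjust_boundaries(b, trace, st, config)
    } else if (!warned && pass == 1) {
      warn(sprintf("temperature-difference stats unavailable (%d brooding / %d active diffs): boundary adjustment skipped",
                   st$n_brooding, st$n_active))
      warned <- TRUE
    }
    b <- drop_short(b, config$min_bout_s)
    if (nrow(b) == nrow(before) &&
        all(b$label == before$label) &&
        all(abs(b$start_s - before$start_s) < 1e-9) &&
        all(abs(b$end_s - before$end_s) < 1e-9)) break
  }
  validate_bouts(b)
  if (!is.null(chick)) {
    attr(b, "feathered") <- flag_feathered(chick, config$mass_thresh_g)
  }
  b
}

#' Detect brooding bouts in a preprocessed trace
#'
#' Convenience wrapper: per-chick two-state HMM fit, Viterbi decoding,
#' candidate extraction and the post-processing rule chain.
#'
#' @param trace A trimmed 5-s trace tibble from [preprocess_chick()].
#' @param chick Optional one-row chick tibble.
#' @param config A [brood_config()].
#' @param seed Seed for the HMM fallback re-initialisation.
#' @return Finalised bout tibble; the fitted `brood_hmm` is attached as
#'   attribute `"hmm"`.
#' @export
detect_brooding <- function(trace, chick = NULL, config = brood_config(),
                            seed = 1) {
  fit <- fit_two_state(trace$odba5, seed = seed, config = config)
  path <- viterbi_decode(fit, trace)
  cands <- states_to_bouts(path, bin_s = config$bin_s,
                           chick_id = attr(trace, "chick_id") %||%
                             (chick$chick_id[1] %||% "chick"))
  out <- run_postprocess(cands, trace, chick, config)
  attr(out, "hmm") <- fit
  out
}

#' Quality-control report for detected bouts
#'
#' Lists brooding bouts whose temperature pattern is inconsistent with
#' heating by a parent (bouts longer than the stabilisation window whose
#' post-stabilisation median on-body temperature does not exceed the
#' ambient mean) for human review — the automated rules never silently
#' "correct" them.
#'
#' @param bouts Finalised bout tibble.
#' @param trace 5-s trace tibble.
#' @param config A [brood_config()].
#' @param path Optional path for a plain-text report.
#' @return Tibble of flagged bouts (invisibly when `path` is given).
#' @export
qc_report <- function(bouts, trace, config = brood_config(), path = NULL) {
  rows <- list()
  for (i in which(bouts$label == "brooding")) {
    dur <- bouts$end_s[i] - bouts$start_s[i]
    if (dur <= config$min_eff_bout_s) next
    idx <- bins_in(trace, bouts$start_s[i] + config$eff_exclude_s,
                   bouts$end_s[i])
    if (!length(idx)) next
    med_tb <- median(trace$tbody5[idx], na.rm = TRUE)
    mean_ta <- mean(trace$tamb5[idx], na.rm = TRUE)
    if (is.finite(med_tb) && is.finite(mean_ta) && med_tb <= mean_ta + 0.5) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        chick_id = bouts$chick_id[i], start_s = bouts$start_s[i],
        end_s = bouts$end_s[i], median_tbody = med_tb,
        mean_tamb = mean_ta,
        reason = "no warming above ambient after stabilisation")
    }
  }
  flagged <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(chick_id = character(), start_s = numeric(),
                   end_s = numeric(), median_tbody = numeric(),
                   mean_tamb = numeric(), reason = character())
  if (!is.null(path)) {
    lines <- c(sprintf("brooding QC report: %d of %d brooding bouts flagged",
                       nrow(flagged), sum(bouts$label == "brooding")),
               sprintf("%s %.0f-%.0f s: median tbody %.1f C vs ambient %.1f C (%s)",
                       flagged$chick_id, flagged$start_s, flagged$end_s,
                       flagged$median_tbody, flagged$mean_tamb, flagged$reason))
    writeLines(lines, path)
    return(invisible(flagged))
  }
  flagged
}
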