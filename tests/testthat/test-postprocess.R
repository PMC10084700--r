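test_that("daylight bouts without a dark bin are demoted, night bouts exempt", {
  t5 <- seq(0, 595, 5)
  # day: high sun; light 300 lx everywhere
  tr_day <- make_trace(t5, light5 = 300, sun_elev = 40)
  cands <- make_bouts(c(0, 100, 400), c(100, 400, 600),
                      c("active", "brooding", "active"))
  out <- apply_light_rule(cands, tr_day)
  expect_equal(out$label[2], "other_inactive")

  # night: same light, label unchanged
  tr_night <- make_trace(t5, light5 = 300, sun_elev = -20)
  expect_equal(apply_light_rule(cands, tr_night)$label[2], "brooding")

  # one dark bin among very bright bins retains the bout
  tr_mix <- make_trace(t5, light5 = 5000, sun_elev = 40)
  tr_mix$light5[tr_mix$t5 == 200] <- 10
  expect_equal(apply_light_rule(cands, tr_mix)$label[2], "brooding")

  tr_na <- make_trace(t5, sun_elev = 40)
  tr_na$light5 <- NA_real_
  expect_error(apply_light_rule(cands, tr_na), "light channel")
})

test_that("light rule never increases daylight brooding time", {
  s <- shared_sim()
  fit <- fit_two_state(s$trace, seed = 1)
  cands <- states_to_bouts(viterbi_decode(fit, s$trace),
                           chick_id = "NLShared")
  out <- apply_light_rule(cands, s$trace)
  day_time <- function(b) {
    bb <- b[b$label == "brooding", ]
    if (!nrow(bb)) return(0)
    sum(vapply(seq_len(nrow(bb)), function(i) {
      idx <- s$trace$t5 >= bb$start_s[i] & s$trace$t5 < bb$end_s[i]
      5 * sum(idx & s$trace$sun_elev >= -6)
    }, numeric(1)))
  }
  expect_lte(day_time(out), day_time(cands))
})

test_that("temperature-difference medians match their construction", {
  t5 <- seq(0, 495, 5)
  tb <- numeric(length(t5))
  # warming 0.2 degC/bin inside the bout, cooling -0.1 outside
  bout <- t5 >= 200 & t5 < 400
  tb[1] <- 30
  for (i in 2:length(t5)) tb[i] <- tb[i - 1] + if (bout[i]) 0.2 else -0.1
  tr <- make_trace(t5, tbody5 = tb)
  cands <- make_bouts(c(0, 200, 400), c(200, 400, 500),
                      c("active", "brooding", "active"))
  st <- temp_diff_stats(cands, tr)
  expect_true(st$available)
  expect_equal(st$median_diff_brooding, 0.2, tolerance = 1e-9)
  expect_equal(st$median_diff_active, -0.1, tolerance = 1e-9)

  # constant temperature gives zero medians
  st0 <- temp_diff_stats(cands, make_trace(t5, tbody5 = 35))
  expect_equal(st0$median_diff_brooding, 0)
  expect_equal(st0$median_diff_active, 0)

  # insufficient bins -> unavailable
  small <- make_bouts(c(0, 20), c(20, 40), c("active", "brooding"))
  st_na <- temp_diff_stats(small, make_trace(seq(0, 35, 5), tbody5 = 35))
  expect_false(st_na$available)
})

test_that("pooled medians match a brute-force group-by on a simulated trace", {
  s <- shared_sim()
  fit <- fit_two_state(s$trace, seed = 1)
  cands <- states_to_bouts(viterbi_decode(fit, s$trace), chick_id = "NLShared")
  st <- temp_diff_stats(cands, s$trace)
  # brute force: label each bin, pool consecutive differences
  lab <- rep(NA_character_, nrow(s$trace))
  for (i in seq_len(nrow(cands))) {
    lab[s$trace$t5 >= cands$start_s[i] & s$trace$t5 < cands$end_s[i]] <- cands$label[i]
  }
  d <- c(NA, diff(s$trace$tbody5))
  expect_equal(st$median_diff_brooding,
               median(d[which(lab == "brooding")], na.rm = TRUE),
               tolerance = 1e-9)
  expect_equal(st$median_diff_active,
               median(d[which(lab == "active")], na.rm = TRUE),
               tolerance = 1e-9)
})

test_that("bout starts move to the warming onset and not further", {
  t5 <- seq(0, 995, 5)
  tb <- rep(30, length(t5))
  # activity ceases at 400 s, contact (warming) at 460 s, bout mid 650 s
  warm <- t5 >= 460 & t5 < 900
  for (i in 2:length(t5)) tb[i] <- tb[i - 1] + if (warm[i]) 0.5 else 0
  tr <- make_trace(t5, tbody5 = pmin(tb, 38))
  cands <- make_bouts(c(0, 400, 900), c(400, 900, 1000),
                      c("active", "brooding", "active"))
  st <- list(median_diff_brooding = 0.02, median_diff_active = 0,
             available = TRUE)
  out <- adjust_boundaries(cands, tr, st)
  expect_equal(out$start_s[out$label == "brooding"], 460, tolerance = 5)
  expect_equal(out$end_s[out$label == "active"][1], 460, tolerance = 5)

  # already aligned bout is a fixed point
  aligned <- make_bouts(c(0, 460, 900), c(460, 900, 1000),
                        c("active", "brooding", "active"))
  out2 <- adjust_boundaries(aligned, tr, st)
  expect_equal(out2$start_s, aligned$start_s)

  # no qualifying bin: unchanged
  flat <- make_trace(t5, tbody5 = 30)
  out3 <- adjust_boundaries(cands, flat, st)
  expect_equal(out3$start_s, cands$start_s)
  expect_equal(out3$end_s, cands$end_s)
})

test_that("short bouts are dropped and short gaps merged, inclusively at 20 s", {
  # 15-s brooding bout between long active bouts disappears
  b <- make_bouts(c(0, 300, 315), c(300, 315, 600),
                  c("active", "brooding", "active"))
  out <- drop_short(b)
  expect_equal(sum(out$label == "brooding"), 0)
  expect_equal(nrow(out), 1)

  # exactly 20 s is removed ("up to 20 s" inclusive)
  b20 <- make_bouts(c(0, 300, 320), c(300, 320, 600),
                    c("active", "brooding", "active"))
  expect_equal(sum(drop_short(b20)$label == "brooding"), 0)

  # 21 s survives
  b21 <- make_bouts(c(0, 300, 321), c(300, 321, 600),
                    c("active", "brooding", "active"))
  expect_equal(sum(drop_short(b21)$label == "brooding"), 1)

  # two 10-min bouts with a 10-s gap merge into one
  m <- make_bouts(c(0, 600, 610), c(600, 610, 1210),
                  c("brooding", "active", "brooding"))
  out_m <- drop_short(m)
  bb <- out_m[out_m$label == "brooding", ]
  expect_equal(nrow(bb), 1)
  expect_equal(bb$end_s - bb$start_s, 1210)
})

test_that("feathered chicks are flagged at 65 g, strictly", {
  ch <- function(m0, m1) tibble::tibble(mass_start = m0, mass_end = m1)
  expect_true(flag_feathered(ch(70, NA)))
  expect_true(flag_feathered(ch(40, 66)))
  expect_false(flag_feathered(ch(30, 40)))
  expect_false(flag_feathered(ch(64.9, 64.9)))
})

test_that("an all-active candidate set post-processes to no brooding", {
  t5 <- seq(0, 3600 - 5, 5)
  tr <- make_trace(t5, sun_elev = -20)
  cands <- make_bouts(0, 3600, "active")
  out <- suppressWarnings(run_postprocess(cands, tr))
  expect_equal(sum(out$label == "brooding"), 0)
})

test_that("post-processing a simulated chick is idempotent and invariant-clean", {
  s <- shared_sim()
  bouts <- detect_brooding(s$trace, s$sim$chick, seed = 1)
  # finalized invariants
  bb <- bouts[bouts$label == "brooding", ]
  expect_true(all(bb$end_s - bb$start_s > 20))
  if (nrow(bb) > 1) {
    expect_true(all(bb$start_s[-1] - bb$end_s[-nrow(bb)] > 20))
  }
  # every daylight brooding bout has a dark bin
  for (i in seq_len(nrow(bb))) {
    idx <- s$trace$t5 >= bb$start_s[i] & s$trace$t5 < bb$end_s[i]
    if (any(s$trace$sun_elev[idx] >= -6)) {
      expect_gte(sum(s$trace$light5[idx] < 50), 1)
    }
  }
  # idempotence
  again <- run_postprocess(bouts, s$trace, s$sim$chick)
  expect_equal(again$start_s, bouts$start_s, tolerance = 1e-9)
  expect_equal(again$end_s, bouts$end_s, tolerance = 1e-9)
  expect_equal(again$label, bouts$label)
})

test_that("boundary adjustment recovers a delayed parental contact", {
  cfg <- sim_config("NL", duration_h = 6, seed = 9, pre_contact_still_s = 60,
                    tbody_noise_sd = 0.01)
  sim <- simulate_chick(cfg, "lagchick")
  trace <- preprocess_chick(sim$raw, sim$ambient, sim$chick)
  bouts <- detect_brooding(trace, sim$chick, seed = 1)
  f <- bout_f1(bouts, sim$truth)
  expect_gt(nrow(f$matches), 3)
  # starts recovered to within one 5-s bin of true contact (median)
  start_err <- median(abs(f$matches$pred_start - f$matches$truth_start))
  expect_lte(start_err, 5)
})

test_that("QC report lists thermally inconsistent bouts only", {
  t5 <- seq(0, 1495, 5)
  tr <- make_trace(t5, tbody5 = 37, tamb5 = 15, sun_elev = -20)
  good <- make_bouts(c(0, 100), c(100, 1500), c("active", "brooding"))
  expect_equal(nrow(qc_report(good, tr)), 0)
  # a bout whose temperature never rises above ambient is flagged
  tr_cold <- make_trace(t5, tbody5 = 15.1, tamb5 = 15, sun_elev = -20)
  flagged <- qc_report(good, tr_cold)
  expect_equal(nrow(flagged), 1)
  path <- withr::local_tempfile(fileext = ".txt")
  qc_report(good, tr_cold, path = path)
  expect_true(file.exists(path))
  expect_gt(length(readLines(path)), 1)
})
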