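utc0 <- as.POSIXct("2019-06-01 00:00:00", tz = "UTC")

chick_row <- function(species = "NL", id = "chick") {
  tibble::tibble(chick_id = id, family_id = "f1", species = species,
                 head_length = 25, mass_start = 20, mass_end = 24,
                 deploy_start = utc0, deploy_end = utc0 + 86400,
                 lat = if (species == "NL") 48.99 else 24.83,
                 lon = if (species == "NL") 14.38 else 55.36)
}

test_that("a fully brooded hour yields 60 brooded minutes, proportion 1", {
  t5 <- seq(0, 3600 - 5, 5)
  tr <- make_trace(t5, chick_id = "chick", start_utc = utc0)
  b <- make_bouts(0, 3600, "brooding")
  hr <- hourly_table(b, tr, chick_row())
  expect_equal(nrow(hr), 1)
  expect_equal(hr$min_brooded, 60)
  expect_equal(hr$prop_brooded, 1)
  expect_equal(hr$min_not_brooded, 0)
})

test_that("a 30-min observed hour with 12 brooded minutes weights by sqrt(30)", {
  t5 <- seq(0, 1800 - 5, 5)  # first half of local hour 01 (UTC+1)
  tr <- make_trace(t5, start_utc = utc0)
  b <- make_bouts(300, 300 + 720, "brooding")
  hr <- hourly_table(b, tr, chick_row())
  expect_equal(hr$min_brooded, 12)
  expect_equal(hr$prop_brooded, 0.4)
  expect_equal(hr$weight, sqrt(30))
  expect_equal(hr$hour_start, 1)  # UTC midnight start = 01:00 local CZ
})

test_that("hourly minutes equal brute-force per-minute counting", {
  set.seed(77)
  t5 <- seq(0, 6 * 3600 - 5, 5)
  tr <- make_trace(t5, start_utc = utc0 + 1800)  # off-hour deployment start
  for (rep in 1:5) {
    edges <- sort(sample(seq(0, 6 * 3600, 60), 8))
    b <- make_bouts(edges[c(1, 3, 5, 7)], edges[c(2, 4, 6, 8)],
                    rep("brooding", 4))
    b <- b[b$end_s > b$start_s, ]
    hr <- hourly_table(b, tr, chick_row())
    # brute force on a 1-s grid
    sec <- 0:(6 * 3600 - 1)
    brooded <- rep(FALSE, length(sec))
    for (i in seq_len(nrow(b))) {
      brooded[sec >= b$start_s[i] & sec < b$end_s[i]] <- TRUE
    }
    local_hour <- floor((as.numeric(utc0 + 1800) + 3600 + sec) / 3600)
    want <- tapply(brooded, local_hour, sum) / 60
    expect_equal(hr$min_brooded, as.numeric(want), tolerance = 1e-9)
    # coverage conservation
    expect_equal(sum(hr$min_brooded) * 60, sum(b$end_s - b$start_s),
                 tolerance = 1e-9)
  }
})

test_that("the previous-hour predictor lags within contiguous hours only", {
  t5 <- seq(0, 3 * 3600 - 5, 5)
  tr <- make_trace(t5, start_utc = utc0)
  b <- make_bouts(c(0, 3600), c(1800, 5400), c("brooding", "brooding"))
  hr <- hourly_table(b, tr, chick_row())
  expect_true(is.na(hr$prev_hour_prop[1]))
  expect_equal(hr$prev_hour_prop[2], hr$prop_brooded[1])
})

test_that("efficiency rows exist only for bouts over 5 min, first 5 min cut", {
  t5 <- seq(0, 1800 - 5, 5)
  # ramp 30 -> 38 over the first 5 min of the bout, then constant 38
  bout_start <- 300
  tb <- ifelse(t5 < bout_start, 30,
               pmin(30 + (t5 - bout_start) * (8 / 300), 38))
  tr <- make_trace(t5, tbody5 = tb, start_utc = utc0)
  ch <- chick_row()
  # 4-min bout: no row
  b4 <- make_bouts(bout_start, bout_start + 240, "brooding")
  expect_equal(nrow(efficiency_table(b4, tr, ch)), 0)
  # 10-min bout: median of the stable phase
  b10 <- make_bouts(bout_start, bout_start + 600, "brooding")
  eff <- efficiency_table(b10, tr, ch)
  expect_equal(nrow(eff), 1)
  expect_equal(eff$median_temp, 38.0)
  expect_gt(eff$bout_dur_s, 300)
})

test_that("efficiency medians lie within the post-300 s temperature range", {
  s <- shared_sim()
  bouts <- detect_brooding(s$trace, s$sim$chick, seed = 1)
  eff <- efficiency_table(bouts, s$trace, s$sim$chick)
  expect_true(all(eff$bout_dur_s > 300))
  for (i in seq_len(nrow(eff))) {
    idx <- s$trace$t5 >= eff$bout_start_s[i] + 300 &
      s$trace$t5 < eff$bout_start_s[i] + eff$bout_dur_s[i]
    expect_gte(eff$median_temp[i], min(s$trace$tbody5[idx]))
    expect_lte(eff$median_temp[i], max(s$trace$tbody5[idx]))
  }
})

test_that("overall rate summarises per-chick proportions", {
  t5 <- seq(0, 3600 - 5, 5)
  tr <- make_trace(t5, chick_id = "c1")
  half <- make_bouts(0, 1800, "brooding", chick_id = "c1")
  ov <- overall_rate(half, tr)
  expect_equal(ov$per_chick$proportion, 0.5)
  expect_equal(ov$median, 0.5)
  none <- make_bouts(numeric(), numeric(), character(), chick_id = "c1")
  expect_equal(overall_rate(none, tr)$per_chick$brooded_s, 0)
})

test_that("diel transform hits the cardinal points and the unit circle", {
  expect_equal(unlist(diel_transform(0)), c(sin_t = 0, cos_t = 1))
  expect_equal(unlist(diel_transform(6)), c(sin_t = 1, cos_t = 0))
  expect_equal(unlist(diel_transform(18)), c(sin_t = -1, cos_t = 0),
               tolerance = 1e-12)
  h <- runif(50, 0, 24 - 1e-9)
  dt <- diel_transform(h)
  expect_equal(dt$sin_t^2 + dt$cos_t^2, rep(1, 50), tolerance = 1e-12)
  expect_error(diel_transform(24), "\\[0, 24\\)")
})

test_that("z-transform uses the n-1 SD and round-trips its constants", {
  zt <- ztransform(c(0, 2))
  expect_equal(zt$z, c(-1, 1) / sqrt(2))
  expect_equal(zt$mean, 1)
  expect_equal(zt$sd, sqrt(2))
  x <- rnorm(100, 5, 3)
  zt2 <- ztransform(x)
  expect_equal(mean(zt2$z), 0, tolerance = 1e-12)
  expect_equal(sd(zt2$z), 1, tolerance = 1e-12)
  expect_equal(zt2$z * zt2$sd + zt2$mean, x, tolerance = 1e-12)
  expect_error(ztransform(rep(3, 10)), "constant")
})

test_that("actograms render to a non-empty file, with and without bouts", {
  s <- shared_sim()
  bouts <- detect_brooding(s$trace, s$sim$chick, seed = 1)
  path <- withr::local_tempfile(fileext = ".pdf")
  render_actogram(s$trace, bouts, path)
  expect_true(file.exists(path))
  expect_gt(file.size(path), 1000)
  path2 <- withr::local_tempfile(fileext = ".pdf")
  render_actogram(s$trace, bouts[0, ], path2)
  expect_gt(file.size(path2), 1000)
})
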