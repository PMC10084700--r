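# minimal sim_truth stand-in with a known per-second state sequence
toy_truth <- function(brood_intervals, n_s) {
  states <- rep("foraging", n_s)
  for (i in seq_len(nrow(brood_intervals))) {
    states[(brood_intervals$start_s[i] + 1):brood_intervals$end_s[i]] <- "brooding"
  }
  structure(list(states = factor(states,
                                 levels = c("brooding", "foraging",
                                            "shade_rest", "other_rest")),
                 bouts = tibble::tibble(state = "brooding",
                                        start_s = brood_intervals$start_s,
                                        end_s = brood_intervals$end_s),
                 brooding_prop = mean(states == "brooding"),
                 config = NULL),
            class = "sim_truth")
}

test_that("a perfect prediction has zero off-diagonal counts", {
  n_s <- 3600
  iv <- tibble::tibble(start_s = c(600, 2000), end_s = c(1200, 3000))
  truth <- toy_truth(iv, n_s)
  tr <- make_trace(seq(0, n_s - 5, 5))
  pred <- make_bouts(iv$start_s, iv$end_s, rep("brooding", 2))
  conf <- sample_confusion(pred, truth, tr)
  expect_equal(conf$fp, 0)
  expect_equal(conf$fn, 0)
  expect_equal(conf$accuracy, 1)
  expect_equal(conf$balanced_accuracy, 1)
})

test_that("an empty prediction scores recall 0, specificity 1", {
  truth <- toy_truth(tibble::tibble(start_s = 0, end_s = 1440), 3600)  # 40%
  tr <- make_trace(seq(0, 3595, 5))
  pred <- make_bouts(numeric(), numeric(), character())
  conf <- sample_confusion(pred, truth, tr)
  expect_equal(conf$recall, 0)
  expect_equal(conf$specificity, 1)
})

test_that("confusion counts equal brute-force per-bin comparison", {
  set.seed(55)
  n_s <- 7200
  tr <- make_trace(seq(0, n_s - 5, 5))
  for (rep in 1:5) {
    edges_t <- sort(sample(seq(0, n_s, 5), 6))
    truth <- toy_truth(tibble::tibble(start_s = edges_t[c(1, 3, 5)],
                                      end_s = edges_t[c(2, 4, 6)]), n_s)
    edges_p <- sort(sample(seq(0, n_s, 5), 6))
    pred <- make_bouts(edges_p[c(1, 3, 5)], edges_p[c(2, 4, 6)],
                       rep("brooding", 3))
    pred <- pred[pred$end_s > pred$start_s, ]
    conf <- sample_confusion(pred, truth, tr)
    # brute force per bin
    p <- a <- logical(nrow(tr))
    for (k in seq_len(nrow(tr))) {
      mid <- tr$t5[k]
      p[k] <- any(pred$start_s <= mid & pred$end_s > mid + 2.5)
      sec <- (tr$t5[k] + 1):(tr$t5[k] + 5)
      a[k] <- sum(truth$states[sec] == "brooding") * 2 >= 5
    }
    expect_equal(conf$tp, sum(p & a))
    expect_equal(conf$tn, sum(!p & !a))
    expect_equal(conf$fp, sum(p & !a))
    expect_equal(conf$fn, sum(!p & a))
  }
})

test_that("timeline mismatches are rejected", {
  truth <- toy_truth(tibble::tibble(start_s = 0, end_s = 100), 600)
  tr <- make_trace(seq(0, 1195, 5))
  pred <- make_bouts(0, 100, "brooding")
  expect_error(sample_confusion(pred, truth, tr), "timeline mismatch")
})

test_that("bout F1 is 1 for identical sets and 0 for disjoint sets", {
  truth <- make_bouts(c(0, 500), c(100, 800), rep("brooding", 2))
  expect_equal(bout_f1(truth, truth)$f1, 1)
  other <- make_bouts(c(1000, 2000), c(1100, 2300), rep("brooding", 2))
  expect_equal(bout_f1(other, truth)$f1, 0)
})

test_that("half-overlap cases match the hand-computed matching", {
  truth <- make_bouts(0, 100, "brooding")
  # IoU = 50/150 = 1/3 < 0.5: no match
  pred_third <- make_bouts(50, 150, "brooding")
  expect_equal(bout_f1(pred_third, truth)$f1, 0)
  # IoU = 80/120 = 2/3 >= 0.5: match
  pred_two_thirds <- make_bouts(20, 120, "brooding")
  f <- bout_f1(pred_two_thirds, truth)
  expect_equal(f$f1, 1)
  expect_equal(f$matches$iou, 2 / 3)
  # two predictions over one truth bout: greedy keeps the larger overlap
  pred_two <- make_bouts(c(0, 60), c(55, 100), rep("brooding", 2))
  f2 <- bout_f1(pred_two, truth)
  expect_equal(f2$recall, 1)
  expect_equal(f2$precision, 0.5)
})

test_that("F1 is symmetric under swapping prediction and truth", {
  set.seed(66)
  for (rep in 1:10) {
    e1 <- sort(sample(0:2000, 8))
    e2 <- sort(sample(0:2000, 6))
    a <- make_bouts(e1[c(1, 3, 5, 7)], e1[c(2, 4, 6, 8)], rep("brooding", 4))
    b <- make_bouts(e2[c(1, 3, 5)], e2[c(2, 4, 6)], rep("brooding", 3))
    a <- a[a$end_s > a$start_s, ]
    b <- b[b$end_s > b$start_s, ]
    expect_equal(bout_f1(a, b)$f1, bout_f1(b, a)$f1, tolerance = 1e-12)
  }
})

test_that("boundary errors reproduce constructed shifts", {
  truth <- make_bouts(c(0, 1000), c(500, 1600), rep("brooding", 2))
  expect_equal(boundary_error(bout_f1(truth, truth)$matches)$median_start_error_s, 0)
  shifted <- make_bouts(c(10, 1010), c(510, 1610), rep("brooding", 2))
  be <- boundary_error(bout_f1(shifted, truth)$matches)
  expect_equal(be$median_start_error_s, 10)
  expect_equal(be$median_end_error_s, 10)
  # random shifts against brute-force recomputation
  set.seed(77)
  sh <- round(runif(2, -30, 30))
  rnd <- make_bouts(truth$start_s + sh, truth$end_s + sh, rep("brooding", 2))
  be2 <- boundary_error(bout_f1(rnd, truth)$matches)
  expect_equal(be2$median_start_error_s, median(abs(sh)))
  # no matches -> unavailable
  none <- boundary_error(bout_f1(make_bouts(5000, 5100, "brooding"),
                                 truth)$matches)
  expect_false(none$available)
})

test_that("truth scored against itself is perfect", {
  s <- shared_sim()
  tb <- truth_bouts(s$sim$truth, "NLShared")
  ev <- evaluate_detection(tb, s$sim$truth, s$trace)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$bout_f1, 1)
  expect_equal(ev$rate_error, 0)
})
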