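make_inst <- function(rows, cols, label, h = 16, w = 16)
  instance_mask(rect_mask(h, w, rows, cols), label)

test_that("the four-way outcome rule covers its four cells", {
  a <- make_inst(1:8, 1:8, "CM")
  a_cap <- make_inst(1:8, 1:8, "CAP")
  expect_identical(classify_outcome(a, a, 0.5), "TP")
  expect_identical(classify_outcome(a_cap, a, 0.5), "TN")  # same mask, other label
  # the 1/3-IoU fixture: same label below threshold, other label below threshold
  b <- make_inst(1:2, 1:2, "CM"); c2 <- make_inst(1:2, 2:3, "CM")
  expect_equal(mask_iou(b, c2), 1 / 3)
  expect_identical(classify_outcome(b, c2, 0.5), "FP")
  c2_cap <- make_inst(1:2, 2:3, "CAP")
  expect_identical(classify_outcome(c2_cap, b, 0.5), "FN")
  # strict COCO mode collapses label mismatches to FP
  expect_identical(classify_outcome(a_cap, a, 0.5, rule = "coco"), "FP")
})

test_that("outcome classification is exhaustive and mutually exclusive", {
  set.seed(61)
  for (k in 1:40) {
    p <- random_rect_instance(16, 16)
    g <- random_rect_instance(16, 16)
    phi <- stats::runif(1, 0.05, 1)
    out <- classify_outcome(p, g, phi)
    expect_true(out %in% c("TP", "FP", "TN", "FN"))
    # exactly one cell applies, determined by (label match, IoU side)
    want <- if (p$label == g$label) {
      if (mask_iou(p, g) >= phi) "TP" else "FP"
    } else {
      if (mask_iou(p, g) >= phi) "TN" else "FN"
    }
    expect_identical(out, want)
  }
})

test_that("greedy matching handles the canonical cases", {
  gts <- list(make_inst(1:6, 1:6, "CM"), make_inst(9:14, 9:14, "CAP"))
  # perfect predictions: all TP at any phi <= 1
  for (phi in c(0.3, 0.5, 0.95)) {
    m <- match_predictions(gts, gts, phi)
    expect_equal(unname(m$outcomes), c(2, 0, 0, 0))
  }
  # no predictions: every ground truth is a miss
  m0 <- match_predictions(list(), gts, 0.5)
  expect_equal(unname(m0$outcomes["FN"]), 2)
  expect_equal(m0$detection$CM[["fn"]], 1)
  expect_equal(m0$detection$CAP[["fn"]], 1)
  # two predictions over one ground truth: one matches, one is FP
  g1 <- list(make_inst(1:6, 1:6, "CM"))
  p2 <- list(make_inst(1:6, 1:6, "CM"), make_inst(1:5, 1:6, "CM"))
  m2 <- match_predictions(p2, g1, 0.5)
  expect_equal(unname(m2$outcomes["TP"]), 1)
  expect_equal(unname(m2$outcomes["FP"]), 1)
  # the greedy pick is the higher-IoU pair
  a <- m2$assignment
  expect_equal(a$pred[!is.na(a$gt) & a$outcome == "TP"], 1)
})

test_that("greedy matching equals exhaustive optimal assignment when unambiguous", {
  set.seed(67)
  for (k in 1:12) {
    # unambiguous scenes: predictions are perturbed copies of distinct,
    # well-separated ground truths
    n <- sample(2:5, 1)
    gts <- lapply(seq_len(n), function(i) {
      r0 <- 1 + (i - 1) * 12
      make_inst(r0:(r0 + 7), 3:10, sample(c("CM", "CAP"), 1), h = 64, w = 16)
    })
    preds <- lapply(gts, function(g) {
      shift <- sample(0:2, 1)
      idx <- which(g$mask, arr.ind = TRUE)
      m <- matrix(FALSE, 64, 16)
      m[pmin(idx[, 1] + shift, 64) + (idx[, 2] - 1) * 64] <- TRUE
      instance_mask(m, g$label)
    })
    phi <- sample(c(0.5, 0.75), 1)
    got <- match_predictions(preds, gts, phi)$outcomes[["TP"]]
    expect_equal(got, oracle_optimal_tp(preds, gts, phi))
  }
})

test_that("TP count and metrics are monotone non-increasing in phi", {
  set.seed(71)
  for (k in 1:6) {
    sc <- easy_scene(seed = 200 + k, px = 96)
    preds <- closed_loop_predict(sc, jitter_px = 3, seed = k)
    tps <- vapply(seq(0.5, 0.95, by = 0.05), function(phi)
      match_predictions(preds, sc$masks, phi)$outcomes[["TP"]], numeric(1))
    expect_true(all(diff(tps) <= 0))
  }
})

test_that("metrics hit their bounds on perfect and empty predictions", {
  gts <- list(list(make_inst(1:6, 1:6, "CM"), make_inst(9:14, 9:14, "CAP")))
  for (setting in c("iou50", "iou75", "sweep")) {
    ev <- evaluate_instances(gts, gts, eval_config(setting))
    expect_equal(ev$mAP, 1); expect_equal(ev$mAR, 1); expect_equal(ev$F1, 1)
  }
  ev0 <- evaluate_instances(list(list()), gts, eval_config("iou50"))
  expect_equal(ev0$mAR, 0); expect_equal(ev0$F1, 0)
  expect_length(eval_config("sweep")$thresholds, 10)
  expect_error(evaluate_instances(list(list()), list(list())), "ground-truth")
})

test_that("ranked AP integrates the precision-recall curve over scores", {
  g <- list(make_inst(1:6, 1:6, "CM"), make_inst(9:14, 9:14, "CM"))
  # one true hit scored above one miss: AP ~ first-hit precision at half recall
  preds <- list(g[[1]], make_inst(1:2, 12:13, "CM"))
  scores <- list(c(0.9, 0.8))
  ev <- evaluate_instances(list(preds), list(g), eval_config("iou50"),
                           scores_by_image = scores)
  expect_identical(ev$ap_mode, "ranked")
  # recall 0.5 at precision 1, then no further hits: 101-point AP ~ 0.5
  expect_equal(ev$mAP, mean(c(rep(1, 51), rep(0, 50))), tolerance = 1e-9)
  # unscored predictions fall back to set-level precision
  ev2 <- evaluate_instances(list(preds), list(g), eval_config("iou50"))
  expect_identical(ev2$ap_mode, "set-level")
  expect_equal(ev2$mAP, 0.5)
})

test_that("accuracy stays a diagnostic with its worked example", {
  expect_equal(simple_accuracy(9, 10), 0.9)  # 9 capillaries, 1 missed CM
  expect_equal(simple_accuracy(0, 7), 0)
  expect_equal(simple_accuracy(7, 7), 1)
  expect_error(simple_accuracy(0, 0), "positive")
})

test_that("relative error and run aggregation follow their definitions", {
  expect_equal(relative_error(10, 10), 0)
  expect_equal(relative_error(12, 10), 0.2)
  expect_error(relative_error(1, 0), "undefined")
  expect_equal(aggregate_runs(c(0.5, 0.5, 0.5))$sd, 0)
  two <- aggregate_runs(c(0, 1))
  expect_equal(two$mean, 0.5)
  expect_equal(two$sd, sqrt(0.5), tolerance = 1e-12)  # two-point closed form
  expect_error(aggregate_runs(0.7), "2 runs")
})
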