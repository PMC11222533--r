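# Instance-segmentation evaluation: IoU-thresholded outcome classification,
# greedy one-to-one matching, mAP/mAR/F1 over single thresholds and the
# [0.5:0.95] sweep, and mean +/- SD aggregation across repeated test runs.
#
# Outcome rule: a matched prediction with the SAME label as its ground
# truth is TP when IoU >= phi and FP when IoU < phi; with a DIFFERENT
# label it is TN when IoU >= phi and FN when IoU < phi. This four-way rule
# departs from strict COCO convention (where a label mismatch is simply a
# false positive); a strict-COCO mode is available behind `rule = "coco"`
# but the four-way rule is the default. Precision/recall use TP/FP/FN
# only; TN is tallied and reported.

#' Evaluation configuration
#'
#' Three standard settings: single IoU thresholds 0.5 and 0.75, and the
#' sweep 0.50 to 0.95 in steps of 0.05 (exactly 10 thresholds), under
#' which metrics are additionally averaged across thresholds. Matching is
#' always greedy-by-IoU, one-to-one, label-agnostic.
#'
#' @param setting `"iou50"`, `"iou75"`, or `"sweep"`; ignored when
#'   `thresholds` is given.
#' @param thresholds Optional explicit IoU thresholds in `(0, 1]`.
#' @param rule Outcome rule: `"fourway"` (default) or strict `"coco"`.
#' @return An object of class `eval_config`.
#' @export
eval_config <- function(setting = c("iou50", "iou75", "sweep"),
                        thresholds = NULL, rule = c("fourway", "coco")) {
  rule <- match.arg(rule)
  if (is.null(thresholds)) {
    setting <- match.arg(setting)
    thresholds <- switch(setting,
                         iou50 = 0.5, iou75 = 0.75,
                         sweep = seq(0.5, 0.95, by = 0.05))
  } else {
    setting <- "custom"
    stopifnot(all(thresholds > 0), all(thresholds <= 1))
  }
  structure(list(setting = setting, thresholds = thresholds,
                 matching_policy = "greedy-by-IoU", rule = rule),
            class = "eval_config")
}

#' Classify one prediction/ground-truth pair
#'
#' Applies the outcome rule at IoU threshold `phi` to a matched pair of
#' masks (see the rule description above).
#'
#' @param m_p,m_gt Predicted and ground-truth `instance_mask` objects with
#'   identical raster dimensions.
#' @param phi IoU threshold in `(0, 1]`.
#' @param rule `"fourway"` (default) or `"coco"` (label mismatch = FP).
#' @return One of `"TP"`, `"FP"`, `"TN"`, `"FN"`.
#' @export
classify_outcome <- function(m_p, m_gt, phi, rule = c("fourway", "coco")) {
  rule <- match.arg(rule)
  stopifnot(phi > 0, phi <= 1)
  iou <- mask_iou(m_p, m_gt)
  same <- m_p$label == m_gt$label
  if (rule == "coco") {
    if (same && iou >= phi) "TP" else "FP"
  } else if (same) {
    if (iou >= phi) "TP" else "FP"
  } else {
    if (iou >= phi) "TN" else "FN"
  }
}

# IoU of every (pred, gt) pair; empty predictions (failed masks) get IoU 0
# against any non-empty ground truth.
iou_matrix <- function(pred_masks, gt_masks) {
  M <- matrix(0, length(pred_masks), length(gt_masks))
  for (i in seq_along(pred_masks)) {
    pm <- as_mask_matrix(pred_masks[[i]])
    if (!any(pm)) next
    for (j in seq_along(gt_masks))
      M[i, j] <- mask_iou(pm, gt_masks[[j]])
  }
  M
}

#' Greedy one-to-one matching of predictions to ground truth
#'
#' Candidate pairs with positive IoU are taken in order of descending IoU
#' (label-agnostically); each prediction and each ground truth is used at
#' most once. Matched pairs are classified with [classify_outcome()] at
#' `phi`; unmatched predictions are false positives and unmatched ground
#' truths false negatives under their own labels.
#'
#' @param preds A `segmentation_result` or list of `instance_mask`.
#' @param gts List of ground-truth `instance_mask`.
#' @param phi IoU threshold.
#' @param rule Outcome rule (see [classify_outcome()]).
#' @return List: `assignment` data frame (`pred`, `gt`, `iou`, `outcome`,
#'   `pred_label`, `gt_label`), four-way `outcomes` count vector, and
#'   per-label `detection` counts (`tp`, `fp`, `fn`) used by
#'   precision/recall.
#' @export
match_predictions <- function(preds, gts, phi, rule = c("fourway", "coco")) {
  rule <- match.arg(rule)
  pred_masks <- if (inherits(preds, "segmentation_result")) preds$instances
                else preds
  M <- iou_matrix(pred_masks, gts)
  np <- length(pred_masks); ng <- length(gts)
  pred_used <- logical(np); gt_used <- logical(ng)
  rows <- list()
  if (np > 0 && ng > 0) {
    ord <- order(-as.vector(M),
                 rep(seq_len(np), times = ng),
                 rep(seq_len(ng), each = np))
    for (k in ord) {
      if (M[k] <= 0) break
      i <- (k - 1) %% np + 1; j <- (k - 1) %/% np + 1
      if (pred_used[i] || gt_used[j]) next
      pred_used[i] <- TRUE; gt_used[j] <- TRUE
      rows[[length(rows) + 1]] <- data.frame(
        pred = i, gt = j, iou = M[i, j],
        outcome = classify_outcome(pred_masks[[i]], gts[[j]], phi, rule),
        pred_label = pred_masks[[i]]$label, gt_label = gts[[j]]$label,
        stringsAsFactors = FALSE)
    }
  }
  for (i in which(!pred_used))
    rows[[length(rows) + 1]] <- data.frame(
      pred = i, gt = NA_integer_, iou = 0, outcome = "FP",
      pred_label = pred_masks[[i]]$label, gt_label = NA_character_,
      stringsAsFactors = FALSE)
  for (j in which(!gt_used))
    rows[[length(rows) + 1]] <- data.frame(
      pred = NA_integer_, gt = j, iou = 0, outcome = "FN",
      pred_label = NA_character_, gt_label = gts[[j]]$label,
      stringsAsFactors = FALSE)
  assignment <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pred = integer(0), gt = integer(0), iou = numeric(0),
               outcome = character(0), pred_label = character(0),
               gt_label = character(0), stringsAsFactors = FALSE)
  outcomes <- c(TP = sum(assignment$outcome == "TP"),
                FP = sum(assignment$outcome == "FP"),
                TN = sum(assignment$outcome == "TN"),
                FN = sum(assignment$outcome == "FN"))
  detection <- lapply(stats::setNames(nm = CLASS_LABELS), function(L) {
    tp <- sum(assignment$outcome == "TP" & assignment$pred_label == L,
              na.rm = TRUE)
    n_pred <- sum(vapply(pred_masks, `[[`, character(1), "label") == L)
    n_gt <- sum(vapply(gts, `[[`, character(1), "label") == L)
    c(tp = tp, fp = n_pred - tp, fn = n_gt - tp)
  })
  list(assignment = assignment, outcomes = outcomes, detection = detection)
}

# 101-point interpolated average precision from ranked TP flags.
ap_interpolated <- function(tp_flags, scores, n_gt) {
  if (n_gt == 0) return(NA_real_)
  if (length(tp_flags) == 0) return(0)
  ord <- order(-scores)
  tp <- cumsum(tp_flags[ord]); fp <- cumsum(!tp_flags[ord])
  recall <- tp / n_gt; precision <- tp / (tp + fp)
  mean(vapply(seq(0, 1, by = 0.01), function(r) {
    ok <- recall >= r
    if (!any(ok)) 0 else max(precision[ok])
  }, numeric(1)))
}

#' Evaluate predicted instances against ground truth
#'
#' Pools matches over images; per label and per threshold computes
#' precision = TP/(TP+FP), recall = TP/(TP+FN), and AP (101-point
#' score-ranked interpolation when every prediction carries a confidence
#' score, otherwise the set-level precision at the operating point). mAP
#' and mAR average over the class labels present in the ground truth; under
#' the sweep setting they additionally average over the 10 thresholds. F1
#' is the harmonic mean of mAP and mAR.
#'
#' @param preds_by_image List (one per image) of prediction lists
#'   (`segmentation_result` or lists of `instance_mask`).
#' @param gts_by_image Parallel list of ground-truth mask lists.
#' @param config An `eval_config`.
#' @param scores_by_image Optional parallel list of per-prediction score
#'   vectors (overrides scores stored in the masks).
#' @return An object of class `eval_report`: `per_threshold` data frame,
#'   `mAP`, `mAR`, `F1`, pooled four-way `outcomes`, `config`, and
#'   `ap_mode` (`"ranked"` or `"set-level"`).
#' @export
evaluate_instances <- function(preds_by_image, gts_by_image,
                               config = eval_config("iou50"),
                               scores_by_image = NULL) {
  stopifnot(inherits(config, "eval_config"),
            length(preds_by_image) == length(gts_by_image))
  if (sum(lengths(gts_by_image)) == 0)
    stop("evaluation requires at least one ground-truth instance")
  get_masks <- function(p) if (inherits(p, "segmentation_result")) p$instances
                           else p
  n_img <- length(preds_by_image)
  score_of <- function(img, idx) {
    if (!is.null(scores_by_image)) return(scores_by_image[[img]][idx])
    s <- get_masks(preds_by_image[[img]])[[idx]]$score
    s
  }
  all_scores <- unlist(lapply(seq_len(n_img), function(i) {
    k <- length(get_masks(preds_by_image[[i]]))
    if (k == 0) numeric(0) else vapply(seq_len(k), function(j)
      score_of(i, j), numeric(1))
  }))
  ranked <- length(all_scores) > 0 && !anyNA(all_scores)

  rows <- list(); pooled_outcomes <- c(TP = 0, FP = 0, TN = 0, FN = 0)
  for (phi in config$thresholds) {
    matches <- lapply(seq_len(n_img), function(i)
      match_predictions(preds_by_image[[i]], gts_by_image[[i]], phi,
                        rule = config$rule))
    if (phi == config$thresholds[1])
      pooled_outcomes <- Reduce(`+`, lapply(matches, `[[`, "outcomes"))
    for (L in CLASS_LABELS) {
      det <- Reduce(`+`, lapply(matches, function(m) m$detection[[L]]))
      n_gt <- det[["tp"]] + det[["fn"]]
      if (n_gt == 0) next  # label absent from ground truth: skip
      precision <- if (det[["tp"]] + det[["fp"]] == 0) 0
                   else det[["tp"]] / (det[["tp"]] + det[["fp"]])
      recall <- det[["tp"]] / n_gt
      ap <- if (ranked) {
        flags <- list(); scr <- list()
        for (i in seq_len(n_img)) {
          pm <- get_masks(preds_by_image[[i]])
          labs <- vapply(pm, `[[`, character(1), "label")
          for (j in which(labs == L)) {
            a <- matches[[i]]$assignment
            flags[[length(flags) + 1]] <-
              any(a$outcome == "TP" & !is.na(a$pred) & a$pred == j)
            scr[[length(scr) + 1]] <- score_of(i, j)
          }
        }
        ap_interpolated(unlist(flags), unlist(scr), n_gt)
      } else precision
      rows[[length(rows) + 1]] <- data.frame(
        label = L, phi = phi, tp = det[["tp"]], fp = det[["fp"]],
        fn = det[["fn"]], precision = precision, recall = recall, ap = ap,
        stringsAsFactors = FALSE)
    }
  }
  per_threshold <- do.call(rbind, rows)
  mAP <- mean(per_threshold$ap)
  mAR <- mean(per_threshold$recall)
  F1 <- if (mAP + mAR == 0) 0 else 2 * mAP * mAR / (mAP + mAR)
  structure(list(per_threshold = per_threshold, mAP = mAP, mAR = mAR,
                 F1 = F1, outcomes = pooled_outcomes, config = config,
                 ap_mode = if (ranked) "ranked" else "set-level"),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> setting %s (%d threshold%s, AP %s)\n",
              x$config$setting, length(x$config$thresholds),
              if (length(x$config$thresholds) > 1) "s" else "", x$ap_mode))
  cat(sprintf("  mAP %.3f  mAR %.3f  F1 %.3f\n", x$mAP, x$mAR, x$F1))
  invisible(x)
}

#' Plain accuracy (diagnostic only)
#'
#' Fraction of correct outcomes. Kept as a diagnostic: with class
#' imbalance (e.g. 9 capillaries and a single cardiomyocyte, the lone CM
#' missed) accuracy reads 90% while CM performance is zero, which is why
#' headline evaluation uses mAP/mAR/F1 instead.
#'
#' @param n_correct,n_total Counts, `0 <= n_correct <= n_total`,
#'   `n_total > 0`.
#' @return `n_correct / n_total`.
#' @export
simple_accuracy <- function(n_correct, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  stopifnot(n_correct >= 0, n_correct <= n_total)
  n_correct / n_total
}

#' Relative error of an assessment
#'
#' `|predicted - truth| / truth`, the per-measurement error used for
#' capillarization assessment.
#'
#' @param predicted,truth Numeric scalars; `truth` must be nonzero.
#' @return Non-negative relative error.
#' @export
relative_error <- function(predicted, truth) {
  if (!is.finite(truth) || truth == 0)
    stop("relative error undefined for zero (or non-finite) ground truth")
  abs(predicted - truth) / abs(truth)
}

#' Aggregate a metric over repeated test runs
#'
#' Sample mean and sample standard deviation (n - 1 denominator) over the
#' runs provided.
#'
#' @param values Numeric vector with at least 2 values.
#' @return List with `mean`, `sd`, `n`.
#' @export
aggregate_runs <- function(values) {
  if (length(values) < 2) stop("aggregation requires at least 2 runs")
  list(mean = mean(values), sd = stats::sd(values), n = length(values))
}
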