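# Shared fixtures and independent oracles, all built in code.

# small acquisition geometry used by most tests (keeps rasters cheap);
# FOV kept at the standard 42.5 um so physical-unit arithmetic is realistic
test_meta <- function(px = 64) image_meta(px, px, fov_um = 42.5)

rect_mask <- function(h, w, rows, cols) {
  m <- matrix(FALSE, h, w)
  m[rows, cols] <- TRUE
  m
}

# random axis-aligned rectangular instance on an h x w raster
random_rect_instance <- function(h, w, label = sample(c("CM", "CAP"), 1)) {
  r0 <- sample.int(h - 2, 1); r1 <- min(h, r0 + sample.int(8, 1))
  c0 <- sample.int(w - 2, 1); c1 <- min(w, c0 + sample.int(8, 1))
  instance_mask(rect_mask(h, w, r0:r1, c0:c1), label)
}

# random detection set with boxes inside a frame x [0,w) x [0,h)
random_detection_set <- function(n, w = 100, h = 100) {
  detection_set(lapply(seq_len(n), function(i) {
    x0 <- stats::runif(1, 0, w - 2); y0 <- stats::runif(1, 0, h - 2)
    detection(bbox(x0, y0, x0 + stats::runif(1, 1, w - x0),
                   y0 + stats::runif(1, 1, h - y0)),
              sample(c("CM", "CAP"), 1), stats::runif(1))
  }))
}

# --- independent oracles ---

# exhaustive per-pixel min/max scan (bounding box oracle)
oracle_bbox_scan <- function(mask) {
  xs <- integer(0); ys <- integer(0)
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask)))
    if (mask[r, c]) { xs <- c(xs, c - 1); ys <- c(ys, r - 1) }
  c(x_min = min(xs), y_min = min(ys), x_max = max(xs) + 1, y_max = max(ys) + 1)
}

# exhaustive O(n^2) double loop over (box_i, centroid_j) membership --
# the defining construction of the prompt sets
oracle_prompts_double_loop <- function(dset) {
  n <- dset$n
  cents <- lapply(dset$detections, function(d) bbox_centroid(d$box))
  lapply(seq_len(n), function(i) {
    box <- dset$detections[[i]]$box
    pts <- list()
    for (j in seq_len(n)) {
      p <- cents[[j]]
      if (p[["x"]] >= box[["x_min"]] && p[["x"]] < box[["x_max"]] &&
          p[["y"]] >= box[["y_min"]] && p[["y"]] < box[["y_max"]])
        pts[[length(pts) + 1]] <- c(p[["x"]], p[["y"]], as.numeric(j == i))
    }
    do.call(rbind, pts)
  })
}

# canonical ordering of a prompt point matrix for set comparison
sort_points <- function(pts) pts[order(pts[, 1], pts[, 2], pts[, 3]), , drop = FALSE]

# optimal one-to-one assignment by exhaustive permutation (<= 6 instances):
# maximizes the number of same-label pairs with IoU >= phi
oracle_optimal_tp <- function(pred_masks, gt_masks, phi) {
  np <- length(pred_masks); ng <- length(gt_masks)
  M <- matrix(0, np, ng)
  for (i in seq_len(np)) for (j in seq_len(ng))
    if (any(pred_masks[[i]]$mask))
      M[i, j] <- mask_iou(pred_masks[[i]], gt_masks[[j]])
  labs_p <- vapply(pred_masks, `[[`, character(1), "label")
  labs_g <- vapply(gt_masks, `[[`, character(1), "label")
  # recursively try every injective pred -> gt assignment (incl. unmatched)
  best_from <- function(i, free_gts) {
    if (i > np) return(0)
    best <- best_from(i + 1, free_gts)  # leave pred i unmatched
    for (j in free_gts) {
      if (M[i, j] <= 0) next
      tp <- as.integer(M[i, j] >= phi && labs_p[i] == labs_g[j])
      best <- max(best, tp + best_from(i + 1, setdiff(free_gts, j)))
    }
    best
  }
  best_from(1, seq_len(ng))
}

# scene small enough for closed-loop tests
easy_scene <- function(seed, px = 160)
  generate_scene(scene_preset("easy", meta = test_meta(px), seed = seed))

closed_loop_predict <- function(scene, jitter_px = 0, seed = 1L,
                                backend = "reference") {
  cfg <- pipeline_config(
    detector = detector_config(annotations = scene$masks,
                               jitter_px = jitter_px, seed = seed),
    backend = backend, meta = scene$meta)
  predict_instances(scene$image, cfg)
}
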