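# disk-on-bright-background fixture: dark object(s) on a bright field,
# the polarity of basement-membrane staining
disk_image <- function(px, centers, radii, dark = 2000, bright = 50000) {
  img <- matrix(bright, px, px)
  for (k in seq_along(radii)) {
    for (r in seq_len(px)) for (c in seq_len(px)) {
      if ((c - 1 - centers[[k]][1])^2 + (r - 1 - centers[[k]][2])^2 <=
          radii[k]^2) img[r, c] <- dark
    }
  }
  img
}

disk_mask <- function(px, center, radius) {
  m <- matrix(FALSE, px, px)
  for (r in seq_len(px)) for (c in seq_len(px))
    if ((c - 1 - center[1])^2 + (r - 1 - center[2])^2 <= radius^2)
      m[r, c] <- TRUE
  m
}

prompt_for_box <- function(b, label = "CM", extra_neg = NULL) {
  cen <- bbox_centroid(b)
  pts <- rbind(c(cen[["x"]], cen[["y"]], 1))
  if (!is.null(extra_neg)) pts <- rbind(pts, c(extra_neg, 0))
  prompt_set(b, pts, label)
}

test_that("the reference segmenter recovers a dark disk from its prompt", {
  img <- disk_image(48, list(c(24, 24)), 10)
  truth <- disk_mask(48, c(24, 24), 10)
  b <- bbox_from_mask(truth)
  m <- reference_prompt_segmenter(img, prompt_for_box(b))
  expect_gte(mask_iou(m, truth), 0.9)
})

test_that("negative points delete intruding components", {
  # second dark disk inside an enlarged box; negative point sits on it
  img <- disk_image(60, list(c(20, 20), c(42, 42)), c(9, 6))
  truth <- disk_mask(60, c(20, 20), 9)
  intruder <- disk_mask(60, c(42, 42), 6)
  box <- bbox(8, 8, 52, 52)  # covers both disks; centroid (30,30) misses both
  # centre the box on the target so its centroid is the positive point
  box <- bbox(9, 9, 31, 31)
  m <- reference_prompt_segmenter(img, prompt_for_box(box))
  expect_gte(mask_iou(m, truth), 0.9)
  # now a box whose centroid is on the target and that also covers the
  # intruder, with a negative point on the intruder
  box2 <- bbox(4, 4, 36, 36)
  m2 <- reference_prompt_segmenter(
    img, prompt_set(box2, rbind(c(20, 20, 1), c(30, 30, 0)), "CM"))
  # (30,30) is background here: negative on background leaves target alone
  expect_gte(mask_iou(m2, truth), 0.9)
  # negative point on the target's own component deletes it -> failed mask
  m3 <- reference_prompt_segmenter(
    img, prompt_set(box2, rbind(c(20, 20, 1), c(22, 20, 0)), "CM"))
  expect_false(any(m3))
})

test_that("structureless crops and bright-phase positives fail gracefully", {
  img <- matrix(30000, 40, 40)
  m <- reference_prompt_segmenter(img, prompt_for_box(bbox(5, 5, 25, 25)))
  expect_false(any(m))  # uniform image: no structure

  # positive point on the bright phase (no dark component underneath)
  img2 <- disk_image(40, list(c(10, 10)), 5)
  m2 <- reference_prompt_segmenter(img2, prompt_for_box(bbox(16, 16, 36, 36)))
  expect_false(any(m2))
})

test_that("segment_with_prompts enforces the per-backend contract", {
  img <- disk_image(48, list(c(24, 24)), 10)
  truth <- disk_mask(48, c(24, 24), 10)
  b <- bbox_from_mask(truth)
  expect_error(segment_with_prompts(img, list(prompt_for_box(b)), "nope"),
               "unknown segmentation backend")
  res0 <- segment_with_prompts(img, list(), "reference")
  expect_length(res0$instances, 0)

  # a deliberately leaky backend: returns the whole frame
  register_segmenter("leaky", function(image, prompt)
    matrix(TRUE, nrow(image), ncol(image)))
  res <- segment_with_prompts(img, list(prompt_for_box(b, "CAP")), "leaky")
  expect_length(res$instances, 1)
  expect_identical(res$instances[[1]]$label, "CAP")
  # box containment is enforced by clipping, whatever the backend emits
  out_box <- bbox_from_mask(res$instances[[1]])
  expect_gte(out_box[["x_min"]], b[["x_min"]])
  expect_gte(out_box[["y_min"]], b[["y_min"]])
  expect_lte(out_box[["x_max"]], ceiling(b[["x_max"]]))
  expect_lte(out_box[["y_max"]], ceiling(b[["y_max"]]))
})

test_that("masks stay inside their prompt boxes and avoid negative points", {
  set.seed(31)
  for (k in 1:4) {
    sc <- easy_scene(seed = 100 + k, px = 128)
    dets <- oracle_detector(sc$masks)
    prompts <- generate_prompts(dets)
    res <- segment_with_prompts(sc$image, prompts, "reference")
    for (i in seq_along(prompts)) {
      m <- res$instances[[i]]$mask
      if (!any(m)) next
      ob <- bbox_from_mask(m); pb <- prompts[[i]]$box
      expect_gte(ob[["x_min"]], floor(pb[["x_min"]]))
      expect_gte(ob[["y_min"]], floor(pb[["y_min"]]))
      expect_lte(ob[["x_max"]], ceiling(pb[["x_max"]]))
      expect_lte(ob[["y_max"]], ceiling(pb[["y_max"]]))
      neg <- prompts[[i]]$points[prompts[[i]]$points[, "label"] == 0, ,
                                 drop = FALSE]
      for (r in seq_len(nrow(neg)))
        expect_false(m[floor(neg[r, 2]) + 1, floor(neg[r, 1]) + 1])
    }
  }
})

test_that("segmentation is deterministic", {
  sc <- easy_scene(seed = 77, px = 128)
  prompts <- generate_prompts(oracle_detector(sc$masks))
  a <- segment_with_prompts(sc$image, prompts, "reference")
  b <- segment_with_prompts(sc$image, prompts, "reference")
  expect_identical(lapply(a$instances, `[[`, "mask"),
                   lapply(b$instances, `[[`, "mask"))
})
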