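test_that("preprocessing is deterministic with the stated limit behavior", {
  const <- matrix(1234, 16, 16)
  expect_equal(wiener3(const), const)          # zero-variance identity
  expect_true(all(preprocess(const) == 0))     # degenerate stretch -> zeros

  set.seed(8)
  noisy <- matrix(20000, 32, 32)
  hits <- sample.int(32 * 32, 60)
  noisy[hits] <- noisy[hits] + sample(c(-1, 1), 60, TRUE) * 15000
  expect_lt(stats::var(as.vector(wiener3(noisy))),
            stats::var(as.vector(noisy)))      # impulse noise is smoothed

  ramp <- matrix(seq(0, 65535, length.out = 64 * 64), 64, 64)
  out <- contrast_stretch(ramp)
  v_in <- as.vector(ramp); v_out <- as.vector(out)
  expect_true(all(diff(v_out[order(v_in)]) >= 0))  # monotone mapping
  expect_identical(preprocess(noisy), preprocess(noisy))
})

test_that("splits reproduce the 67/8/32 protocol and partition the index set", {
  sp <- split_dataset(107, split_spec(seed = 1))
  expect_equal(lengths(sp[c("train", "val", "test")]),
               c(train = 67L, val = 8L, test = 32L))

  sp10 <- split_dataset(10, split_spec(seed = 3))
  expect_equal(lengths(sp10[c("train", "val", "test")]),
               c(train = 6L, val = 1L, test = 3L))

  expect_identical(split_dataset(107, split_spec(seed = 5)),
                   split_dataset(107, split_spec(seed = 5)))
  expect_false(identical(split_dataset(107, split_spec(seed = 5))$test,
                         split_dataset(107, split_spec(seed = 6))$test))

  set.seed(12)
  for (n in c(7, 23, 107, 200)) {
    sp <- split_dataset(n, split_spec(seed = sample.int(1000, 1)))
    expect_identical(sort(c(sp$train, sp$val, sp$test)), seq_len(n))
  }
  expect_error(split_dataset(2, split_spec()), "n_items")
})

test_that("rotations follow the index-mapping oracle and are involutive", {
  img <- matrix(seq_len(16), 4, 4)
  m <- rect_mask(4, 4, 1, 1)  # single pixel at (x=0, y=0)
  rots <- rotate_augment(img, list(instance_mask(m, "CM")))
  # 90 cw sends (0,0) -> (3,0)
  expect_equal(which(rots$cw$masks[[1]]$mask, arr.ind = TRUE),
               matrix(c(1L, 4L), 1, dimnames = list(NULL, c("row", "col"))))
  # 90 ccw sends (0,0) -> (0,3)
  expect_equal(which(rots$ccw$masks[[1]]$mask, arr.ind = TRUE),
               matrix(c(4L, 1L), 1, dimnames = list(NULL, c("row", "col"))))
  # 180 twice is the identity
  twice <- rotate_augment(rots$flip$image, rots$flip$masks)
  expect_identical(twice$flip$image, img)
  expect_identical(twice$flip$masks[[1]]$mask, m)
  expect_error(rotate_augment(matrix(0, 3, 4)), "square")

  set.seed(19)
  inst <- random_rect_instance(12, 12)
  for (nm in c("cw", "ccw", "flip")) {
    r <- rotate_augment(matrix(0, 12, 12), list(inst))[[nm]]
    expect_equal(sum(r$masks[[1]]$mask), sum(inst$mask))  # area preserved
  }
})

test_that("rotating then boxing equals boxing then rotating", {
  set.seed(23)
  for (k in 1:10) {
    inst <- random_rect_instance(16, 16)
    rots <- rotate_augment(matrix(0, 16, 16), list(inst))
    for (nm in c("cw", "ccw", "flip")) {
      via_mask <- bbox_from_mask(rots[[nm]]$masks[[1]])
      via_box <- capquant:::rotate_box(bbox_from_mask(inst), nm, 16, 16)
      expect_equal(unclass(via_mask), unclass(via_box))
    }
  }
})

test_that("mosaic composition conserves annotations and scales boxes", {
  img <- matrix(stats::runif(64 * 64), 64, 64)
  full <- instance_mask(matrix(TRUE, 64, 64), "CM")
  sm <- list(image = img, masks = list(full))
  out <- mosaic_augment(list(sm, sm, sm, sm), seed = 2)
  expect_equal(dim(out$image), c(64, 64))
  expect_length(out$masks, 4)  # count conservation
  # a full-frame box lands as a quarter-frame box in some quadrant
  b <- bbox_from_mask(out$masks[[1]])
  expect_equal(bbox_width(b), 32); expect_equal(bbox_height(b), 32)
  expect_true(b[["x_min"]] %in% c(0, 32) && b[["y_min"]] %in% c(0, 32))
  # all four quadrants are covered exactly once
  corners <- t(vapply(out$masks, function(m) {
    bb <- bbox_from_mask(m); c(bb[["x_min"]], bb[["y_min"]])
  }, numeric(2)))
  expect_equal(nrow(unique(corners)), 4)
  expect_identical(mosaic_augment(list(sm, sm, sm, sm), seed = 2)$masks[[1]]$mask,
                   out$masks[[1]]$mask)  # seeded determinism
  expect_error(mosaic_augment(list(sm, sm, sm), seed = 1), "four")
})

test_that("mosaicking a mask then boxing equals transforming the box", {
  set.seed(29)
  insts <- lapply(1:4, function(i)
    instance_mask(rect_mask(32, 32, (2 * i):(2 * i + 9), 5:20), "CM"))
  samples <- lapply(insts, function(m)
    list(image = matrix(0, 32, 32), masks = list(m)))
  out <- mosaic_augment(samples, seed = 7)
  set.seed(7); quad <- sample.int(4)
  offs <- list(c(0, 0), c(0, 16), c(16, 0), c(16, 16))
  for (s in 1:4) {
    b0 <- bbox_from_mask(insts[[s]])
    o <- offs[[quad[s]]]
    # odd-index subsampling keeps even 0-based coordinates z -> z / 2, so a
    # box [min, max) maps to [ceiling(min/2), floor((max-1)/2) + 1)
    want <- c(ceiling(b0[["x_min"]] / 2) + o[2],
              ceiling(b0[["y_min"]] / 2) + o[1],
              floor((b0[["x_max"]] - 1) / 2) + 1 + o[2],
              floor((b0[["y_max"]] - 1) / 2) + 1 + o[1])
    expect_equal(unname(unclass(bbox_from_mask(out$masks[[s]]))), want)
  }
})

test_that("weak annotations circumscribe masks and round-trip via YOLO/COCO", {
  set.seed(37)
  meta <- test_meta(64)
  masks <- lapply(1:5, function(i) random_rect_instance(64, 64))
  anns <- masks_to_detector_annotations(masks)
  expect_length(anns, 5)
  for (i in 1:5)
    expect_equal(unclass(anns[[i]]$box), unclass(bbox_from_mask(masks[[i]])))

  ds <- detection_set(anns)
  ypath <- withr::local_tempfile(fileext = ".txt")
  write_yolo(ds, meta, ypath)
  back <- read_yolo(ypath, meta)
  for (i in 1:5) {
    expect_identical(back$detections[[i]]$label, ds$detections[[i]]$label)
    expect_lt(max(abs(unclass(back$detections[[i]]$box) -
                      unclass(ds$detections[[i]]$box))), 0.5)
  }

  cpath <- withr::local_tempfile(fileext = ".json")
  write_coco_detections(ds, cpath)
  cback <- read_coco_detections(cpath)
  for (i in 1:5)  # integer-aligned boxes round-trip bit-exactly
    expect_identical(unclass(cback$detections[[i]]$box),
                     unclass(ds$detections[[i]]$box))
})

test_that("the ROI admission rule gates on structure coverage", {
  meta <- test_meta(20)
  big <- instance_mask(rect_mask(20, 20, 1:18, 1:19), "CM")  # 85.5% coverage
  small <- instance_mask(rect_mask(20, 20, 1:10, 1:10), "CM")  # 25%
  expect_true(roi_admissible(list(big), meta))
  expect_false(roi_admissible(list(small), meta))
  expect_false(roi_admissible(list(), meta))
})

test_that("augment_dataset expands to a requested total with originals kept", {
  set.seed(41)
  samples <- lapply(1:5, function(i) {
    m <- random_rect_instance(16, 16)
    list(image = matrix(stats::runif(256), 16, 16), masks = list(m))
  })
  out <- augment_dataset(samples, target_total = 12, seed = 3)
  expect_length(out, 12)
  out2 <- augment_dataset(samples, seed = 3)  # no cap: 5 + 15 rotations + 1 mosaic
  expect_length(out2, 21)
})
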