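# Dataset tooling mirroring the training workflow: raw 16-bit frames are
# Wiener-filtered and contrast-stretched; masks are circumscribed into weak
# (bounding-box) annotations; the image set is split 70/30 into
# train+validation/test with 10% of train+validation held out for
# validation; the training set is expanded by three fixed rotations and
# four-quadrant mosaic composition.

# 3x3 local statistics with edge replication. Used by the Wiener filter so
# constant images pass through unchanged at the borders too.
.local_stats_3x3 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  p <- x[c(1, seq_len(h), h), c(1, seq_len(w), w)]  # replicate-pad by 1
  s <- matrix(0, h, w); s2 <- matrix(0, h, w)
  for (dr in 0:2) for (dc in 0:2) {
    block <- p[dr + seq_len(h), dc + seq_len(w)]
    s <- s + block; s2 <- s2 + block^2
  }
  mu <- s / 9
  list(mean = mu, var = pmax(s2 / 9 - mu^2, 0))
}

#' Adaptive 3x3 Wiener filter
#'
#' Pixelwise adaptive Wiener denoising over a 3x3 neighbourhood: with local
#' mean m and variance v, and noise power nu estimated as the mean local
#' variance, the output is `m + max(v - nu, 0) / max(v, nu) * (x - m)`.
#' Flat regions are smoothed toward the local mean; high-variance structure
#' (membrane ridges) is preserved. Edges are handled by replication, so a
#' constant image is returned unchanged.
#'
#' @param x Numeric matrix.
#' @param noise Optional noise power; estimated from the image when `NULL`.
#' @return Filtered matrix, same dimensions.
#' @export
wiener3 <- function(x, noise = NULL) {
  if (!is.matrix(x)) stop("input must be a 2-D raster")
  st <- .local_stats_3x3(x)
  if (is.null(noise)) noise <- mean(st$var)
  if (noise == 0) return(x)
  gain <- pmax(st$var - noise, 0) / pmax(st$var, noise)
  st$mean + gain * (x - st$mean)
}

#' Percentile contrast stretch
#'
#' Linear stretch mapping the `p_low` and `p_high` intensity percentiles to
#' the full dynamic range `[0, 2^bit_depth - 1]`, clipping beyond them. The
#' mapping is monotone non-decreasing. A constant image (degenerate
#' percentiles) maps to all zeros.
#'
#' @param x Numeric matrix.
#' @param p_low,p_high Clipping percentiles (defaults 0.35% and 99.65%).
#' @param bit_depth Output dynamic range (default 16).
#' @return Stretched matrix in `[0, 2^bit_depth - 1]`.
#' @export
contrast_stretch <- function(x, p_low = 0.0035, p_high = 0.9965,
                             bit_depth = 16L) {
  if (!is.matrix(x)) stop("input must be a 2-D raster")
  q <- stats::quantile(x, c(p_low, p_high), names = FALSE, type = 7)
  top <- 2^bit_depth - 1
  if (q[2] <= q[1]) return(matrix(0, nrow(x), ncol(x)))
  pmin(pmax((x - q[1]) / (q[2] - q[1]), 0), 1) * top
}

#' Preprocess a raw acquisition frame
#'
#' The standard two-step pipeline for raw 16-bit frames: 3x3 adaptive
#' Wiener filtering followed by contrast stretching to full dynamic range.
#' Deterministic.
#'
#' @param raw Numeric matrix (raw counts).
#' @param bit_depth Dynamic range of the output (default 16).
#' @return Preprocessed matrix.
#' @export
preprocess <- function(raw, bit_depth = 16L) {
  if (!is.matrix(raw)) stop("input must be a 2-D raster")
  contrast_stretch(wiener3(raw), bit_depth = bit_depth)
}

#' ROI admission filter
#'
#' Accepts an image for the dataset only when its annotated myocardial
#' structures (all masks pooled) cover at least `min_coverage` of the field
#' of view.
#'
#' @param masks List of `instance_mask` objects for one image.
#' @param meta The image's `image_meta`.
#' @param min_coverage Minimum covered fraction of the FOV (default 0.8).
#' @return Logical: keep this image?
#' @export
roi_admissible <- function(masks, meta, min_coverage = 0.8) {
  stopifnot(inherits(meta, "image_meta"))
  if (length(masks) == 0) return(FALSE)
  cov <- Reduce(`|`, lapply(masks, as_mask_matrix))
  mean(cov) >= min_coverage
}

#' Split specification for dataset partitioning
#'
#' @param test_fraction Fraction of all items held out for testing
#'   (default 0.30).
#' @param val_fraction_of_trainval Fraction of the remaining
#'   train+validation items used for validation (default 0.10).
#' @param seed Integer seed for the shuffle.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(test_fraction = 0.30, val_fraction_of_trainval = 0.10,
                       seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1,
            val_fraction_of_trainval > 0, val_fraction_of_trainval < 1)
  structure(list(test_fraction = test_fraction,
                 val_fraction_of_trainval = val_fraction_of_trainval,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Shuffle and partition a dataset into train/validation/test
#'
#' Counts use round-half-up: `n_test = floor(test_fraction * n + 0.5)`, then
#' `n_val = floor(val_fraction * (n - n_test) + 0.5)` from the remainder,
#' and the rest train. With the defaults and n = 107 this yields the
#' 67/8/32 train/validation/test partition. The shuffle is seeded and the
#' seed recorded in the output.
#'
#' @param n_items Number of items (>= 3).
#' @param spec A `split_spec`.
#' @return List with integer index vectors `train`, `val`, `test`, and the
#'   `seed` used. The three sets partition `1:n_items`.
#' @export
split_dataset <- function(n_items, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"), n_items >= 3)
  n_test <- floor(spec$test_fraction * n_items + 0.5)
  n_val <- floor(spec$val_fraction_of_trainval * (n_items - n_test) + 0.5)
  n_train <- n_items - n_test - n_val
  if (n_test < 1 || n_val < 1 || n_train < 1)
    stop("split produces an empty partition; adjust fractions or n_items")
  set.seed(spec$seed)
  idx <- sample.int(n_items)
  list(train = sort(idx[seq_len(n_train)]),
       val = sort(idx[n_train + seq_len(n_val)]),
       test = sort(idx[n_train + n_val + seq_len(n_test)]),
       seed = spec$seed)
}

# index maps for the three rotations, 0-based pixel coords in a W x H frame:
#   cw  (90 deg clockwise):         (x, y) -> (H - 1 - y, x)
#   ccw (90 deg counter-clockwise): (x, y) -> (y, W - 1 - x)
#   flip (180 deg):                 (x, y) -> (W - 1 - x, H - 1 - y)
rotate_raster <- function(m, direction = c("cw", "ccw", "flip")) {
  direction <- match.arg(direction)
  switch(direction,
    cw   = t(m[nrow(m):1, , drop = FALSE]),
    ccw  = t(m)[ncol(m):1, , drop = FALSE],
    flip = m[nrow(m):1, ncol(m):1, drop = FALSE])
}

rotate_box <- function(box, direction = c("cw", "ccw", "flip"), width, height) {
  direction <- match.arg(direction)
  x0 <- box[["x_min"]]; y0 <- box[["y_min"]]
  x1 <- box[["x_max"]]; y1 <- box[["y_max"]]
  switch(direction,
    cw   = bbox(height - y1, x0, height - y0, x1),
    ccw  = bbox(y0, width - x1, y1, width - x0),
    flip = bbox(width - x1, height - y1, width - x0, height - y0))
}

#' Rotation augmentation in three fixed directions
#'
#' Emits the three rotated copies used for training-set expansion —
#' 90 degrees clockwise, 90 degrees counter-clockwise, and 180 degrees —
#' with masks transformed consistently. 90-degree rotations require a
#' square raster.
#'
#' @param image Numeric matrix.
#' @param masks List of `instance_mask` objects on the same raster.
#' @return Named list (`cw`, `ccw`, `flip`) of `list(image, masks)`.
#' @export
rotate_augment <- function(image, masks = list()) {
  stopifnot(is.matrix(image))
  if (nrow(image) != ncol(image))
    stop("90-degree rotations require a square raster")
  out <- lapply(c(cw = "cw", ccw = "ccw", flip = "flip"), function(dir) {
    list(image = rotate_raster(image, dir),
         masks = lapply(masks, function(m)
           instance_mask(rotate_raster(m$mask, dir), m$label, m$score)))
  })
  out
}

#' Mosaic augmentation: four images into one
#'
#' Downscales each of four same-sized square samples by 2 (block-mean for
#' the image, odd-index subsampling for masks, which preserves labels) and
#' places them into the four quadrants of an output frame of the original
#' size. Quadrant assignment is a seeded permutation. Annotation count is
#' conserved, except that masks whose every foreground pixel falls between
#' subsampling sites would vanish — these raise an error rather than emit
#' an empty instance.
#'
#' @param samples List of exactly 4 `list(image, masks)` entries.
#' @param seed Integer seed for the quadrant shuffle.
#' @return `list(image, masks)` at the original frame size.
#' @export
mosaic_augment <- function(samples, seed = 1L) {
  if (length(samples) != 4) stop("mosaic needs exactly four samples")
  dims <- unique(lapply(samples, function(s) dim(s$image)))
  if (length(dims) != 1) stop("mosaic samples must share dimensions")
  h <- dims[[1]][1]; w <- dims[[1]][2]
  if (h %% 2 != 0 || w %% 2 != 0 || h != w)
    stop("mosaic requires square samples with even side length")
  hh <- h %/% 2; wh <- w %/% 2
  down_img <- function(m)  # 2x2 block mean
    (m[seq(1, h, 2), seq(1, w, 2)] + m[seq(2, h, 2), seq(1, w, 2)] +
     m[seq(1, h, 2), seq(2, w, 2)] + m[seq(2, h, 2), seq(2, w, 2)]) / 4
  down_mask <- function(m) m[seq(1, h, 2), seq(1, w, 2)]  # nearest neighbour
  set.seed(seed)
  quad <- sample.int(4)  # quadrant for each sample: 1 TL, 2 TR, 3 BL, 4 BR
  offs <- list(c(0, 0), c(0, wh), c(hh, 0), c(hh, wh))  # (row, col) offsets
  image <- matrix(0, h, w)
  masks <- list()
  for (s in seq_len(4)) {
    o <- offs[[quad[s]]]
    image[o[1] + seq_len(hh), o[2] + seq_len(wh)] <- down_img(samples[[s]]$image)
    for (m in samples[[s]]$masks) {
      dm <- down_mask(m$mask)
      if (!any(dm))
        stop("mosaic downscaling erased an instance mask (object too thin)")
      full <- matrix(FALSE, h, w)
      full[o[1] + seq_len(hh), o[2] + seq_len(wh)] <- dm
      masks[[length(masks) + 1]] <- instance_mask(full, m$label, m$score)
    }
  }
  list(image = image, masks = masks)
}

#' Weak annotations from pixel-wise masks
#'
#' The box-circumscription step that turns pixel-wise masks into detector
#' training data: one tight bounding box plus label (and the mask's score,
#' if any) per mask.
#'
#' @param masks List of `instance_mask` objects, each non-empty.
#' @return List of `detection` objects (confidence 1 unless the mask
#'   carries a score).
#' @export
masks_to_detector_annotations <- function(masks) {
  lapply(masks, function(m) {
    detection(bbox_from_mask(m), m$label,
              confidence = if (is.na(m$score)) 1 else m$score)
  })
}

#' Expand a training set by rotation and mosaic augmentation
#'
#' Emits every original sample, its three rotated copies, and seeded mosaic
#' compositions of randomly drawn quadruplets; when `target_total` is given,
#' a seeded subsample of the rotation/mosaic pool is drawn so the output has
#' exactly that many samples (originals are always kept).
#'
#' @param samples List of `list(image, masks)` training samples.
#' @param target_total Optional total output count
#'   (>= `length(samples)`).
#' @param mosaic Logical: include mosaic compositions (default TRUE).
#' @param seed Integer seed.
#' @return List of `list(image, masks)` samples.
#' @export
augment_dataset <- function(samples, target_total = NULL, mosaic = TRUE,
                            seed = 1L) {
  n <- length(samples)
  stopifnot(n >= 1)
  set.seed(seed)
  pool <- list()
  for (s in samples) pool <- c(pool, unname(rotate_augment(s$image, s$masks)))
  if (mosaic && n >= 1) {
    n_mosaic <- max(1L, n %/% 4L)
    for (k in seq_len(n_mosaic)) {
      pick <- sample.int(n, 4, replace = n < 4)
      pool[[length(pool) + 1]] <-
        mosaic_augment(samples[pick], seed = seed + k)
    }
  }
  if (!is.null(target_total)) {
    stopifnot(target_total >= n)
    extra <- min(target_total - n, length(pool))
    pool <- pool[sample.int(length(pool))[seq_len(extra)]]
  }
  c(samples, pool)
}
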