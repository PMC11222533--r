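# Coordinate conventions used throughout the package:
#  * masks are logical matrices with dim = c(height, width); matrix row r
#    holds pixel row y = r - 1, matrix column c holds pixel column x = c - 1
#    (0-based pixel coordinates, like COCO rasters)
#  * bounding boxes are half-open: [x_min, x_max) x [y_min, y_max), so
#    area = (x_max - x_min) * (y_max - y_min) exactly for pixel-aligned boxes

CLASS_LABELS <- c("CM", "CAP")

#' Image metadata: pixel grid and physical field of view
#'
#' Describes the acquisition geometry of one image: pixel dimensions, field
#' of view in micrometres, and bit depth. The per-axis pixel size in
#' micrometres is derived as `fov_um / c(width_px, height_px)` and is the
#' single source of physical units for area measurements.
#'
#' @param width_px,height_px Positive integer pixel dimensions.
#' @param fov_um Physical field of view, micrometres; length-1 (square) or
#'   length-2 `c(width, height)`.
#' @param bit_depth Integer bit depth of the raster (default 16).
#' @return An object of class `image_meta` with fields `width_px`,
#'   `height_px`, `fov_um`, `bit_depth` and derived `pixel_size_um`
#'   (`c(x, y)` in micrometres per pixel).
#' @examples
#' meta <- image_meta(512, 512, fov_um = 42.5)
#' meta$pixel_size_um
#' @export
image_meta <- function(width_px, height_px, fov_um = 42.5, bit_depth = 16L) {
  stopifnot(length(width_px) == 1, length(height_px) == 1,
            width_px >= 1, height_px >= 1,
            width_px == as.integer(width_px), height_px == as.integer(height_px))
  if (length(fov_um) == 1) fov_um <- c(fov_um, fov_um)
  stopifnot(length(fov_um) == 2, all(is.finite(fov_um)), all(fov_um > 0))
  structure(list(
    width_px = as.integer(width_px),
    height_px = as.integer(height_px),
    fov_um = as.numeric(fov_um),
    bit_depth = as.integer(bit_depth),
    pixel_size_um = as.numeric(fov_um) / c(width_px, height_px)
  ), class = "image_meta")
}

#' @export
print.image_meta <- function(x, ...) {
  cat(sprintf("<image_meta> %d x %d px, FOV %.4g x %.4g um, %d-bit (pixel %.4g x %.4g um)\n",
              x$width_px, x$height_px, x$fov_um[1], x$fov_um[2], x$bit_depth,
              x$pixel_size_um[1], x$pixel_size_um[2]))
  invisible(x)
}

#' Construct a bounding box
#'
#' Boxes are axis-aligned, in 0-based pixel coordinates, and half-open:
#' the box covers `[x_min, x_max) x [y_min, y_max)`, so a box circumscribing
#' a single pixel at (0, 0) is `bbox(0, 0, 1, 1)` and its area is 1.
#'
#' @param x_min,y_min,x_max,y_max Box corners; must satisfy
#'   `x_max > x_min`, `y_max > y_min`.
#' @return A named numeric vector of class `bbox`.
#' @export
bbox <- function(x_min, y_min, x_max, y_max) {
  b <- c(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
         x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  if (any(!is.finite(b))) stop("bbox coordinates must be finite")
  if (b["x_max"] <= b["x_min"] || b["y_max"] <= b["y_min"])
    stop("degenerate bbox: x_max must exceed x_min and y_max must exceed y_min")
  class(b) <- "bbox"
  b
}

is_bbox <- function(b) inherits(b, "bbox")

bbox_width  <- function(b) unname(b["x_max"] - b["x_min"])
bbox_height <- function(b) unname(b["y_max"] - b["y_min"])

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox> [%.6g, %.6g) x [%.6g, %.6g)\n",
              x["x_min"], x["x_max"], x["y_min"], x["y_max"]))
  invisible(x)
}

#' Construct a labeled instance mask
#'
#' An instance is a binary raster with a class label (`"CM"` for
#' cardiomyocyte, `"CAP"` for capillary) and an optional confidence score.
#'
#' @param mask Logical (or coercible 0/1) matrix, `dim = c(height, width)`.
#' @param label `"CM"` or `"CAP"`.
#' @param score Optional confidence in `[0, 1]`; `NA` when absent.
#' @return An object of class `instance_mask`.
#' @export
instance_mask <- function(mask, label, score = NA_real_) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (!is.logical(mask)) {
    storage.mode(mask) <- "double"
    mask <- mask != 0
  }
  label <- match.arg(label, CLASS_LABELS)
  if (!is.na(score) && (score < 0 || score > 1)) stop("score must lie in [0, 1]")
  structure(list(mask = mask, label = label, score = as.numeric(score)),
            class = "instance_mask")
}

#' @export
print.instance_mask <- function(x, ...) {
  cat(sprintf("<instance_mask> %s, %d px foreground in %d x %d raster%s\n",
              x$label, sum(x$mask), ncol(x$mask), nrow(x$mask),
              if (is.na(x$score)) "" else sprintf(", score %.3f", x$score)))
  invisible(x)
}

as_mask_matrix <- function(m) {
  if (inherits(m, "instance_mask")) m$mask else m
}

#' Tightest bounding box of a mask
#'
#' Returns the smallest axis-aligned box containing every foreground pixel,
#' in half-open convention (`x_max` = largest foreground column index + 1).
#' This is the box-circumscription step used to derive weak (bounding-box)
#' annotations from pixel-wise masks.
#'
#' @param mask An `instance_mask` or logical matrix with at least one
#'   foreground pixel.
#' @return A `bbox`. Errors on an empty mask rather than returning a
#'   degenerate box.
#' @examples
#' m <- matrix(FALSE, 10, 10); m[4:8, 3:6] <- TRUE  # rows 3..7, cols 2..5
#' bbox_from_mask(m)  # (2, 3, 6, 8)
#' @export
bbox_from_mask <- function(mask) {
  m <- as_mask_matrix(mask)
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("cannot take the bounding box of an empty mask")
  bbox(x_min = min(idx[, 2]) - 1, y_min = min(idx[, 1]) - 1,
       x_max = max(idx[, 2]),     y_max = max(idx[, 1]))
}

#' Geometric centre of a bounding box
#'
#' The centroid attached to each detection box; prompts are built from these
#' box centres because at inference time only detections (no masks) exist.
#'
#' @param box A `bbox`.
#' @return Numeric `c(x, y)`.
#' @export
bbox_centroid <- function(box) {
  stopifnot(is_bbox(box))
  c(x = unname(box["x_min"] + box["x_max"]) / 2,
    y = unname(box["y_min"] + box["y_max"]) / 2)
}

#' Point-in-box membership (half-open)
#'
#' `TRUE` iff `x_min <= x < x_max` and `y_min <= y < y_max`. The lower
#' edges are inclusive and the upper edges exclusive so boundary ties are
#' resolved deterministically.
#'
#' @param p Numeric `c(x, y)`.
#' @param box A `bbox`.
#' @return Logical scalar.
#' @export
point_in_box <- function(p, box) {
  stopifnot(is_bbox(box), length(p) >= 2)
  p[[1]] >= box[["x_min"]] && p[[1]] < box[["x_max"]] &&
    p[[2]] >= box[["y_min"]] && p[[2]] < box[["y_max"]]
}

#' Intersection over union of two masks
#'
#' Pixelwise IoU between a predicted and a ground-truth mask; the overlap
#' measure that gates outcome classification in evaluation.
#'
#' @param m_p,m_gt `instance_mask` objects or logical matrices of identical
#'   dimensions.
#' @return IoU in `[0, 1]`. Errors when the rasters disagree in shape or
#'   when both masks are empty (the union is empty and IoU undefined).
#' @export
mask_iou <- function(m_p, m_gt) {
  a <- as_mask_matrix(m_p); b <- as_mask_matrix(m_gt)
  if (!identical(dim(a), dim(b))) stop("mask dimensions differ")
  uni <- sum(a | b)
  if (uni == 0) stop("IoU undefined: both masks are empty")
  sum(a & b) / uni
}

#' Physical mask area in square micrometres
#'
#' Foreground pixel count times the per-pixel physical area from the image
#' metadata. With the default acquisition geometry (512 x 512 px over a
#' 42.5 um square field of view) a full-frame mask measures 1806.25 um^2.
#'
#' @param mask An `instance_mask` or logical matrix.
#' @param meta An `image_meta` whose dimensions match the mask.
#' @return Area in um^2 (0 for an empty mask).
#' @export
mask_area_um2 <- function(mask, meta) {
  m <- as_mask_matrix(mask)
  stopifnot(inherits(meta, "image_meta"))
  if (nrow(m) != meta$height_px || ncol(m) != meta$width_px)
    stop("mask dimensions do not match image metadata")
  sum(m) * meta$pixel_size_um[1] * meta$pixel_size_um[2]
}

# Pixel footprint of a (possibly fractional) box, clipped to the raster:
# matrix rows/cols (1-based) covered by the half-open box. Fractionally
# covered pixels are included.
box_pixel_range <- function(box, height, width) {
  rows <- max(1L, floor(box[["y_min"]]) + 1L):min(height, ceiling(box[["y_max"]]))
  cols <- max(1L, floor(box[["x_min"]]) + 1L):min(width, ceiling(box[["x_max"]]))
  if (box[["y_min"]] >= height || box[["y_max"]] <= 0 ||
      box[["x_min"]] >= width || box[["x_max"]] <= 0)
    stop("box lies entirely outside the raster")
  list(rows = rows, cols = cols)
}

# Clip a logical mask to a box footprint (coarse-constraint enforcement).
clip_mask_to_box <- function(mask, box) {
  m <- as_mask_matrix(mask)
  keep <- matrix(FALSE, nrow(m), ncol(m))
  rng <- box_pixel_range(box, nrow(m), ncol(m))
  keep[rng$rows, rng$cols] <- TRUE
  m & keep
}
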