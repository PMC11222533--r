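# Standard-format I/O: 16-bit TIFF / PNG rasters, COCO JSON instance
# annotations (uncompressed RLE or polygon segmentations), COCO detection
# JSON, YOLO-txt boxes, and labeled instance-index TIFFs. Category ids are
# fixed: CM = 1, CAP = 2 (YOLO classes 0 and 1).

COCO_CATEGORIES <- data.frame(id = c(1L, 2L), name = c("CM", "CAP"))

label_to_category <- function(label) match(label, COCO_CATEGORIES$name)
category_to_label <- function(id) COCO_CATEGORIES$name[match(id, COCO_CATEGORIES$id)]

#' Read a grayscale image raster
#'
#' Reads TIFF or PNG into a numeric matrix of raster counts, with matrix
#' rows as image rows. 16-bit TIFFs are read at native integer counts;
#' PNG values are rescaled from `[0, 1]` to the requested bit depth.
#'
#' @param path File path (`.tif`, `.tiff`, or `.png`).
#' @param bit_depth Count range used to rescale PNG input (default 16).
#' @return Numeric matrix.
#' @export
read_image <- function(path, bit_depth = 16L) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    img <- png::readPNG(path) * (2^bit_depth - 1)
  } else stop("unsupported image format: ", ext)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Write a grayscale image raster
#'
#' Writes a numeric count matrix as 16-bit TIFF or (8-bit) PNG.
#'
#' @param img Numeric matrix in `[0, 2^bit_depth - 1]`.
#' @param path Output path; format chosen by extension.
#' @param bit_depth Count range of `img` (default 16).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bit_depth = 16L) {
  stopifnot(is.matrix(img))
  norm <- pmin(pmax(img / (2^bit_depth - 1), 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    png::writePNG(norm, path)
  } else stop("unsupported image format: ", ext)
  invisible(path)
}

# --- COCO run-length encoding (uncompressed counts, column-major order,
# --- first count is the number of leading background pixels)

rle_encode_mask <- function(mask) {
  v <- as.integer(as.vector(mask))  # column-major, matching COCO order
  r <- rle(v)
  counts <- r$lengths
  if (r$values[1] != 0) counts <- c(0L, counts)
  list(counts = as.integer(counts), size = dim(mask))
}

rle_decode_mask <- function(counts, size) {
  v <- rep(rep(c(0L, 1L), length.out = length(counts)), counts)
  stopifnot(length(v) == prod(size))
  matrix(v == 1L, size[1], size[2])
}

# Even-odd scanline rasterization of a COCO polygon ring
# (flat [x1,y1,x2,y2,...]); a pixel is foreground when its centre lies
# inside the ring.
rasterize_polygon <- function(xy, height, width) {
  px <- xy[seq(1, length(xy), 2)]; py <- xy[seq(2, length(xy), 2)]
  n <- length(px)
  m <- matrix(FALSE, height, width)
  for (r in seq_len(height)) {
    yc <- r - 0.5
    xs <- numeric(0)
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1 else k + 1
      y1 <- py[k]; y2 <- py[k2]
      if ((y1 <= yc && y2 > yc) || (y2 <= yc && y1 > yc))
        xs <- c(xs, px[k] + (yc - y1) / (y2 - y1) * (px[k2] - px[k]))
    }
    if (length(xs) == 0) next
    xs <- sort(xs)
    for (k in seq(1, length(xs) - 1, by = 2)) {
      c0 <- max(1L, ceiling(xs[k] + 0.5))
      c1 <- min(width, floor(xs[k + 1] + 0.5))
      if (c1 >= c0) m[r, c0:c1] <- TRUE
    }
  }
  m
}

#' Write instance masks as a COCO JSON dataset
#'
#' One image entry per element of `masks_by_image`; each mask becomes an
#' annotation with uncompressed-RLE segmentation, tight `[x, y, w, h]`
#' bounding box, pixel area, category id (CM = 1, CAP = 2) and, when
#' present, a score. Integer-aligned boxes round-trip bit-exactly.
#'
#' @param masks_by_image List (one element per image) of lists of
#'   `instance_mask`.
#' @param meta Shared `image_meta`.
#' @param path Output path.
#' @param file_names Optional image file names recorded in the JSON.
#' @return `path`, invisibly.
#' @export
write_coco <- function(masks_by_image, meta, path,
                       file_names = sprintf("image_%03d.tif",
                                            seq_along(masks_by_image))) {
  stopifnot(inherits(meta, "image_meta"))
  images <- lapply(seq_along(masks_by_image), function(i) list(
    id = i, width = meta$width_px, height = meta$height_px,
    file_name = file_names[[i]]))
  annotations <- list(); aid <- 0L
  for (i in seq_along(masks_by_image)) for (m in masks_by_image[[i]]) {
    aid <- aid + 1L
    b <- bbox_from_mask(m)
    ann <- list(
      id = aid, image_id = i,
      category_id = label_to_category(m$label),
      segmentation = rle_encode_mask(m$mask),
      bbox = c(b[["x_min"]], b[["y_min"]], bbox_width(b), bbox_height(b)),
      area = sum(m$mask), iscrowd = 0L)
    if (!is.na(m$score)) ann$score <- m$score
    annotations[[aid]] <- ann
  }
  payload <- list(images = images, annotations = annotations,
                  categories = lapply(seq_len(nrow(COCO_CATEGORIES)),
                                      function(k) as.list(COCO_CATEGORIES[k, ])))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a COCO JSON dataset into instance masks
#'
#' Supports uncompressed-RLE and polygon segmentations; an annotation with
#' no segmentation yields a box-filled mask (the box interpreted as a
#' rectangle of foreground).
#'
#' @param path COCO JSON path.
#' @return List with `meta` (an `image_meta` from the first image entry),
#'   `masks_by_image` (list of lists of `instance_mask`, indexed by image
#'   id), and `file_names`.
#' @export
read_coco <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  stopifnot(length(payload$images) >= 1)
  img1 <- payload$images[[1]]
  meta <- image_meta(img1$width, img1$height)
  h <- meta$height_px; w <- meta$width_px
  masks_by_image <- rep(list(list()), length(payload$images))
  for (ann in payload$annotations) {
    seg <- ann$segmentation
    if (is.null(seg)) {
      b <- as.numeric(ann$bbox)
      m <- matrix(FALSE, h, w)
      rng <- box_pixel_range(bbox(b[1], b[2], b[1] + b[3], b[2] + b[4]), h, w)
      m[rng$rows, rng$cols] <- TRUE
    } else if (!is.null(seg$counts)) {
      m <- rle_decode_mask(as.integer(unlist(seg$counts)),
                           as.integer(unlist(seg$size)))
    } else {
      rings <- lapply(seg, function(ring) as.numeric(unlist(ring)))
      m <- Reduce(`|`, lapply(rings, rasterize_polygon, height = h, width = w))
    }
    score <- if (is.null(ann$score)) NA_real_ else ann$score
    im <- instance_mask(m, category_to_label(ann$category_id), score)
    iid <- ann$image_id
    masks_by_image[[iid]] <- c(masks_by_image[[iid]], list(im))
  }
  list(meta = meta, masks_by_image = masks_by_image,
       file_names = vapply(payload$images, `[[`, character(1), "file_name"))
}

#' Write detections as COCO detection JSON
#'
#' The flat COCO results format:
#' `[{image_id, category_id, bbox [x,y,w,h], score}, ...]`.
#'
#' @param detections A `detection_set`.
#' @param path Output path.
#' @param image_id Image id recorded for every detection (default 1).
#' @return `path`, invisibly.
#' @export
write_coco_detections <- function(detections, path, image_id = 1L) {
  stopifnot(inherits(detections, "detection_set"))
  payload <- lapply(detections$detections, function(d) list(
    image_id = image_id,
    category_id = label_to_category(d$label),
    bbox = c(d$box[["x_min"]], d$box[["y_min"]],
             bbox_width(d$box), bbox_height(d$box)),
    score = d$confidence))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read COCO detection JSON
#'
#' @param path COCO detection results path.
#' @return A `detection_set` (all images pooled).
#' @export
read_coco_detections <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  detection_set(lapply(payload, function(d) {
    b <- as.numeric(unlist(d$bbox))
    detection(bbox(b[1], b[2], b[1] + b[3], b[2] + b[4]),
              category_to_label(d$category_id),
              confidence = if (is.null(d$score)) 1 else d$score)
  }))
}

#' Write detections in YOLO-txt format
#'
#' One line per detection: `class cx cy w h` with class 0 = CM, 1 = CAP and
#' box centre/size normalized by the image dimensions (6 decimal places, so
#' boxes round-trip within half a pixel).
#'
#' @param detections A `detection_set`.
#' @param meta The image's `image_meta` (for normalization).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_yolo <- function(detections, meta, path) {
  stopifnot(inherits(detections, "detection_set"), inherits(meta, "image_meta"))
  lines <- vapply(detections$detections, function(d) {
    cen <- bbox_centroid(d$box)
    sprintf("%d %.6f %.6f %.6f %.6f",
            label_to_category(d$label) - 1L,
            cen[["x"]] / meta$width_px, cen[["y"]] / meta$height_px,
            bbox_width(d$box) / meta$width_px,
            bbox_height(d$box) / meta$height_px)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read YOLO-txt detections
#'
#' @param path YOLO-txt path.
#' @param meta The image's `image_meta` (to denormalize).
#' @return A `detection_set` (confidence 1, or the optional 6th column).
#' @export
read_yolo <- function(path, meta) {
  stopifnot(inherits(meta, "image_meta"))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  detection_set(lapply(lines, function(ln) {
    f <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    cx <- f[2] * meta$width_px; cy <- f[3] * meta$height_px
    bw <- f[4] * meta$width_px; bh <- f[5] * meta$height_px
    detection(bbox(cx - bw / 2, cy - bh / 2, cx + bw / 2, cy + bh / 2),
              category_to_label(f[1] + 1L),
              confidence = if (length(f) >= 6) f[6] else 1)
  }))
}

#' Write instance masks as a labeled 16-bit index TIFF
#'
#' Pixel value k marks mask k (0 = background); class labels are stored in
#' a JSON sidecar `<path>.labels.json`. Requires pairwise-disjoint masks.
#'
#' @param masks List of `instance_mask` objects.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_instance_tiff <- function(masks, path) {
  stopifnot(length(masks) >= 1, length(masks) < 2^16)
  d <- dim(masks[[1]]$mask)
  idx <- matrix(0L, d[1], d[2])
  for (k in seq_along(masks)) {
    m <- masks[[k]]$mask
    if (any(idx[m] != 0L)) stop("instance-index TIFF requires disjoint masks")
    idx[m] <- k
  }
  tiff::writeTIFF(idx / (2^16 - 1), path, bits.per.sample = 16L)
  jsonlite::write_json(
    lapply(masks, function(m) list(label = m$label, score = m$score)),
    paste0(path, ".labels.json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a labeled instance-index TIFF
#'
#' @param path TIFF path written by [write_instance_tiff()].
#' @return List of `instance_mask` objects.
#' @export
read_instance_tiff <- function(path) {
  idx <- round(tiff::readTIFF(path) * (2^16 - 1))
  labels <- jsonlite::fromJSON(paste0(path, ".labels.json"),
                               simplifyVector = FALSE)
  lapply(seq_along(labels), function(k)
    instance_mask(idx == k, labels[[k]]$label,
                  if (is.null(labels[[k]]$score)) NA_real_
                  else labels[[k]]$score))
}
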