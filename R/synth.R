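# Synthetic basement-membrane-style scenes with exact ground truth. The
# generator emulates the geometry that motivates the fine-constraint prompt
# design: a dense tessellation of non-convex cardiomyocyte profiles whose
# bounding boxes overlap, with small capillary rings wedged at cell
# junctions whose boxes are frequently enclosed by CM boxes. Rendering
# follows the staining polarity of basement-membrane immunofluorescence:
# bright ridges (membrane) around dark interiors (cytoplasm, lumens).

#' Synthetic scene specification
#'
#' Fully determines a scene together with its `seed`.
#'
#' @param n_cm Number of cardiomyocyte profiles to tessellate.
#' @param caps_per_cm Mean number of capillaries per CM (capillary count is
#'   `round(caps_per_cm * n_cm)`, subject to placement feasibility).
#' @param shape_irregularity In `[0, 1]`: 0 gives near-convex blobs, 1
#'   strongly lobed non-convex profiles (lobing drives CM-box overlap).
#' @param membrane_thickness_px Erosion depth separating adjacent interiors;
#'   the rendered bright ridge between two cells is about twice this.
#' @param noise_sd Gaussian noise SD in raster counts (0 = noiseless).
#' @param meta An `image_meta` (default 512 x 512 px, 42.5 um FOV, 16-bit).
#' @param seed Integer seed; `(spec, seed)` fully determines the scene.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(n_cm = 6, caps_per_cm = 2, shape_irregularity = 0.6,
                       membrane_thickness_px = 2L, noise_sd = 800,
                       meta = image_meta(512, 512, fov_um = 42.5), seed = 1L) {
  stopifnot(n_cm >= 1, caps_per_cm >= 0,
            shape_irregularity >= 0, shape_irregularity <= 1,
            membrane_thickness_px >= 1, noise_sd >= 0,
            inherits(meta, "image_meta"))
  structure(list(n_cm = as.integer(n_cm), caps_per_cm = caps_per_cm,
                 shape_irregularity = shape_irregularity,
                 membrane_thickness_px = as.integer(membrane_thickness_px),
                 noise_sd = noise_sd, meta = meta, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Named scene presets
#'
#' `"default"` is the dense regime that exercises fine constraints
#' (6 lobed CMs, ~2 capillaries per CM, moderate noise). `"easy"` keeps the
#' same layout but with mild lobing and no noise — the clean closed-loop
#' benchmark setting.
#'
#' @param name `"default"` or `"easy"`.
#' @param meta Optional `image_meta` override.
#' @param seed Integer seed.
#' @return A `scene_spec`.
#' @export
scene_preset <- function(name = c("default", "easy"),
                         meta = image_meta(512, 512, fov_um = 42.5),
                         seed = 1L) {
  name <- match.arg(name)
  switch(name,
    default = scene_spec(n_cm = 6, caps_per_cm = 2, shape_irregularity = 0.6,
                         membrane_thickness_px = 2L, noise_sd = 800,
                         meta = meta, seed = seed),
    easy    = scene_spec(n_cm = 6, caps_per_cm = 2, shape_irregularity = 0.2,
                         membrane_thickness_px = 2L, noise_sd = 0,
                         meta = meta, seed = seed))
}

# Lobed-cell tessellation: each cell has a seed point and an angular radial
# warp w(theta) >= 1 - irregularity; pixels are assigned to the cell with
# the smallest warped distance r / w(theta), which yields non-convex,
# interlocking profiles as irregularity grows.
.tessellate <- function(spec) {
  h <- spec$meta$height_px; w <- spec$meta$width_px; n <- spec$n_cm
  nc <- ceiling(sqrt(n)); nr <- ceiling(n / nc)
  cx0 <- (rep(seq_len(nc), times = nr)[seq_len(n)] - 0.5) * w / nc
  cy0 <- (rep(seq_len(nr), each = nc)[seq_len(n)] - 0.5) * h / nr
  sx <- cx0 + stats::runif(n, -0.2, 0.2) * w / nc
  sy <- cy0 + stats::runif(n, -0.2, 0.2) * h / nr
  k1 <- sample(2:4, n, replace = TRUE); k2 <- sample(3:5, n, replace = TRUE)
  a1 <- stats::runif(n, 0.5, 1); a2 <- stats::runif(n, 0.5, 1)
  p1 <- stats::runif(n, 0, 2 * pi); p2 <- stats::runif(n, 0, 2 * pi)
  X <- matrix(rep(seq_len(w) - 1, each = h), h, w)
  Y <- matrix(rep(seq_len(h) - 1, times = w), h, w)
  D <- matrix(Inf, h * w, n)
  for (i in seq_len(n)) {
    dx <- X - sx[i]; dy <- Y - sy[i]
    r <- sqrt(dx^2 + dy^2); th <- atan2(dy, dx)
    warp <- 1 + spec$shape_irregularity *
      (a1[i] * cos(k1[i] * th + p1[i]) + a2[i] * cos(k2[i] * th + p2[i])) / 2
    D[, i] <- r / pmax(warp, 0.05)
  }
  matrix(max.col(-D, ties.method = "first"), h, w)
}

# Draw a filled disk as a logical matrix (pixel centres at integer coords).
.disk_mask <- function(h, w, cx, cy, r) {
  rows <- max(1, floor(cy - r)):min(h, ceiling(cy + r))
  cols <- max(1, floor(cx - r)):min(w, ceiling(cx + r))
  m <- matrix(FALSE, h, w)
  dy2 <- ((rows - 1) - cy)^2
  for (jc in seq_along(cols)) {
    dx2 <- ((cols[jc] - 1) - cx)^2
    m[rows[dx2 + dy2 <= r^2], cols[jc]] <- TRUE
  }
  m
}

#' Generate a synthetic myocardial cross-section scene
#'
#' Tessellates the frame into `n_cm` lobed cell profiles, erodes each by
#' `membrane_thickness_px` so bright membrane ridges separate dark
#' interiors, wedges ring-shaped capillaries at cell junctions (dark lumen
#' inside a bright ring), renders the scene at the metadata's bit depth and
#' adds Gaussian noise. Ground-truth instance masks are the dark phases:
#' eroded (and capillary-carved) CM interiors and capillary lumens; they
#' are pairwise disjoint by construction.
#'
#' @param spec A `scene_spec`.
#' @return A list with `image` (numeric matrix in raster counts), `masks`
#'   (list of `instance_mask`, CMs then CAPs), `meta`, and `spec`.
#' @examples
#' sc <- generate_scene(scene_preset("easy", meta = image_meta(128, 128)))
#' length(sc$masks)
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  h <- spec$meta$height_px; w <- spec$meta$width_px
  assign <- .tessellate(spec)

  brush <- EBImage::makeBrush(2L * spec$membrane_thickness_px + 1L, "disc")
  pad <- spec$membrane_thickness_px + 1L
  interiors <- lapply(seq_len(spec$n_cm), function(i) {
    # zero-pad so the frame edge erodes like any other cell boundary
    padded <- matrix(0, h + 2L * pad, w + 2L * pad)
    padded[pad + seq_len(h), pad + seq_len(w)] <- as.numeric(assign == i)
    er <- EBImage::erode(padded, brush)
    er[pad + seq_len(h), pad + seq_len(w)] > 0.5
  })

  # capillaries at junctions: candidate sites are tessellation boundary
  # pixels; accepted sites keep a separation margin from each other and the
  # frame edge
  n_cap_target <- round(spec$caps_per_cm * spec$n_cm)
  caps <- list()
  if (n_cap_target > 0) {
    boundary <- matrix(FALSE, h, w)
    boundary[-h, ] <- boundary[-h, ] | (assign[-h, ] != assign[-1, ])
    boundary[, -w] <- boundary[, -w] | (assign[, -w] != assign[, -1])
    r_max <- 0.055 * min(h, w)
    margin <- ceiling(r_max + 2 * spec$membrane_thickness_px + 2)
    cand <- which(boundary, arr.ind = TRUE)
    cand <- cand[cand[, 1] > margin & cand[, 1] <= h - margin &
                 cand[, 2] > margin & cand[, 2] <= w - margin, , drop = FALSE]
    cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
    min_sep <- 2 * (r_max + 2 * spec$membrane_thickness_px + 1)
    placed <- matrix(numeric(0), 0, 2)
    k <- 1
    while (length(caps) < n_cap_target && k <= nrow(cand)) {
      cy <- cand[k, 1] - 1; cx <- cand[k, 2] - 1
      k <- k + 1
      if (nrow(placed) > 0 &&
          any((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2 < min_sep^2)) next
      r_in <- stats::runif(1, 0.035, 0.055) * min(h, w)
      caps[[length(caps) + 1]] <- list(
        cx = cx, cy = cy, r_in = r_in,
        r_out = r_in + 2 * spec$membrane_thickness_px)
      placed <- rbind(placed, c(cx, cy))
    }
  }

  # carve capillary footprints (lumen + ring) out of CM interiors so ground
  # truth stays disjoint and ridges render around every lumen
  cap_lumen <- matrix(FALSE, h, w); cap_foot <- matrix(FALSE, h, w)
  for (cp in caps) {
    cap_lumen <- cap_lumen | .disk_mask(h, w, cp$cx, cp$cy, cp$r_in)
    cap_foot <- cap_foot | .disk_mask(h, w, cp$cx, cp$cy, cp$r_out)
  }
  masks <- list()
  for (i in seq_len(spec$n_cm)) {
    m <- interiors[[i]] & !cap_foot
    if (!any(m))
      stop("infeasible scene spec: a cell interior vanished; reduce n_cm, ",
           "membrane thickness, or capillary load")
    masks[[length(masks) + 1]] <- instance_mask(m, "CM")
  }
  for (cp in caps)
    masks[[length(masks) + 1]] <-
      instance_mask(.disk_mask(h, w, cp$cx, cp$cy, cp$r_in), "CAP")

  dark_phase <- Reduce(`|`, lapply(masks, `[[`, "mask"),
                       matrix(FALSE, h, w))
  max_count <- 2^spec$meta$bit_depth - 1
  img <- matrix(0.75 * max_count, h, w)
  img[dark_phase] <- 0.12 * max_count
  if (spec$noise_sd > 0)
    img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
  img <- round(pmin(pmax(img, 0), max_count))

  list(image = img, masks = masks, meta = spec$meta, spec = spec)
}

#' Packing statistics of a labeled mask set
#'
#' Quantifies the dense-packing phenomena that make fine constraints
#' necessary: how often capillary boxes are fully enclosed by a CM box and
#' how often CM boxes overlap each other.
#'
#' @param masks List of `instance_mask` objects.
#' @return A list: `n_cm`, `n_cap`, `cap_enclosed_fraction` (fraction of CAP
#'   boxes fully inside at least one CM box; `NaN` when no CAPs),
#'   `cm_box_overlap_rate` (fraction of CM box pairs that intersect; `NaN`
#'   with fewer than 2 CMs).
#' @export
scene_statistics <- function(masks) {
  labs <- vapply(masks, `[[`, character(1), "label")
  boxes <- lapply(masks, bbox_from_mask)
  cm <- boxes[labs == "CM"]; cap <- boxes[labs == "CAP"]
  enclosed <- function(a, b)  # a fully inside b
    a[["x_min"]] >= b[["x_min"]] && a[["y_min"]] >= b[["y_min"]] &&
    a[["x_max"]] <= b[["x_max"]] && a[["y_max"]] <= b[["y_max"]]
  intersects <- function(a, b)
    a[["x_min"]] < b[["x_max"]] && b[["x_min"]] < a[["x_max"]] &&
    a[["y_min"]] < b[["y_max"]] && b[["y_min"]] < a[["y_max"]]
  cap_enc <- if (length(cap) == 0) NaN else
    mean(vapply(cap, function(cb)
      any(vapply(cm, function(mb) enclosed(cb, mb), logical(1))), logical(1)))
  ov <- if (length(cm) < 2) NaN else {
    pairs <- utils::combn(length(cm), 2)
    mean(vapply(seq_len(ncol(pairs)), function(k)
      intersects(cm[[pairs[1, k]]], cm[[pairs[2, k]]]), logical(1)))
  }
  list(n_cm = sum(labs == "CM"), n_cap = sum(labs == "CAP"),
       cap_enclosed_fraction = cap_enc, cm_box_overlap_rate = ov)
}
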