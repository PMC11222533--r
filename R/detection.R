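# Object-detector contract. The production detector in the original method
# is a trained YOLO-family network; here it is an adapter slot behind a
# registry, and the shipped adapter is a ground-truth-backed oracle that
# turns annotation masks into (optionally jittered) detections so the whole
# pipeline runs and is testable without any trained weights.

.detector_registry <- new.env(parent = emptyenv())

#' Register a detector adapter
#'
#' An adapter is a function `function(image, config) -> detection_set`.
#' Registered adapters are selected by name through [detect()].
#'
#' @param name Adapter identifier.
#' @param fn Adapter function.
#' @export
register_detector <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  assign(name, fn, envir = .detector_registry)
  invisible(name)
}

#' List registered detector adapters
#' @return Character vector of adapter names.
#' @export
list_detectors <- function() ls(.detector_registry)

#' Detector configuration
#'
#' @param adapter_name Registered adapter to use (default `"oracle"`).
#' @param confidence_threshold Minimum confidence to keep, in `[0, 1]`.
#' @param max_detections Cap on the number of detections returned.
#' @param annotations For the oracle adapter: list of `instance_mask`
#'   ground-truth annotations backing the detections.
#' @param jitter_px Oracle adapter: uniform box-edge jitter half-width in
#'   pixels (0 = tight ground-truth boxes).
#' @param seed Oracle adapter: seed for the jitter draw.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(adapter_name = "oracle", confidence_threshold = 0,
                            max_detections = 1000L, annotations = NULL,
                            jitter_px = 0, seed = 1L) {
  stopifnot(confidence_threshold >= 0, confidence_threshold <= 1,
            max_detections >= 1, jitter_px >= 0)
  structure(list(adapter_name = adapter_name,
                 confidence_threshold = confidence_threshold,
                 max_detections = as.integer(max_detections),
                 annotations = annotations,
                 jitter_px = jitter_px, seed = as.integer(seed)),
            class = "detector_config")
}

#' Run the configured detector on an image
#'
#' Dispatches to the registered adapter, then applies the shared contract:
#' detections below the confidence threshold are dropped, boxes are clipped
#' to the image bounds, and the result is stably sorted by descending
#' confidence (ties broken by `x_min`, then `y_min`).
#'
#' @param image 2-D numeric raster.
#' @param config A `detector_config`.
#' @return A `detection_set`.
#' @export
detect <- function(image, config) {
  stopifnot(is.matrix(image), inherits(config, "detector_config"))
  if (!exists(config$adapter_name, envir = .detector_registry))
    stop(sprintf("unknown detector adapter '%s' (registered: %s)",
                 config$adapter_name,
                 paste(list_detectors(), collapse = ", ")))
  fn <- get(config$adapter_name, envir = .detector_registry)
  ds <- fn(image, config)
  stopifnot(inherits(ds, "detection_set"))
  dets <- Filter(function(d) d$confidence >= config$confidence_threshold,
                 ds$detections)
  dets <- lapply(dets, function(d) {
    d$box <- bbox(max(0, d$box[["x_min"]]), max(0, d$box[["y_min"]]),
                  min(ncol(image), d$box[["x_max"]]),
                  min(nrow(image), d$box[["y_max"]]))
    d
  })
  if (length(dets) > 1) {
    conf <- vapply(dets, `[[`, numeric(1), "confidence")
    x0 <- vapply(dets, function(d) d$box[["x_min"]], numeric(1))
    y0 <- vapply(dets, function(d) d$box[["y_min"]], numeric(1))
    dets <- dets[order(-conf, x0, y0)]
  }
  if (length(dets) > config$max_detections)
    dets <- dets[seq_len(config$max_detections)]
  detection_set(dets)
}

#' Oracle detector: detections from ground-truth masks
#'
#' Emits one detection per annotation mask — the mask's tight bounding box,
#' its label, confidence 1.0. An optional seeded jitter displaces each box
#' edge independently by Uniform(-jitter_px, +jitter_px) to emulate an
#' imperfect detector; jittered boxes are kept valid (minimum 1 px extent)
#' and within the frame of the mask raster.
#'
#' @param annotations Non-empty list of `instance_mask` objects, each with
#'   at least one foreground pixel.
#' @param jitter_px Jitter half-width in pixels (default 0).
#' @param seed Seed for the jitter draw (default 1).
#' @return A `detection_set` with one detection per annotation, in
#'   annotation order.
#' @export
oracle_detector <- function(annotations, jitter_px = 0, seed = 1L) {
  stopifnot(is.list(annotations))
  if (length(annotations) == 0) return(detection_set())
  rng <- local({
    set.seed(seed)
    function(n) stats::runif(n, -jitter_px, jitter_px)
  })
  dets <- lapply(annotations, function(a) {
    stopifnot(inherits(a, "instance_mask"))
    b <- bbox_from_mask(a)  # errors on an empty mask
    if (jitter_px > 0) {
      j <- rng(4)
      h <- nrow(a$mask); w <- ncol(a$mask)
      x0 <- min(max(0, b[["x_min"]] + j[1]), w - 1)
      y0 <- min(max(0, b[["y_min"]] + j[2]), h - 1)
      x1 <- max(min(w, b[["x_max"]] + j[3]), x0 + 1)
      y1 <- max(min(h, b[["y_max"]] + j[4]), y0 + 1)
      b <- bbox(x0, y0, x1, y1)
    }
    detection(b, a$label, confidence = 1)
  })
  detection_set(dets)
}

# Default adapter: reads ground-truth annotations and jitter settings from
# the detector_config. The image argument is unused beyond bounds clipping
# in detect(); the oracle is annotation-driven by construction.
register_detector("oracle", function(image, config) {
  if (is.null(config$annotations))
    stop("oracle adapter requires ground-truth annotations in the config")
  oracle_detector(config$annotations,
                  jitter_px = config$jitter_px, seed = config$seed)
})
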