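# Prompt-driven segmentation backends. The original method prompts a
# pretrained promptable model (zero-shot, no tuning); that slot exists here
# as a registry entry, and the shipped backend is a deterministic reference
# segmenter built on classical image operations so the pipeline runs with
# no pretrained weights. All backends share one hard contract: a predicted
# mask never leaks outside its prompt box (the box is the maximal range of
# the mask), enforced by post-hoc clipping.

.segmenter_registry <- new.env(parent = emptyenv())

#' Register a segmentation backend
#'
#' A backend is a function `function(image, prompt) -> logical matrix`
#' (full-frame binary mask for one prompt).
#'
#' @param name Backend identifier.
#' @param fn Backend function.
#' @export
register_segmenter <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  assign(name, fn, envir = .segmenter_registry)
  invisible(name)
}

#' List registered segmentation backends
#' @return Character vector of backend names.
#' @export
list_segmenters <- function() ls(.segmenter_registry)

#' Segment an image under a list of prompts
#'
#' Runs the chosen backend once per prompt and returns one mask per prompt,
#' in prompt order, with the prompt's class label attached. Every mask is
#' clipped to its prompt box before being returned, whatever the backend
#' produced. A backend failure for a prompt (no structure found) yields an
#' empty mask flagged in `failed`, not an error.
#'
#' @param image 2-D numeric raster.
#' @param prompts List of `prompt_set` objects.
#' @param backend Registered backend name (default `"reference"`).
#' @return An object of class `segmentation_result`: `instances` (list of
#'   `instance_mask`), `prompt_indices`, and logical `failed` per prompt.
#' @export
segment_with_prompts <- function(image, prompts, backend = "reference") {
  stopifnot(is.matrix(image), is.list(prompts))
  if (!exists(backend, envir = .segmenter_registry))
    stop(sprintf("unknown segmentation backend '%s' (registered: %s)",
                 backend, paste(list_segmenters(), collapse = ", ")))
  fn <- get(backend, envir = .segmenter_registry)
  instances <- vector("list", length(prompts))
  failed <- logical(length(prompts))
  for (i in seq_along(prompts)) {
    p <- prompts[[i]]
    stopifnot(inherits(p, "prompt_set"))
    if (p$box[["x_max"]] > ncol(image) || p$box[["y_max"]] > nrow(image))
      stop("prompt box exceeds image bounds")
    m <- fn(image, p)
    stopifnot(is.matrix(m), identical(dim(m), dim(image)))
    m <- clip_mask_to_box(m, p$box)
    failed[i] <- !any(m)
    instances[[i]] <- structure(
      list(mask = m, label = p$label, score = NA_real_),
      class = "instance_mask")  # empty masks allowed here: failed predictions
  }
  structure(list(instances = instances,
                 prompt_indices = seq_along(prompts),
                 failed = failed, backend = backend),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d mask(s) from backend '%s'%s\n",
              length(x$instances), x$backend,
              if (any(x$failed)) sprintf(" (%d failed)", sum(x$failed)) else ""))
  invisible(x)
}

#' Reference prompt segmenter
#'
#' Deterministic, parameter-free segmenter for bright-membrane/dark-interior
#' staining. Basement-membrane immunostaining outlines structures with
#' bright ridges around dark lumens and cytoplasm, so within the prompt-box
#' crop the object is the dark phase:
#'
#' 1. crop the image to the prompt box;
#' 2. threshold the crop with Otsu's method and keep the low-intensity phase;
#' 3. label 4-connected components of that phase;
#' 4. keep the component containing the positive (label-1) point;
#' 5. delete every component containing a negative (label-0) point — the
#'    fine constraint; a negative point landing in the positive component
#'    deletes it too, which surfaces as a failed (empty) prediction.
#'
#' @param image 2-D numeric raster.
#' @param prompt A `prompt_set`.
#' @return Full-frame logical mask (all-FALSE = failed prediction, e.g. a
#'   structureless crop or a positive point on the bright phase).
#' @export
reference_prompt_segmenter <- function(image, prompt) {
  stopifnot(is.matrix(image), inherits(prompt, "prompt_set"))
  rng <- box_pixel_range(prompt$box, nrow(image), ncol(image))
  crop <- image[rng$rows, rng$cols, drop = FALSE]
  out <- matrix(FALSE, nrow(image), ncol(image))
  lo <- min(crop); hi <- max(crop)
  if (hi <= lo) return(out)  # structureless crop
  norm <- (crop - lo) / (hi - lo)
  thr <- EBImage::otsu(norm, range = c(0, 1))
  dark <- norm < thr
  if (!any(dark)) return(out)
  lab <- EBImage::bwlabel(dark)
  # point (x, y) -> crop matrix indices; points are guaranteed inside the box
  comp_at <- function(pt) {
    r <- floor(pt[2]) + 1 - (rng$rows[1] - 1)
    c <- floor(pt[1]) + 1 - (rng$cols[1] - 1)
    if (r < 1 || r > nrow(lab) || c < 1 || c > ncol(lab)) 0 else lab[r, c]
  }
  pts <- prompt$points
  pos_comp <- comp_at(pts[pts[, "label"] == 1, , drop = FALSE][1, 1:2])
  if (pos_comp == 0) return(out)  # positive point on the bright phase
  neg <- pts[pts[, "label"] == 0, , drop = FALSE]
  if (nrow(neg) > 0) {
    neg_comps <- unique(vapply(seq_len(nrow(neg)),
                               function(k) comp_at(neg[k, 1:2]), numeric(1)))
    if (pos_comp %in% neg_comps) return(out)
  }
  out[rng$rows, rng$cols] <- lab == pos_comp
  out
}

register_segmenter("reference", reference_prompt_segmenter)

# Adapter slot for an external promptable model (e.g. a pretrained
# vision-foundation segmenter). No weights ship with the package; register
# a closure over your model with register_segmenter("sam", fn) to use it.
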