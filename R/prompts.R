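# Prompt engineering: each detection's bounding box is the coarse constraint
# (it bounds the maximal extent of the predicted mask and carries the class
# label); a set of binary-labeled centroids is the fine constraint. For
# detection i the set holds every detected centroid c_j that falls inside
# box B_i: c_i itself labeled 1 (target), intruding neighbours labeled 0.
# In densely packed myocardium CM boxes overlap and capillary boxes are
# often fully enclosed by CM boxes, so the negative points are what keeps a
# promptable segmenter from bleeding into neighbours.

#' Construct a detection
#'
#' @param box A `bbox`.
#' @param label `"CM"` or `"CAP"`.
#' @param confidence Score in `[0, 1]`.
#' @return An object of class `detection`.
#' @export
detection <- function(box, label, confidence = 1) {
  stopifnot(is_bbox(box))
  label <- match.arg(label, CLASS_LABELS)
  stopifnot(is.finite(confidence), confidence >= 0, confidence <= 1)
  structure(list(box = box, label = label, confidence = as.numeric(confidence)),
            class = "detection")
}

#' Construct a detection set
#'
#' An ordered list of detections; order is stable and meaningful (prompt i
#' is generated from detection i).
#'
#' @param detections List of `detection` objects (possibly empty).
#' @return An object of class `detection_set`.
#' @export
detection_set <- function(detections = list()) {
  stopifnot(is.list(detections),
            all(vapply(detections, inherits, logical(1), "detection")))
  structure(list(detections = detections, n = length(detections)),
            class = "detection_set")
}

#' @export
print.detection_set <- function(x, ...) {
  labs <- vapply(x$detections, `[[`, character(1), "label")
  cat(sprintf("<detection_set> %d detections (%d CM, %d CAP)\n",
              x$n, sum(labs == "CM"), sum(labs == "CAP")))
  invisible(x)
}

#' @export
length.detection_set <- function(x) x$n

#' Generate enhanced prompts from a detection set
#'
#' For every detection i, emits one prompt: the box `B_i` plus the point set
#' `P_i` built by traversing the centroids of all detections and keeping
#' those that fall inside `B_i` (half-open membership). The generating
#' detection's own centroid is always a member and carries binary label 1;
#' every other member carries label 0. In sparse scenes no foreign centroid
#' intrudes and each prompt degenerates to its single positive point.
#'
#' The traversal examines all n x n (centroid, box) pairs, so cost is
#' quadratic in the number of detections.
#'
#' @param detections A `detection_set`.
#' @return A list of `prompt_set` objects, one per detection, in detection
#'   order; empty list for an empty detection set.
#' @examples
#' d <- detection_set(list(
#'   detection(bbox(0, 0, 10, 10), "CM"),
#'   detection(bbox(2, 2, 6, 6), "CAP")))
#' p <- generate_prompts(d)
#' p[[1]]$points  # (5,5) labeled 1 and the intruder (4,4) labeled 0
#' @export
generate_prompts <- function(detections) {
  stopifnot(inherits(detections, "detection_set"))
  n <- detections$n
  if (n == 0) return(list())
  cents <- t(vapply(detections$detections,
                    function(d) bbox_centroid(d$box), numeric(2)))
  lapply(seq_len(n), function(i) {
    box <- detections$detections[[i]]$box
    inside <- cents[, 1] >= box[["x_min"]] & cents[, 1] < box[["x_max"]] &
              cents[, 2] >= box[["y_min"]] & cents[, 2] < box[["y_max"]]
    if (!inside[i])  # geometrically impossible for a valid box; assert anyway
      stop("internal error: a box does not contain its own centroid")
    members <- c(i, setdiff(which(inside), i))  # positive point first
    pts <- cbind(x = cents[members, 1], y = cents[members, 2],
                 label = as.numeric(members == i))
    prompt_set(box = box, points = pts,
               label = detections$detections[[i]]$label, source_index = i)
  })
}

#' Construct a prompt set
#'
#' One engineered prompt: a bounding box (coarse constraint) plus
#' binary-labeled points (fine constraint). Exactly one point carries label
#' 1 and it must be the box centroid; every point must lie inside the box.
#'
#' @param box A `bbox`.
#' @param points Numeric matrix with columns `x`, `y`, `label` (0 or 1).
#' @param label Class label carried from the detection.
#' @param source_index Index of the generating detection.
#' @return An object of class `prompt_set`.
#' @export
prompt_set <- function(box, points, label, source_index = NA_integer_) {
  stopifnot(is_bbox(box), is.matrix(points), ncol(points) == 3)
  label <- match.arg(label, CLASS_LABELS)
  if (!all(points[, 3] %in% c(0, 1))) stop("point labels must be 0 or 1")
  if (sum(points[, 3] == 1) != 1) stop("exactly one positive point required")
  pos <- points[points[, 3] == 1, , drop = FALSE]
  cen <- bbox_centroid(box)
  if (abs(pos[1, 1] - cen[["x"]]) > 1e-9 || abs(pos[1, 2] - cen[["y"]]) > 1e-9)
    stop("the positive point must be the box centroid")
  for (k in seq_len(nrow(points)))
    if (!point_in_box(points[k, 1:2], box))
      stop("every prompt point must lie within the prompt box")
  colnames(points) <- c("x", "y", "label")
  structure(list(box = box, points = points, label = label,
                 source_index = as.integer(source_index)),
            class = "prompt_set")
}

#' @export
print.prompt_set <- function(x, ...) {
  cat(sprintf("<prompt_set> %s from detection %d: 1 positive + %d negative point(s)\n",
              x$label, x$source_index, sum(x$points[, "label"] == 0)))
  invisible(x)
}

#' Serialize prompts to JSON
#'
#' Exchange format between the prompt generator and any segmentation
#' backend: `{"box": [x_min,y_min,x_max,y_max], "points": [[x,y,label],...],
#' "class": "CM"|"CAP"}` per prompt.
#'
#' @param prompts List of `prompt_set` objects.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
prompts_to_json <- function(prompts, path = NULL) {
  payload <- lapply(prompts, function(p) list(
    box = as.numeric(p$box),
    points = unname(apply(p$points, 1, as.numeric, simplify = FALSE)),
    class = p$label,
    source_index = p$source_index))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read prompts from JSON
#'
#' @param path File path or JSON string produced by [prompts_to_json()].
#' @return List of `prompt_set` objects.
#' @export
prompts_from_json <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(payload, function(p) {
    pts <- do.call(rbind, lapply(p$points, as.numeric))
    prompt_set(box = do.call(bbox, as.list(as.numeric(p$box))),
               points = pts, label = p$class,
               source_index = if (is.null(p$source_index)) NA_integer_
                              else p$source_index)
  })
}
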