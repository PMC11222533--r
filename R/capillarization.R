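# Capillarization assessment: the seven measurements derived from a set of
# labeled instance masks on one image, and relative-error tables against a
# ground-truth report.

CAP_MEASUREMENTS <- c("n_cm", "n_cap", "area_cm_um2", "area_cap_um2",
                      "cdfa_per_um2", "cdca_per_um2", "ccr")

#' Capillarization measurements for one image
#'
#' From labeled masks computes: CM count, capillary count, total CM area
#' and total capillary area (um^2), capillary density per FOV area
#' (CDFA, um^-2, capillary count / physical FOV area), capillary density
#' per CM area (CDCA, um^-2, capillary count / total CM mask area), and the
#' capillary-to-CM ratio (CCR, capillary count / CM count). When no CM is
#' present (or CM area is zero) CDCA and CCR are undefined and reported as
#' `NA`, never silently zeroed.
#'
#' Areas are summed per mask by default; `area_mode = "union"` instead
#' measures the union footprint per label, which differs when predicted
#' masks overlap.
#'
#' @param masks List of `instance_mask` objects matching `meta`.
#' @param meta The image's `image_meta`.
#' @param area_mode `"per_mask"` (default) or `"union"`.
#' @return An object of class `capillarization_report` with the seven
#'   measurements plus `fov_area_um2` and `area_mode`.
#' @examples
#' meta <- image_meta(64, 64, fov_um = 42.5)
#' m <- matrix(FALSE, 64, 64); m[10:20, 10:20] <- TRUE
#' assess(list(instance_mask(m, "CM")), meta)
#' @export
assess <- function(masks, meta, area_mode = c("per_mask", "union")) {
  stopifnot(inherits(meta, "image_meta"))
  area_mode <- match.arg(area_mode)
  for (m in masks) {
    stopifnot(inherits(m, "instance_mask"))
    if (nrow(m$mask) != meta$height_px || ncol(m$mask) != meta$width_px)
      stop("mask dimensions do not match image metadata")
  }
  labs <- vapply(masks, `[[`, character(1), "label")
  n_cm <- sum(labs == "CM"); n_cap <- sum(labs == "CAP")
  area_of <- function(label) {
    ms <- masks[labs == label]
    if (length(ms) == 0) return(0)
    if (area_mode == "per_mask")
      sum(vapply(ms, mask_area_um2, numeric(1), meta = meta))
    else
      mask_area_um2(Reduce(`|`, lapply(ms, `[[`, "mask")), meta)
  }
  area_cm <- area_of("CM"); area_cap <- area_of("CAP")
  fov_area <- prod(meta$fov_um)
  structure(list(
    n_cm = n_cm, n_cap = n_cap,
    area_cm_um2 = area_cm, area_cap_um2 = area_cap,
    cdfa_per_um2 = n_cap / fov_area,
    cdca_per_um2 = if (area_cm > 0) n_cap / area_cm else NA_real_,
    ccr = if (n_cm > 0) n_cap / n_cm else NA_real_,
    fov_area_um2 = fov_area, area_mode = area_mode
  ), class = "capillarization_report")
}

#' @export
print.capillarization_report <- function(x, ...) {
  fmt <- function(v, d = 4) if (is.na(v)) "undefined" else formatC(v, digits = d, format = "g")
  cat("<capillarization_report>\n")
  cat(sprintf("  CMs: %d (%.1f um^2)   capillaries: %d (%.1f um^2)\n",
              x$n_cm, x$area_cm_um2, x$n_cap, x$area_cap_um2))
  cat(sprintf("  CDFA %s um^-2   CDCA %s um^-2   CCR %s\n",
              fmt(x$cdfa_per_um2), fmt(x$cdca_per_um2), fmt(x$ccr)))
  invisible(x)
}

#' Convert a capillarization report to a one-row data frame
#'
#' @param x A `capillarization_report`.
#' @param ... Unused.
#' @return One-row data frame with the seven measurements (undefined
#'   values as `NA`).
#' @export
as.data.frame.capillarization_report <- function(x, ...) {
  as.data.frame(x[CAP_MEASUREMENTS], stringsAsFactors = FALSE)
}

#' Relative errors between predicted and ground-truth reports
#'
#' Applies [relative_error()] to each of the seven measurements. Pairs
#' whose ground truth is zero or undefined are flagged (`delta = NA`,
#' `defined = FALSE`) rather than computed.
#'
#' @param predicted,truth `capillarization_report` objects from the same
#'   image geometry.
#' @return Data frame with columns `measurement`, `predicted`, `truth`,
#'   `delta`, `defined`.
#' @export
report_errors <- function(predicted, truth) {
  stopifnot(inherits(predicted, "capillarization_report"),
            inherits(truth, "capillarization_report"))
  if (!isTRUE(all.equal(predicted$fov_area_um2, truth$fov_area_um2)))
    stop("reports come from different image geometries")
  rows <- lapply(CAP_MEASUREMENTS, function(f) {
    p <- predicted[[f]]; t <- truth[[f]]
    ok <- !is.na(t) && t != 0 && !is.na(p)
    data.frame(measurement = f, predicted = p, truth = t,
               delta = if (ok) relative_error(p, t) else NA_real_,
               defined = ok, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
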