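#' Measure the GUV diameter from a closed-vesicle frame mask
#'
#' From a full-frame binary mask (Sobel + isodata, not half-cropped), small
#' particles are removed with the same rule as [remove_specks()], the inner
#' closed membrane contour is identified by directional scanning outward
#' from the image center (the image center is required to lie inside the
#' vesicle, and scanning from it hits the inner contour before the outer
#' halo), its interior is hole-filled, and the diameter is reported as that
#' of a circle with the same area as the filled region:
#' `2 * pixel_size * sqrt(area / pi)`.
#'
#' A broken contour cannot enclose an interior: hole filling then leaves a
#' thin arc whose area is far below that of a disk spanning its bounding
#' box, which is reported as "vesicle not closed". Callers may substitute a
#' user-supplied diameter in that case.
#'
#' @param mask Full-frame logical matrix (thresholded gradient image of a
#'   frame showing the vesicle fully closed).
#' @param pixel_size Micrometers per pixel.
#' @param reference_area Optional membrane reference area in pixels for
#'   speck removal; `NULL` skips the despeckling step.
#' @param sensitivity Speck-removal sensitivity, 0..100.
#' @return GUV diameter in micrometers (scalar).
#' @export
measure_diameter <- function(mask, pixel_size, reference_area = NULL,
                             sensitivity = 50) {
  check_positive(pixel_size, "pixel_size")
  if (!is.null(reference_area)) {
    mask <- remove_specks(mask, reference_area, sensitivity)
  }
  h <- nrow(mask)
  lab <- directional_label(mask, origin_row = floor(h / 2) + 1L)
  comp <- if (lab$left_label != 0L) lab$left_label else lab$right_label
  if (lab$left_label != 0L && lab$right_label != 0L &&
      lab$left_label != lab$right_label) {
    stop_guv("vesicle not closed in this frame: left and right membrane elements differ",
             "geometry")
  }
  cm <- lab$labels == comp
  filled <- EBImage::fillHull(cm * 1L) > 0
  area <- sum(filled)
  idx <- which(cm, arr.ind = TRUE)
  bb_area <- (diff(range(idx[, 1])) + 1) * (diff(range(idx[, 2])) + 1)
  # a closed contour fills to a disk-like region (~pi/4 of its bounding box);
  # a broken arc fills to almost nothing
  if (area < 0.5 * (pi / 4) * bb_area) {
    stop_guv("vesicle not closed in this frame: contour does not enclose an interior",
             "geometry")
  }
  2 * pixel_size * sqrt(area / pi)
}

#' Radius-constancy gate
#'
#' The edge-tension relation assumes the vesicle radius stays roughly
#' constant during pore closure. The pre-pulse and post-closure radii are
#' compared and vesicles whose radii deviate by more than 5% are flagged;
#' the analysis still completes (a warning, never a hard stop) so the user
#' can decide whether to discard the measurement.
#'
#' @param before Vesicle radius before pore opening, micrometers.
#' @param after Vesicle radius after pore closure, micrometers. This is the
#'   radius R used in the edge-tension relation.
#' @return An object of class `guv_geometry`: list with `radius_before`,
#'   `radius_after`, `deviation` (|before - after| / before) and
#'   `exceeds_gate` (deviation > 0.05).
#' @export
radius_gate <- function(before, after) {
  check_positive(before, "before")
  check_positive(after, "after")
  dev <- abs(before - after) / before
  geo <- structure(
    list(radius_before = before, radius_after = after,
         deviation = dev, exceeds_gate = dev > 0.05),
    class = "guv_geometry"
  )
  if (geo$exceeds_gate) {
    warn_guv(sprintf(
      "GUV radius changed by %.1f%% between first and last frame (> 5%%); consider discarding this vesicle",
      100 * dev), "radius_gate")
  }
  geo
}

#' @export
print.guv_geometry <- function(x, ...) {
  cat(sprintf(
    "<guv_geometry> R before %.3g um, after %.3g um, deviation %.2f%%%s\n",
    x$radius_before, x$radius_after, 100 * x$deviation,
    if (isTRUE(x$exceeds_gate)) " [exceeds 5% gate]" else ""
  ))
  invisible(x)
}
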