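#' Read a multi-page grayscale TIFF as a frame stack
#'
#' @param path Path to a single-file multi-page TIFF (8- or 16-bit grayscale).
#' @param params An [acquisition_params()] object.
#' @return A [frame_stack()] preserving frame order and bit depth.
#' @export
read_stack <- function(path, params) {
  if (!file.exists(path)) stop_guv(sprintf("file not found: %s", path), "io")
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
    error = function(e) stop_guv(sprintf("could not read TIFF '%s': %s",
                                         path, conditionMessage(e)), "io")
  )
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2L, logical(1)))) {
    stop_guv("RGB/multichannel TIFF not supported; convert to grayscale first", "io")
  }
  if (length(pages) < 3L) {
    stop_guv(paste0(
      "TIFF has fewer than 3 frames; the sequence must contain frames with ",
      "the vesicle closed both before pore opening and after pore closure"
    ), "io")
  }
  bits <- attr(pages[[1]], "bits.per.sample")
  if (is.null(bits)) bits <- if (max(unlist(pages)) > 255) 16L else 8L
  frame_stack(pages, bit_depth = as.integer(bits), params = params)
}

#' Write a frame stack as a multi-page grayscale TIFF
#'
#' Intensities are stored at the stack's native bit depth; a stack written
#' and re-read round-trips voxelwise.
#'
#' @param stack A [frame_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  mx <- scale_max(stack$bit_depth)
  pages <- lapply(seq_len(n_frames(stack)), function(i) {
    clamp(round(stack$frames[, , i]), 0, mx) / mx
  })
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth,
                  compression = "none")
  invisible(path)
}

#' Rolling-ball background subtraction
#'
#' Estimates a smooth per-frame background as the grayscale morphological
#' opening of the intensity surface with a disc structuring element of the
#' given radius (the envelope a ball of that radius traces when rolled under
#' the surface), and subtracts it. Structures smaller than the ball (the
#' membrane ring, the halo) survive; smooth illumination gradients are
#' removed. The result is clipped to the valid intensity range.
#'
#' This step is optional in the pipeline but recommended when videos come
#' from different microscopy systems with uneven illumination.
#'
#' @param stack A [frame_stack()].
#' @param ball_radius Radius of the structuring element in pixels (default
#'   50). Must be smaller than the smaller frame dimension.
#' @return A new [frame_stack()] with the background removed.
#' @export
subtract_background <- function(stack, ball_radius = 50) {
  check_positive(ball_radius, "ball_radius")
  d <- dim(stack$frames)
  if (2 * ball_radius + 1 > min(d[1], d[2])) {
    stop_guv("`ball_radius` too large for the frame size", "params")
  }
  mx <- scale_max(stack$bit_depth)
  brush <- EBImage::makeBrush(2L * floor(ball_radius) + 1L, shape = "disc")
  out <- stack$frames
  for (i in seq_len(d[3])) {
    f01 <- stack$frames[, , i] / mx
    bg <- EBImage::dilate(EBImage::erode(f01, brush), brush)
    out[, , i] <- pmax(f01 - bg, 0) * mx
  }
  set_frames(stack, out)
}

#' Crop region
#'
#' A rectangular region in pixel coordinates (1-based, rows = top..bottom).
#'
#' @param top,left 1-based coordinates of the top-left corner.
#' @param height,width Extents in pixels; the area must be at least 256 px^2
#'   (a 16 x 16 region) so that a vesicle can plausibly fit.
#' @return An object of class `guv_crop`.
#' @export
crop_region <- function(top, left, height, width) {
  for (v in c(top, left, height, width)) {
    if (!is_scalar_num(v) || v < 1 || v != round(v)) {
      stop_guv("crop coordinates must be positive integers", "crop")
    }
  }
  if (height * width < 256) {
    stop_guv("crop region too small (area must be >= 16 x 16 px)", "crop")
  }
  structure(list(top = as.integer(top), left = as.integer(left),
                 height = as.integer(height), width = as.integer(width)),
            class = "guv_crop")
}

#' @export
print.guv_crop <- function(x, ...) {
  cat(sprintf("<guv_crop> top %d, left %d, %d x %d px\n",
              x$top, x$left, x$height, x$width))
  invisible(x)
}

#' Suggest a crop region containing the vesicle
#'
#' Builds the maximum-intensity projection of the whole sequence (so a
#' drifting vesicle is fully covered), applies isodata thresholding, takes
#' the bounding box of the largest connected foreground component, and
#' expands its width and height by 20% (10% on each side), clamped at the
#' frame borders. The returned region keeps the vesicle inside the frame
#' throughout the sequence and leaves the image center inside the vesicle.
#'
#' @param stack A [frame_stack()].
#' @return A [crop_region()].
#' @export
suggest_crop <- function(stack) {
  mip <- apply(stack$frames, c(1, 2), max)
  if (diff(range(mip)) == 0) stop_guv("no vesicle detected", "crop")
  thr <- isodata_threshold(mip)
  mask <- mip > thr
  if (!any(mask)) stop_guv("no vesicle detected", "crop")
  labels <- label_components(mask)
  areas <- tabulate(labels[labels > 0])
  big <- which.max(areas)
  idx <- which(labels == big, arr.ind = TRUE)
  r1 <- min(idx[, 1]); r2 <- max(idx[, 1])
  c1 <- min(idx[, 2]); c2 <- max(idx[, 2])
  bh <- r2 - r1 + 1L; bw <- c2 - c1 + 1L
  er <- round(0.1 * bh); ec <- round(0.1 * bw)
  d <- dim(stack$frames)
  r1 <- max(1L, r1 - er); r2 <- min(d[1], r2 + er)
  c1 <- max(1L, c1 - ec); c2 <- min(d[2], c2 + ec)
  crop_region(top = r1, left = c1, height = r2 - r1 + 1L, width = c2 - c1 + 1L)
}

#' Crop, rotate and time-slice a frame stack
#'
#' Deterministic sub-array edits applied identically to every frame.
#' `crop_stack()` extracts a rectangular region; `rotate90()` rotates by `k`
#' clockwise quarter turns (use it to bring a top- or side-facing pore to the
#' bottom of the image); `slice_time()` keeps frames `first..last`
#' (1-based, inclusive). Acquisition metadata is retained.
#'
#' @param stack A [frame_stack()].
#' @param region A [crop_region()] lying fully inside the frame.
#' @return A new [frame_stack()].
#' @export
crop_stack <- function(stack, region) {
  if (!inherits(region, "guv_crop")) stop_guv("`region` must be a guv_crop", "crop")
  d <- dim(stack$frames)
  r2 <- region$top + region$height - 1L
  c2 <- region$left + region$width - 1L
  if (r2 > d[1] || c2 > d[2]) stop_guv("crop region exceeds frame bounds", "crop")
  set_frames(stack, stack$frames[region$top:r2, region$left:c2, , drop = FALSE])
}

#' @param k Number of clockwise quarter turns (any integer; taken mod 4).
#' @rdname crop_stack
#' @export
rotate90 <- function(stack, k = 1) {
  k <- ((round(k) %% 4) + 4) %% 4
  if (k == 0) return(stack)
  f <- stack$frames
  for (j in seq_len(k)) {
    d <- dim(f)
    out <- array(0, dim = c(d[2], d[1], d[3]))
    for (i in seq_len(d[3])) out[, , i] <- t(f[d[1]:1, , i])
    f <- out
  }
  set_frames(stack, f)
}

#' @param first,last 1-based inclusive frame range to keep.
#' @rdname crop_stack
#' @export
slice_time <- function(stack, first, last) {
  nf <- n_frames(stack)
  if (!is_scalar_num(first) || !is_scalar_num(last) ||
      first < 1 || last > nf || first >= last) {
    stop_guv("need 1 <= first < last <= n_frames", "slice")
  }
  if (last - first + 1 < 3) {
    stop_guv("slice must keep at least 3 frames", "slice")
  }
  set_frames(stack, stack$frames[, , first:last, drop = FALSE])
}
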