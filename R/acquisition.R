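#' Acquisition parameters for a GUV video
#'
#' Bundles the three pieces of metadata that microscope videos do not carry
#' in a standard way but that the edge-tension calculation needs: the frame
#' rate, the pixel resolution and the viscosity of the aqueous medium.
#'
#' @param frame_rate Acquisition rate in frames per second (> 0).
#' @param pixel_size Microscope resolution in micrometers per pixel (> 0).
#' @param viscosity Viscosity of the aqueous medium in units of
#'   10^-3 Pa s (i.e. mPa s; water at room temperature is about 1). Must be
#'   > 0.
#'
#' @return An object of class `guv_acq`: a list with fields `frame_rate`,
#'   `pixel_size`, `viscosity` and the derived frame interval `dt_ms`
#'   (milliseconds between consecutive frames, `1000 / frame_rate`).
#' @examples
#' acquisition_params(frame_rate = 360, pixel_size = 0.25, viscosity = 1)
#' @export
acquisition_params <- function(frame_rate, pixel_size, viscosity) {
  check_positive(frame_rate, "frame_rate")
  check_positive(pixel_size, "pixel_size")
  check_positive(viscosity, "viscosity")
  structure(
    list(
      frame_rate = frame_rate,
      pixel_size = pixel_size,
      viscosity = viscosity,
      dt_ms = 1000 / frame_rate
    ),
    class = "guv_acq"
  )
}

#' @export
print.guv_acq <- function(x, ...) {
  cat(sprintf(
    "<guv_acq> %.4g fps (dt = %.4g ms), %.4g um/px, viscosity %.4g mPa s\n",
    x$frame_rate, x$dt_ms, x$pixel_size, x$viscosity
  ))
  invisible(x)
}

#' Construct a frame stack
#'
#' A frame stack is the in-memory form of a single-vesicle video: an ordered
#' set of grayscale frames plus acquisition metadata. Intensities are kept on
#' the raw integer scale of the stated bit depth (0..255 or 0..65535);
#' analysis operates on these raw values, never on display-normalized copies.
#'
#' @param frames Numeric array of dimension height x width x n_frames, or a
#'   list of equally sized matrices. Values must be non-negative.
#' @param bit_depth Either 8 or 16.
#' @param params An [acquisition_params()] object.
#'
#' @return An object of class `guv_stack` with fields `frames` (3-D array),
#'   `bit_depth` and `params`.
#' @details At least 3 frames are required: the analysis needs frames showing
#'   the vesicle fully closed both before pore opening and after closure in
#'   order to measure the vesicle radius at both ends.
#' @export
frame_stack <- function(frames, bit_depth, params) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) stop_guv("all frames must have the same shape", "stack")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop_guv("`frames` must be a height x width x time array or list of matrices",
             "stack")
  }
  if (dim(frames)[3] < 3L) {
    stop_guv(paste0(
      "need at least 3 frames: the sequence must contain frames with the ",
      "vesicle closed both before pore opening and after pore closure"
    ), "stack")
  }
  if (!bit_depth %in% c(8L, 16L)) stop_guv("`bit_depth` must be 8 or 16", "stack")
  if (min(frames) < 0) stop_guv("frame intensities must be non-negative", "stack")
  if (!inherits(params, "guv_acq")) {
    stop_guv("`params` must be created with acquisition_params()", "stack")
  }
  structure(
    list(frames = frames, bit_depth = as.integer(bit_depth), params = params),
    class = "guv_stack"
  )
}

#' @export
print.guv_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<guv_stack> %d frames of %d x %d px, %d-bit\n", d[3], d[1], d[2],
              x$bit_depth))
  print(x$params)
  invisible(x)
}

#' @export
dim.guv_stack <- function(x) dim(x$frames)

n_frames <- function(stack) dim(stack$frames)[3]

# replace the frame array, keeping metadata
set_frames <- function(stack, frames) {
  stack$frames <- frames
  stack
}
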