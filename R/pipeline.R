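#' Run the full pore edge-tension analysis pipeline
#'
#' Executes the whole analysis on a single-vesicle video: optional
#' rolling-ball background subtraction; editing (rotation, cropping, time
#' slicing); per-frame membrane segmentation (Sobel gradient, isodata
#' threshold, bottom-half restriction, speck removal, directional labeling)
#' and pore-width measurement; vesicle-diameter measurement on the first and
#' last frames with the 5% radius-constancy gate; assembly of the
#' R^2 ln r trace; linear-region selection (automatic unless a manual region
#' is given); and the least-squares fit converting the slope to the edge
#' tension gamma = (3 pi / 2) eta |slope|.
#'
#' Degenerate frames never abort the run: a frame whose segmentation fails
#' is marked invalid, logged, and excluded from the trace.
#'
#' In `"complete"` mode the processed (despeckled bottom-half) mask stack is
#' also written to `out_dir` as a TIFF; `"fast"` mode skips that. The two
#' modes return identical results.
#'
#' @param input A [frame_stack()] or the path to a multi-page grayscale
#'   TIFF.
#' @param frame_rate,pixel_size,viscosity Acquisition metadata (required
#'   when `input` is a path; taken from the stack otherwise, with these
#'   arguments overriding when supplied).
#' @param sensitivity Speck-removal sensitivity, 0..100 (default 50).
#' @param mode `"fast"` (default) or `"complete"`.
#' @param background_subtraction Apply [subtract_background()] first?
#' @param ball_radius Rolling-ball radius in pixels (default 50).
#' @param rotate Clockwise quarter turns applied before analysis.
#' @param crop `NULL` (no crop), `"auto"` (use [suggest_crop()]), a
#'   [crop_region()], or a length-4 vector c(top, left, height, width).
#' @param slice `NULL` or c(first, last) frames to keep (1-based).
#' @param region_ms `NULL` for automatic linear-region detection, or
#'   c(start, end) in ms selecting the region manually.
#' @param final_diameter Optional manual GUV diameter (um) used when the
#'   last-frame measurement fails (or to override it).
#' @param smooth_window Odd moving-average window for the displayed/detected
#'   trace (default 5); the fit always uses raw values.
#' @param out_dir Optional output directory; when given, the pore-size text
#'   file, the dynamics plot, and the result JSON are written there (plus
#'   the processed stack in complete mode).
#' @return A `guv_edge_tension` object augmented with `trace` (the
#'   stage-annotated [build_trace()] tibble), `measurements`, `geometry`,
#'   `config`, `warnings` (character) and `log` (stage-lettered lines).
#' @export
pore_analyze <- function(input,
                         frame_rate = NULL, pixel_size = NULL, viscosity = NULL,
                         sensitivity = 50,
                         mode = c("fast", "complete"),
                         background_subtraction = FALSE, ball_radius = 50,
                         rotate = 0, crop = NULL, slice = NULL,
                         region_ms = NULL, final_diameter = NULL,
                         smooth_window = 5, out_dir = NULL) {
  mode <- match.arg(mode)
  wlog <- character(); slog <- character()
  note <- function(stage, msg) {
    slog <<- c(slog, sprintf("[%s] %s", stage, msg))
  }
  collect <- function(expr) {
    withCallingHandlers(expr, guvpore_warning = function(w) {
      wlog <<- c(wlog, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  if (is.character(input) && length(input) == 1L) {
    if (is.null(frame_rate) || is.null(pixel_size) || is.null(viscosity)) {
      stop_guv("frame_rate, pixel_size and viscosity are required when reading from file",
               "params")
    }
    stack <- read_stack(input, acquisition_params(frame_rate, pixel_size, viscosity))
  } else if (inherits(input, "guv_stack")) {
    stack <- input
    p <- stack$params
    if (!is.null(frame_rate) || !is.null(pixel_size) || !is.null(viscosity)) {
      stack$params <- acquisition_params(frame_rate %||% p$frame_rate,
                                         pixel_size %||% p$pixel_size,
                                         viscosity %||% p$viscosity)
    }
  } else {
    stop_guv("`input` must be a file path or a guv_stack", "params")
  }
  params <- stack$params
  note("load", sprintf("%d frames, %d-bit", n_frames(stack), stack$bit_depth))

  if (isTRUE(background_subtraction)) {
    stack <- subtract_background(stack, ball_radius)
    note("A", sprintf("rolling-ball background subtracted (radius %g px)", ball_radius))
  }
  if (rotate != 0) {
    stack <- rotate90(stack, rotate)
    note("edit", sprintf("rotated %d quarter turn(s)", ((rotate %% 4) + 4) %% 4))
  }
  if (!is.null(crop)) {
    region <- if (identical(crop, "auto")) {
      suggest_crop(stack)
    } else if (inherits(crop, "guv_crop")) {
      crop
    } else {
      crop_region(crop[1], crop[2], crop[3], crop[4])
    }
    stack <- crop_stack(stack, region)
    note("edit", sprintf("cropped to %d x %d px at (%d, %d)",
                         region$height, region$width, region$top, region$left))
  }
  if (!is.null(slice)) {
    stack <- slice_time(stack, slice[1], slice[2])
    note("edit", sprintf("sliced to frames %d..%d", slice[1], slice[2]))
  }

  nf <- n_frames(stack)
  keep_masks <- mode == "complete" && !is.null(out_dir)
  mask_store <- if (keep_masks) vector("list", nf) else NULL
  full_mask_first <- NULL; full_mask_last <- NULL
  reference_area <- NULL
  rows <- vector("list", nf)
  for (i in seq_len(nf)) {
    frame <- stack$frames[, , i]
    res <- collect(tryCatch({
      g <- sobel_gradient(frame)                         # B
      thr <- isodata_threshold(g)                        # C
      mask_full <- g > thr
      if (i == 1L) full_mask_first <- mask_full
      if (i == nf) full_mask_last <- mask_full
      mask <- bottom_half(mask_full)                     # D
      if (is.null(reference_area)) {
        reference_area <- reference_membrane_area(mask)
        note("D", sprintf("reference membrane area %d px from first frame",
                          reference_area))
      }
      mask <- remove_specks(mask, reference_area, sensitivity)
      if (keep_masks) mask_store[[i]] <- mask
      lab <- directional_label(mask)                     # E
      measure_pore(lab, params$pixel_size)               # F
    }, guvpore_error = function(e) {
      wlog <<- c(wlog, sprintf("frame %d excluded: %s", i, conditionMessage(e)))
      tibble::tibble(is_open = FALSE, pore_diameter_um = NA_real_,
                     valid = FALSE, edge_points = list(NULL))
    }))
    rows[[i]] <- res
  }
  measurements <- dplyr::bind_rows(rows)
  measurements$frame <- seq_len(nf)
  note("F", sprintf("%d/%d frames with an open pore",
                    sum(measurements$is_open & measurements$valid), nf))
  if (measurements$is_open[1] || measurements$is_open[nf] ||
      !measurements$valid[1] || !measurements$valid[nf]) {
    collect(warn_guv(paste0(
      "first or last frame does not show a closed vesicle; radii ",
      "measurements may be unreliable (slice the sequence to keep ",
      "closed-vesicle frames at both ends)"), "requirement"))
  }

  # G-H: vesicle diameters from first and last frames
  diam <- function(mask, which) {
    collect(tryCatch(
      measure_diameter(mask, params$pixel_size, reference_area, sensitivity),
      guvpore_error = function(e) {
        wlog <<- c(wlog, sprintf("%s-frame diameter measurement failed: %s",
                                 which, conditionMessage(e)))
        NA_real_
      }))
  }
  d_before <- diam(full_mask_first, "first")
  d_after <- diam(full_mask_last, "last")
  if (!is.null(final_diameter)) {
    check_positive(final_diameter, "final_diameter")
    d_after <- final_diameter
    note("H", sprintf("final diameter manually set to %g um", final_diameter))
  }
  if (is.na(d_after)) {
    stop_guv(paste0("could not measure the vesicle in the last frame; ",
                    "supply `final_diameter` to proceed"), "geometry")
  }
  if (is.na(d_before)) {
    collect(warn_guv("first-frame diameter unavailable; radius gate skipped",
                     "geometry"))
    d_before <- d_after
  }
  geometry <- collect(radius_gate(d_before / 2, d_after / 2))
  note("H", sprintf("R before %.3g um, after %.3g um (deviation %.2f%%)",
                    geometry$radius_before, geometry$radius_after,
                    100 * geometry$deviation))

  # I: trace assembly and smoothing
  trace <- collect(build_trace(measurements, geometry, params))
  trace <- collect(smooth_trace(trace, smooth_window))

  # J: linear-region selection on the open-pore subset
  open_idx <- which(trace$is_open & trace$valid & trace$radius_um > 0)
  t_open <- trace$time_ms[open_idx]
  y_open <- trace$y[open_idx]
  y_detect <- geometry$radius_after^2 * log(trace$smoothed[open_idx])
  region <- if (!is.null(region_ms)) {
    sel <- which(t_open >= region_ms[1] & t_open <= region_ms[2])
    if (length(sel) < 4) {
      stop_guv("manual region contains fewer than 4 open-pore points", "dynamics")
    }
    manual_region(min(sel), max(sel))
  } else {
    collect(detect_linear_region(y_detect, t_open))
  }
  note("J", sprintf("%s linear region: open-pore points %d..%d",
                    region$source, region$start, region$end))

  # K: fit on the raw series
  result <- collect(fit_edge_tension(y_open, t_open, region, params$viscosity))
  note("K", sprintf("slope %.4g um^2/ms -> gamma %.4g pN",
                    result$slope, result$gamma_pN))

  trace <- classify_stages(trace, region = region)
  result$trace <- trace
  result$measurements <- measurements
  result$geometry <- geometry
  result$params <- params
  result$config <- list(sensitivity = sensitivity, mode = mode,
                        background_subtraction = background_subtraction,
                        ball_radius = ball_radius, rotate = rotate,
                        smooth_window = smooth_window,
                        region_source = region$source)
  result$warnings <- wlog
  result$log <- slog

  if (!is.null(out_dir)) {
    write_result_artifacts(result, out_dir,
                           masks = if (keep_masks) mask_store else NULL,
                           stack_bit_depth = stack$bit_depth)
  }
  result
}

# write trace text file, plot, result JSON and (complete mode) the
# processed mask stack
write_result_artifacts <- function(result, out_dir, masks = NULL,
                                   stack_bit_depth = 8L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trace <- result$trace
  # all pore sizes (um) versus time (ms), one row per frame
  write.table(
    data.frame(pore_diameter_um = 2 * trace$radius_um, time_ms = trace$time_ms),
    file.path(out_dir, "pore_sizes_vs_time.txt"),
    row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  p <- ggplot2::autoplot(result)
  ggplot2::ggsave(file.path(out_dir, "pore_dynamics.png"), p,
                  width = 7, height = 5, dpi = 150)
  jsonlite::write_json(result_record(result),
                       file.path(out_dir, "result.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(masks)) {
    ok <- !vapply(masks, is.null, logical(1))
    if (any(ok)) {
      dims <- dim(masks[[which(ok)[1]]])
      arr <- array(0, dim = c(dims, length(masks)))
      for (i in which(ok)) arr[, , i] <- masks[[i]] * scale_max(8L)
      ps <- frame_stack(arr, bit_depth = 8L, params = result$params)
      write_stack(ps, file.path(out_dir, "processed_masks.tif"))
    }
  }
  invisible(out_dir)
}

# machine-readable summary of a fit, used for the result JSON
result_record <- function(result) {
  list(
    gamma_pN = result$gamma_pN,
    slope_um2_per_ms = result$slope,
    intercept_um2 = result$intercept,
    r_squared = result$r_squared,
    radius_before_um = result$geometry$radius_before,
    radius_after_um = result$geometry$radius_after,
    radius_deviation = result$geometry$deviation,
    exceeds_radius_gate = result$geometry$exceeds_gate,
    region = list(start = result$region$start, end = result$region$end,
                  source = result$region$source,
                  fallback = isTRUE(result$region$fallback)),
    n_points = result$n_points,
    params = list(frame_rate = result$params$frame_rate,
                  pixel_size = result$params$pixel_size,
                  viscosity = result$params$viscosity),
    config = result$config,
    warnings = result$warnings,
    version = as.character(packageVersion("guvpore"))
  )
}
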