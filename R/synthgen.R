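#' Specification for a synthetic GUV video
#'
#' Collects the physical and imaging parameters from which a ground-truth
#' pore trace and a synthetic phase-contrast-like video are generated. The
#' defaults emulate a typical fast-camera electroporation recording of a
#' medium-sized GUV: 360 frames/s, a vesicle radius of a few tens of
#' micrometers, a macropore opening to about a third of the vesicle radius,
#' and water-like viscosity.
#'
#' @param R_true Vesicle radius, micrometers.
#' @param gamma_true Pore edge tension, piconewtons.
#' @param viscosity Medium viscosity, mPa s.
#' @param frame_rate Frames per second.
#' @param pixel_size Micrometers per pixel.
#' @param frame_shape Optional c(height, width) in pixels; sized
#'   automatically (vesicle plus halo plus margin) when `NULL`.
#' @param t_growth,t_stable Durations of the pore-growth and stable stages,
#'   ms.
#' @param r_max Maximum (stable-stage) pore radius, micrometers; must be
#'   smaller than `R_true`.
#' @param r_cutoff Pore radius at which slow closure hands over to fast
#'   closure, micrometers (default 0.5).
#' @param noise_sigma Additive Gaussian noise, as a fraction of full scale.
#' @param halo_width Width of the bright phase-contrast halo, pixels.
#' @param membrane_width Width of the dark-to-bright transition ramp at the
#'   membrane, pixels.
#' @param blur_sigma Gaussian blur emulating optics, pixels.
#' @param halo_inset Inward encroachment of the phase-contrast halo over the
#'   object boundary, pixels: the rendered dark-to-bright transition sits at
#'   `R_true/pixel_size - halo_inset`. Phase-contrast halos bleed over edge
#'   boundaries, making dark objects appear slightly shrunken; this is what
#'   produces the mild systematic underestimation of vesicle and pore radii
#'   that automated measurement on such images shows.
#' @param closed_lead,closed_tail Number of closed-vesicle frames rendered
#'   before pore opening and after closure.
#' @param bit_depth 8 or 16.
#' @param pore_angle Angular placement of the pore in degrees; 90 is the
#'   image bottom (default).
#' @param drift_px_per_frame c(row, col) drift of the vesicle center per
#'   frame, pixels.
#' @param seed RNG seed fixing all randomness of the render.
#' @return An object of class `guv_synth_spec`.
#' @export
synthetic_spec <- function(R_true = 20, gamma_true = 40, viscosity = 1,
                           frame_rate = 360, pixel_size = 0.25,
                           frame_shape = NULL,
                           t_growth = 10, t_stable = 15,
                           r_max = 0.3 * R_true, r_cutoff = 0.5,
                           noise_sigma = 0.01, halo_width = 6,
                           membrane_width = 1, blur_sigma = 0.8,
                           halo_inset = 3,
                           closed_lead = 5, closed_tail = 5,
                           bit_depth = 8, pore_angle = 90,
                           drift_px_per_frame = c(0, 0), seed = 1) {
  for (nm in c("R_true", "gamma_true", "viscosity", "frame_rate", "pixel_size",
               "r_max", "r_cutoff", "halo_width", "membrane_width")) {
    check_positive(get(nm), nm)
  }
  if (r_max >= R_true) stop_guv("`r_max` must be smaller than `R_true`", "synth")
  if (r_cutoff >= r_max) stop_guv("`r_cutoff` must be smaller than `r_max`", "synth")
  if (t_growth < 0 || t_stable < 0) stop_guv("stage durations must be >= 0", "synth")
  if (!bit_depth %in% c(8, 16)) stop_guv("`bit_depth` must be 8 or 16", "synth")
  R_px <- R_true / pixel_size
  if (is.null(frame_shape)) {
    drift_n <- 40   # sizing allowance for drifting renders
    side <- 2 * ceiling(1.12 * R_px + halo_width + 8 +
                          max(abs(drift_px_per_frame)) * drift_n / 2)
    frame_shape <- c(side, side)
  }
  if (min(frame_shape) < 2 * (R_px + halo_width)) {
    stop_guv("`frame_shape` too small for the vesicle and its halo", "synth")
  }
  structure(
    list(R_true = R_true, gamma_true = gamma_true, viscosity = viscosity,
         frame_rate = frame_rate, pixel_size = pixel_size,
         frame_shape = as.integer(frame_shape),
         t_growth = t_growth, t_stable = t_stable,
         r_max = r_max, r_cutoff = r_cutoff,
         noise_sigma = noise_sigma, halo_width = halo_width,
         membrane_width = membrane_width, blur_sigma = blur_sigma,
         halo_inset = halo_inset,
         closed_lead = as.integer(closed_lead),
         closed_tail = as.integer(closed_tail),
         bit_depth = as.integer(bit_depth), pore_angle = pore_angle,
         drift_px_per_frame = drift_px_per_frame, seed = as.integer(seed)),
    class = "guv_synth_spec"
  )
}

#' Generate a ground-truth four-stage pore trace
#'
#' Produces the per-frame true pore radius through the four stages of pore
#' life: (i) growth, a smooth cubic ramp from 0 to `r_max` over `t_growth`
#' ms; (ii) stabilization at `r_max` for `t_stable` ms; (iii) slow closure
#' following the leak-out relation exactly, r(t) = exp((C + s t) / R^2) with
#' s = -2 gamma / (3 pi eta), until r falls below `r_cutoff`; (iv) fast
#' closure to 0 over 3 frames. Closed frames are included before and after
#' so the vesicle radius can be measured at both ends.
#'
#' @param spec A [synthetic_spec()].
#' @return A tibble of class `guv_ground_truth`: columns `frame`, `time_ms`,
#'   `r_true` (um), `R_true` (um) and `stage`
#'   (closed/growth/stable/slow/fast). Attribute `slope_true` holds s in
#'   um^2/ms.
#' @export
generate_trace <- function(spec) {
  if (!inherits(spec, "guv_synth_spec")) {
    stop_guv("`spec` must come from synthetic_spec()", "synth")
  }
  dt <- 1000 / spec$frame_rate
  s <- -2 * spec$gamma_true / (3 * pi * spec$viscosity)   # um^2/ms
  R2 <- spec$R_true^2
  t0 <- spec$t_growth + spec$t_stable
  C <- R2 * log(spec$r_max) - s * t0
  # slow stage lasts until r(t) = r_cutoff
  t_end <- (R2 * log(spec$r_cutoff) - C) / s
  n_slow <- sum(seq(0, t_end, by = dt) > t0)
  if (n_slow < 8) {
    stop_guv(paste0(
      "slow-closure stage would span fewer than 8 frames; increase the ",
      "frame rate, the vesicle size or r_max"), "synth")
  }
  t_open <- seq(0, t_end, by = dt)
  r_open <- numeric(length(t_open))
  st_open <- character(length(t_open))
  grow <- t_open <= spec$t_growth & spec$t_growth > 0
  u <- t_open[grow] / spec$t_growth
  r_open[grow] <- spec$r_max * (3 * u^2 - 2 * u^3)
  st_open[grow] <- "growth"
  stab <- !grow & t_open <= t0
  r_open[stab] <- spec$r_max
  st_open[stab] <- "stable"
  slow <- t_open > t0
  r_open[slow] <- exp((C + s * t_open[slow]) / R2)
  st_open[slow] <- "slow"
  # drop any leading zero-radius growth frame (pore not yet open)
  keep <- r_open > 0
  t_open <- t_open[keep]; r_open <- r_open[keep]; st_open <- st_open[keep]
  r_last <- r_open[length(r_open)]
  r_fast <- r_last * c(2 / 3, 1 / 3)
  r <- c(rep(0, spec$closed_lead), r_open, r_fast, 0,
         rep(0, spec$closed_tail))
  stage <- c(rep("closed", spec$closed_lead), st_open,
             rep("fast", 2), rep("closed", spec$closed_tail + 1))
  n <- length(r)
  out <- tibble::tibble(
    frame = seq_len(n),
    time_ms = (seq_len(n) - 1) * dt,
    r_true = r,
    R_true = spec$R_true,
    stage = factor(stage, levels = c("closed", "growth", "stable", "slow", "fast"))
  )
  attr(out, "slope_true") <- s
  attr(out, "spec") <- spec
  class(out) <- c("guv_ground_truth", class(tibble::tibble()))
  out
}

#' Render a synthetic phase-contrast GUV video
#'
#' Draws, for each frame of a ground-truth trace, an idealized
#' phase-contrast image of a sucrose-loaded GUV in glucose: a dark interior
#' disk, a thin darker membrane line at the vesicle radius, a sharp
#' dark-to-bright transition into a bright halo annulus, and a mid-gray
#' background. When the pore is open, an angular sector of the rim whose
#' chord equals the pore diameter 2r is rendered with the local intensity
#' gradient dissipated (solutions mix through the pore), blended smoothly
#' toward background over the outer part of the interior. Gaussian blur
#' stands in for the optics and seeded Gaussian noise for the camera.
#'
#' @param truth A `guv_ground_truth` from [generate_trace()].
#' @param spec The same [synthetic_spec()].
#' @return A [frame_stack()] whose acquisition parameters match the spec.
#' @export
render_stack <- function(truth, spec) {
  if (!inherits(spec, "guv_synth_spec")) {
    stop_guv("`spec` must come from synthetic_spec()", "synth")
  }
  if (any(truth$r_true >= spec$R_true)) {
    stop_guv("ground truth has a pore radius >= the vesicle radius", "synth")
  }
  h <- spec$frame_shape[1]; w <- spec$frame_shape[2]
  R_px <- spec$R_true / spec$pixel_size
  mw <- spec$membrane_width
  halo <- spec$halo_width
  lv <- c(interior = 0.25, halo = 0.92, background = 0.55)
  pore_phi <- spec$pore_angle * pi / 180
  n <- nrow(truth)
  cy0 <- (h + 1) / 2; cx0 <- (w + 1) / 2
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  set.seed(spec$seed)
  frames <- array(0, dim = c(h, w, n))
  mx <- scale_max(spec$bit_depth)
  for (i in seq_len(n)) {
    cy <- cy0 + spec$drift_px_per_frame[1] * (i - 1)
    cx <- cx0 + spec$drift_px_per_frame[2] * (i - 1)
    dy <- rows - cy; dx <- cols - cx
    rad <- sqrt(dy^2 + dx^2)
    # the membrane (a few-nm bilayer) is not resolvable: the dark interior
    # runs up to the dark->bright transition, which phase-contrast places at
    # the membrane radius less the halo encroachment (see halo_inset); the
    # transition itself is a ramp of width membrane_width centered there
    R_img <- R_px - spec$halo_inset
    img <- matrix(lv["background"], h, w)
    img[rad < R_img + halo] <- lv["halo"]
    ramp <- clamp((rad - (R_img - mw / 2)) / mw, 0, 1)
    inside <- rad < R_img + mw / 2
    img[inside] <- lv["interior"] + ramp[inside] * (lv["halo"] - lv["interior"])
    r_um <- truth$r_true[i]
    if (r_um > 0) {
      theta <- asin(min(1, r_um / spec$R_true))
      phi <- atan2(dy, dx)
      dphi <- abs(atan2(sin(phi - pore_phi), cos(phi - pore_phi)))
      zone <- rad <= R_img + halo + 2
      # radial profile of the dissipation: complete across the rim band
      # (blend reaches 100% before the membrane/halo structure starts),
      # fading toward the dark deep interior
      inner1 <- R_img - mw / 2 - 2
      inner0 <- inner1 - 4
      alpha <- clamp((rad - inner0) / (inner1 - inner0), 0, 1)
      # angular profile: the mixed solution has no sharp lateral boundary;
      # feather the transition over a PSF-scale arc centered on the pore
      # edge so the rendered gap chord stays 2r on average
      fa <- 4 / R_px
      wang <- clamp((theta + fa / 2 - dphi) / fa, 0, 1)
      wt <- alpha * wang
      img[zone] <- (1 - wt[zone]) * img[zone] + wt[zone] * lv["background"]
    }
    if (spec$blur_sigma > 0) img <- EBImage::gblur(img, sigma = spec$blur_sigma)
    if (spec$noise_sigma > 0) img <- img + rnorm(h * w, sd = spec$noise_sigma)
    frames[, , i] <- round(clamp(img, 0, 1) * mx)
  }
  frame_stack(frames, bit_depth = spec$bit_depth,
              params = acquisition_params(spec$frame_rate, spec$pixel_size,
                                          spec$viscosity))
}

#' Generate and save a synthetic GUV video with its ground truth
#'
#' Convenience wrapper: [generate_trace()] + [render_stack()], written as a
#' multi-page TIFF with a sidecar ground-truth CSV and a JSON copy of the
#' generating parameters.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory (created if needed).
#' @param basename File stem for the three outputs.
#' @return Invisibly, a list with `stack`, `truth` and the written paths.
#' @export
generate_synthetic_video <- function(spec, out_dir, basename = "synthetic_guv") {
  truth <- generate_trace(spec)
  stack <- render_stack(truth, spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tif <- file.path(out_dir, paste0(basename, ".tif"))
  csv <- file.path(out_dir, paste0(basename, "_truth.csv"))
  js <- file.path(out_dir, paste0(basename, "_spec.json"))
  write_stack(stack, tif)
  utils::write.csv(as.data.frame(truth), csv, row.names = FALSE)
  jsonlite::write_json(unclass(spec), js, auto_unbox = TRUE, digits = NA)
  invisible(list(stack = stack, truth = truth,
                 paths = list(tiff = tif, truth = csv, spec = js)))
}
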