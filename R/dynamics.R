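#' Build the pore-dynamics trace
#'
#' Assembles per-frame pore measurements into a time series and computes the
#' transformed ordinate y(t) = R^2 ln r used for the edge-tension fit, where
#' R is the vesicle radius after pore closure and r the pore radius, both in
#' micrometers (y in um^2, t in ms). During the slow leak-out stage of pore
#' closure y decreases linearly with slope -2*gamma/(3*pi*eta). Frames with a
#' closed pore (r = 0) or an invalid measurement are kept in the trace but
#' excluded from y (ln 0 is undefined).
#'
#' @param measurements A data frame with one row per frame, columns
#'   `is_open`, `pore_diameter_um` and `valid` (as produced by
#'   [segment_frame()] rows bound together).
#' @param geometry A `guv_geometry` from [radius_gate()].
#' @param params An [acquisition_params()].
#' @return A tibble of class `guv_pore_trace` with columns `frame`,
#'   `time_ms`, `is_open`, `valid`, `radius_um`, `smoothed` (initialised to
#'   `radius_um`; see [smooth_trace()]) and `y`. Attributes `params` and
#'   `geometry` carry the metadata.
#' @export
build_trace <- function(measurements, geometry, params) {
  if (!inherits(geometry, "guv_geometry")) {
    stop_guv("`geometry` must come from radius_gate()", "dynamics")
  }
  if (!inherits(params, "guv_acq")) {
    stop_guv("`params` must come from acquisition_params()", "dynamics")
  }
  m <- tibble::as_tibble(measurements)
  n <- nrow(m)
  open_valid <- m$is_open & m$valid
  if (!any(open_valid)) stop_guv("no pore detected in any frame", "dynamics")
  R <- geometry$radius_after
  radius <- ifelse(m$is_open, m$pore_diameter_um / 2, 0)
  y <- ifelse(open_valid & radius > 0, R^2 * log(radius), NA_real_)
  out <- tibble::tibble(
    frame = seq_len(n),
    time_ms = (seq_len(n) - 1) * params$dt_ms,
    is_open = m$is_open,
    valid = m$valid,
    radius_um = radius,
    smoothed = radius,
    y = y
  )
  structure(out, class = c("guv_pore_trace", class(tibble::tibble()))) |>
    set_trace_meta(params, geometry)
}

set_trace_meta <- function(trace, params, geometry) {
  attr(trace, "params") <- params
  attr(trace, "geometry") <- geometry
  trace
}

#' Smooth a pore trace
#'
#' Centered moving average over the open-pore radius samples; near the ends
#' of the open segment the window shrinks symmetrically. Smoothing serves
#' display and linear-region detection only: the edge-tension regression
#' always runs on the raw series, avoiding the autocorrelation that
#' averaging would introduce into the fit.
#'
#' @param trace A `guv_pore_trace`.
#' @param window Odd window length in frames (default 5). `window = 1` is
#'   the identity.
#' @return The trace with its `smoothed` column replaced.
#' @export
smooth_trace <- function(trace, window = 5) {
  if (!is_scalar_num(window) || window < 1 || window %% 2 != 1) {
    stop_guv("`window` must be an odd positive integer", "dynamics")
  }
  open_idx <- which(trace$is_open & trace$valid & trace$radius_um > 0)
  if (window > length(open_idx)) {
    stop_guv("smoothing window longer than the open-pore trace", "dynamics")
  }
  x <- trace$radius_um[open_idx]
  half <- (window - 1) / 2
  n <- length(x)
  sm <- vapply(seq_len(n), function(i) {
    k <- min(half, i - 1, n - i)    # shrink symmetrically at the ends
    mean(x[(i - k):(i + k)])
  }, numeric(1))
  trace$smoothed <- trace$radius_um
  trace$smoothed[open_idx] <- sm
  trace
}

#' Detect the linear slow-closure region
#'
#' Searches all contiguous windows of at least `min_len` points for the
#' longest one whose ordinary least-squares fit has a determination
#' coefficient of at least `r2_min` and a negative slope; among equally long
#' qualifying windows the latest-starting one wins (the slow-closure stage
#' immediately precedes fast closure). If no window qualifies the
#' best-determination window is returned with a warning so the user can
#' inspect or override the choice.
#'
#' @param y,t Numeric vectors (same length, >= 8 points): the transformed
#'   series R^2 ln r and its times in ms. `NA`s are not allowed here; pass
#'   the open-pore subset.
#' @param min_len Minimum number of points in the region (default 5).
#' @param r2_min Determination-coefficient threshold (default 0.995;
#'   applied to the smoothed series this is strict enough to keep the
#'   stable plateau and fast-closure frames out of the window).
#' @return A list of class `guv_region` with `start`, `end` (indices into
#'   `y`/`t`), `source` (`"automatic"`) and `fallback` (logical).
#' @export
detect_linear_region <- function(y, t, min_len = 5, r2_min = 0.995) {
  if (length(y) != length(t)) stop_guv("`y` and `t` must have equal length", "dynamics")
  keep <- is.finite(y) & is.finite(t)
  if (!all(keep)) stop_guv("`y` and `t` must be finite; pass the open-pore subset", "dynamics")
  n <- length(y)
  if (n < 8) {
    stop_guv("trace too short for automatic detection (need >= 8 open-pore points); supply the region manually",
             "dynamics")
  }
  tc <- t - mean(t)   # center for numerical stability
  s_t <- c(0, cumsum(tc)); s_tt <- c(0, cumsum(tc^2))
  s_y <- c(0, cumsum(y)); s_yy <- c(0, cumsum(y^2))
  s_ty <- c(0, cumsum(tc * y))
  win_stats <- function(i, j) {
    m <- j - i + 1
    st <- s_t[j + 1] - s_t[i]; stt <- s_tt[j + 1] - s_tt[i]
    sy <- s_y[j + 1] - s_y[i]; syy <- s_yy[j + 1] - s_yy[i]
    sty <- s_ty[j + 1] - s_ty[i]
    sxx <- stt - st^2 / m
    sYY <- syy - sy^2 / m
    sxy <- sty - st * sy / m
    slope <- if (sxx > 0) sxy / sxx else 0
    r2 <- if (sxx > 0 && sYY > 0) sxy^2 / (sxx * sYY) else NA_real_
    c(slope = slope, r2 = r2)
  }
  best_len <- 0L; best_start <- 0L
  fb_r2 <- -Inf; fb <- c(1L, min_len)
  for (i in seq_len(n - min_len + 1L)) {
    for (j in (i + min_len - 1L):n) {
      st <- win_stats(i, j)
      if (is.finite(st["r2"]) && st["slope"] < 0 && st["r2"] > fb_r2) {
        fb_r2 <- st["r2"]; fb <- c(i, j)
      }
      if (is.finite(st["r2"]) && st["r2"] >= r2_min && st["slope"] < 0) {
        len <- j - i + 1L
        if (len > best_len || (len == best_len && i > best_start)) {
          best_len <- len; best_start <- i
        }
      }
    }
  }
  if (best_len > 0L) {
    structure(list(start = best_start, end = best_start + best_len - 1L,
                   source = "automatic", fallback = FALSE),
              class = "guv_region")
  } else {
    warn_guv("no window met the linearity criteria; falling back to the best-determination window - inspect the trace",
             "region_fallback")
    structure(list(start = fb[1], end = fb[2],
                   source = "automatic", fallback = TRUE),
              class = "guv_region")
  }
}

#' Manually specified linear region
#'
#' @param start,end Indices into the open-pore series (end - start >= 3).
#' @return A `guv_region` with `source = "manual"`.
#' @export
manual_region <- function(start, end) {
  if (!is_scalar_num(start) || !is_scalar_num(end) || end - start < 3) {
    stop_guv("a linear region needs end - start >= 3 (at least 4 points)", "dynamics")
  }
  structure(list(start = as.integer(start), end = as.integer(end),
                 source = "manual", fallback = FALSE),
            class = "guv_region")
}

#' Fit the edge tension from the linear region
#'
#' Ordinary least squares y = s t + C on the selected region of the raw
#' transformed series, followed by the unit conversion from the slow
#' leak-out relation R^2 ln r = -(2 gamma / (3 pi eta)) t + C:
#' gamma = (3 pi / 2) * eta * |s|. With eta in mPa s and s in um^2/ms the
#' product is directly in piconewtons (1 mPa s * 1 um^2/ms = 1e-12 N).
#' A closing pore requires s < 0; a non-negative slope is an error.
#'
#' @param y,t Numeric vectors: transformed series (um^2) and time (ms) of
#'   the open-pore subset.
#' @param region A `guv_region` (from [detect_linear_region()] or
#'   [manual_region()]).
#' @param viscosity Medium viscosity in mPa s.
#' @return An object of class `guv_edge_tension`: list with `gamma_pN`,
#'   `slope` (um^2/ms), `intercept` (um^2, the experiment-dependent constant
#'   C), `r_squared`, `region`, `viscosity`, `n_points`, `fit` (the `lm`
#'   object) and `data` (tibble of t, y, in_region).
#' @export
fit_edge_tension <- function(y, t, region, viscosity) {
  check_positive(viscosity, "viscosity")
  if (!inherits(region, "guv_region")) stop_guv("`region` must be a guv_region", "dynamics")
  if (region$start < 1 || region$end > length(y)) {
    stop_guv("region indices outside the trace", "dynamics")
  }
  idx <- region$start:region$end
  ts <- t[idx]; ys <- y[idx]
  ok <- is.finite(ys) & is.finite(ts)
  if (sum(ok) < 4) stop_guv("fewer than 4 finite points in the selected region", "dynamics")
  fit <- lm(ys ~ ts, subset = ok)
  s <- unname(coef(fit)[2]); C <- unname(coef(fit)[1])
  if (s >= 0) {
    stop_guv("pore not closing in selected region (non-negative slope)", "dynamics")
  }
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (r2 < 0.9) {
    warn_guv(sprintf("low determination coefficient in the selected region (R^2 = %.3f)", r2),
             "fit_quality")
  }
  structure(
    list(
      gamma_pN = 1.5 * pi * viscosity * abs(s),
      slope = s,
      intercept = C,
      r_squared = r2,
      region = region,
      viscosity = viscosity,
      n_points = sum(ok),
      fit = fit,
      data = tibble::tibble(t = t, y = y,
                            in_region = seq_along(y) %in% idx)
    ),
    class = "guv_edge_tension"
  )
}

#' @export
print.guv_edge_tension <- function(x, ...) {
  cat("<guv_edge_tension>\n")
  cat(sprintf("  gamma     = %.3g pN\n", x$gamma_pN))
  cat(sprintf("  slope     = %.4g um^2/ms  (C = %.4g um^2)\n", x$slope, x$intercept))
  cat(sprintf("  R^2       = %.4f over %d points (%s region %d..%d)\n",
              x$r_squared, x$n_points, x$region$source, x$region$start, x$region$end))
  if (!is.null(x$geometry)) print(x$geometry)
  invisible(x)
}

#' Annotate the four stages of pore dynamics
#'
#' Pore life proceeds through growth, stabilization at a maximum radius,
#' slow (linear) closure and fast final closure. This annotates each frame
#' with a heuristic stage label for reporting; only the slow-closure stage
#' is used quantitatively (for the edge-tension fit). Growth runs up to the
#' first frame at the maximum smoothed radius; stable covers the plateau
#' within 10% of the maximum; slow closure is the detected (or supplied)
#' linear region of y; fast closure is everything after it.
#'
#' @param trace A smoothed `guv_pore_trace`.
#' @param region Optional `guv_region` (indices into the open-pore subset);
#'   computed with [detect_linear_region()] when absent.
#' @return The trace with a `stage` factor column
#'   (closed/growth/stable/slow/fast/invalid).
#' @export
classify_stages <- function(trace, region = NULL) {
  open_idx <- which(trace$is_open & trace$valid & trace$radius_um > 0)
  stage <- rep("closed", nrow(trace))
  stage[!trace$valid] <- "invalid"
  if (length(open_idx) > 0) {
    r <- trace$smoothed[open_idx]
    if (diff(range(r)) == 0) {
      # flat trace: every open frame sits at the plateau, nothing to fit
      stage[open_idx] <- "stable"
      trace$stage <- factor(stage,
                            levels = c("closed", "growth", "stable", "slow", "fast", "invalid"))
      return(trace)
    }
    if (is.null(region)) {
      region <- tryCatch(
        detect_linear_region(trace$y[open_idx], trace$time_ms[open_idx]),
        guvpore_error = function(e) NULL
      )
    }
    i_max <- which.max(r)
    plateau <- r >= 0.9 * max(r)
    st <- rep("slow", length(open_idx))
    if (i_max > 1) st[seq_len(i_max - 1)] <- "growth"
    last_plateau <- max(which(plateau))
    st[i_max:last_plateau] <- "stable"
    if (!is.null(region)) {
      st[region$start:region$end] <- "slow"
      if (region$end < length(open_idx)) {
        st[(region$end + 1):length(open_idx)] <- "fast"
      }
    }
    stage[open_idx] <- st
  } else {
    warn_guv("no open-pore frames to classify", "stages")
  }
  trace$stage <- factor(stage,
                        levels = c("closed", "growth", "stable", "slow", "fast", "invalid"))
  trace
}
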