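#' Sobel gradient magnitude
#'
#' Convolves the frame with the 3x3 horizontal and vertical Sobel kernels and
#' returns the gradient magnitude. In phase-contrast GUV images the sharp
#' dark-to-bright transition at the membrane produces a strong closed ridge
#' of gradient, which is what the downstream thresholding segments.
#'
#' @param frame A numeric matrix of at least 3 x 3.
#' @return A numeric matrix of the same size (replicated-border convolution).
#' @export
sobel_gradient <- function(frame) {
  if (!is.matrix(frame) || nrow(frame) < 3 || ncol(frame) < 3) {
    stop_guv("`frame` must be a matrix of at least 3 x 3", "segmentation")
  }
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  ky <- t(kx)
  gx <- EBImage::filter2(frame, kx, boundary = "replicate")
  gy <- EBImage::filter2(frame, ky, boundary = "replicate")
  sqrt(gx^2 + gy^2)
}

#' Isodata intensity threshold
#'
#' Iterative intermeans thresholding: starting from the midpoint of the
#' intensity range, the threshold is repeatedly replaced by the average of
#' the means of the two classes it induces, until it converges to the fixed
#' point T = (mean(x <= T) + mean(x > T)) / 2.
#'
#' @param frame Numeric matrix (or vector) with at least two distinct values.
#' @param tol Convergence tolerance as a fraction of the intensity range.
#' @return The converged threshold (scalar). Pixels strictly above it are
#'   foreground.
#' @export
isodata_threshold <- function(frame, tol = 1e-6) {
  x <- as.numeric(frame)
  rng <- range(x)
  if (diff(rng) == 0) stop_guv("cannot threshold constant image", "segmentation")
  t_cur <- mean(rng)
  eps <- tol * diff(rng)
  for (iter in seq_len(200)) {
    lo <- x[x <= t_cur]
    hi <- x[x > t_cur]
    if (length(hi) == 0L || length(lo) == 0L) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t_cur) <= eps) {
      t_cur <- t_new
      break
    }
    t_cur <- t_new
  }
  t_cur
}

#' Keep the bottom half of a mask or frame
#'
#' The pore under analysis is required to sit at the bottom of the image, so
#' per-frame pore analysis is restricted to rows `floor(h/2)+1 .. h`. For odd
#' heights the extra row goes to the bottom half, erring on the side of a
#' larger analysis region. Note that after this crop the top row passes
#' through the vesicle center, which is what makes the directional top-center
#' scan of [directional_label()] find the inner membrane contour rather than
#' the outer halo.
#'
#' @param mask A logical or numeric matrix with at least 2 rows.
#' @return The bottom-half rows of `mask`.
#' @export
bottom_half <- function(mask) {
  h <- nrow(mask)
  if (is.null(h) || h < 2) stop_guv("mask must have at least 2 rows", "segmentation")
  mask[(floor(h / 2) + 1L):h, , drop = FALSE]
}

#' Label connected components (8-connectivity)
#'
#' Diagonal neighbours count as connected: a one-pixel-thin membrane contour
#' running diagonally must remain a single component. Labels are assigned in
#' order of each component's first pixel in column-major order, so labeling
#' is deterministic.
#'
#' @param mask Logical matrix.
#' @return Integer matrix of the same size; 0 = background, 1..k = components.
#' @export
label_components <- function(mask) {
  if (!is.matrix(mask)) stop_guv("`mask` must be a matrix", "segmentation")
  mask <- mask > 0
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask)
  labels <- matrix(0L, h, w)
  if (length(fg) == 0L) return(labels)
  vid <- integer(h * w)
  vid[fg] <- seq_along(fg)
  rr <- ((fg - 1L) %% h) + 1L
  cc <- ((fg - 1L) %/% h) + 1L
  edges <- list()
  offsets <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (off in offsets) {
    r2 <- rr + off[1]; c2 <- cc + off[2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    nb <- (c2[ok] - 1L) * h + r2[ok]
    src <- fg[ok]
    hit <- mask[nb]
    if (any(hit)) edges[[length(edges) + 1L]] <- cbind(vid[src[hit]], vid[nb[hit]])
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges)) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  }
  comp <- igraph::components(g)$membership
  # renumber by first pixel (column-major) so labels are deterministic
  first_px <- vapply(split(fg, comp), min, numeric(1))
  relab <- integer(length(first_px))
  relab[order(first_px)] <- seq_along(first_px)
  labels[fg] <- relab[comp]
  labels
}

#' Remove small specks from a binary mask
#'
#' Dirt in the optics, floating membranous debris and halo perturbations
#' appear as small foreground elements that can mislead membrane
#' identification. Components whose area is strictly smaller than a
#' percentage of a reference membrane area are removed. The percentage is
#' controlled by a user-facing sensitivity on a 0-100 scale, mapped linearly
#' and inversely onto the 15%..0% range: higher sensitivity means a smaller
#' area threshold and therefore more surviving elements; sensitivity 100
#' removes nothing. Because the threshold is relative to the membrane area
#' itself, speck removal behaves consistently across image resolutions.
#'
#' @param mask Logical matrix.
#' @param reference_area Membrane reference area in pixels (> 0), measured
#'   from the first frame (see [reference_membrane_area()]).
#' @param sensitivity Integer-valued scale 0..100 (default 50, i.e. a 7.5%
#'   area threshold).
#' @return Logical matrix with small components removed.
#' @export
remove_specks <- function(mask, reference_area, sensitivity = 50) {
  check_positive(reference_area, "reference_area")
  if (!is_scalar_num(sensitivity) || sensitivity < 0 || sensitivity > 100) {
    stop_guv("`sensitivity` must be in [0, 100]", "params")
  }
  pct <- 0.15 * (1 - sensitivity / 100)
  thr <- pct * reference_area
  labels <- label_components(mask)
  k <- max(labels)
  if (k == 0L) {
    stop_guv("no membrane found: mask has no foreground elements", "segmentation")
  }
  areas <- tabulate(labels[labels > 0L], nbins = k)
  keep <- which(areas >= thr)   # strict "smaller than" removal
  if (length(keep) == 0L) {
    stop_guv("sensitivity too low: speck removal erased all elements", "segmentation")
  }
  out <- matrix(labels %in% keep & labels > 0L, nrow(mask), ncol(mask))
  out
}

#' Directional labeling of membrane elements
#'
#' Identifies which connected component the membrane contour belongs to on
#' each side of the vesicle by scanning for foreground pixels outward from a
#' scan origin (by default the top-center pixel, which after [bottom_half()]
#' lies at the vesicle center). The left scan visits pixels row by row
#' downward, moving column-by-column from the center toward the left edge;
#' the right scan mirrors it. The first foreground pixel hit on each side
#' selects that side's component.
#'
#' If both scans land in the same component the membrane contour is
#' continuous: the pore is closed. Different labels mean the contour is
#' interrupted: there is an open pore between the two elements.
#'
#' @param mask Logical matrix (typically despeckled).
#' @param origin_row Row from which scanning starts (default 1, the top row).
#' @return A list of class `guv_labeled` with `labels` (integer matrix),
#'   `left_label`, `right_label` (0 when no foreground was found on that
#'   side) and `center_col`.
#' @export
directional_label <- function(mask, origin_row = 1L) {
  labels <- label_components(mask)
  h <- nrow(mask); w <- ncol(mask)
  cc <- floor(w / 2) + 1L
  origin_row <- max(1L, min(h, as.integer(origin_row)))
  fg <- which(labels > 0L, arr.ind = TRUE)
  fg <- fg[fg[, 1] >= origin_row, , drop = FALSE]
  side_label <- function(cols_ok, key_col) {
    sel <- fg[cols_ok, , drop = FALSE]
    if (nrow(sel) == 0L) return(0L)
    key <- (sel[, 1] - origin_row) * w + key_col(sel[, 2])
    px <- sel[which.min(key), ]
    labels[px[1], px[2]]
  }
  left <- side_label(fg[, 2] <= cc, function(col) cc - col)
  right <- side_label(fg[, 2] >= cc, function(col) col - cc)
  if (left == 0L && right == 0L) {
    stop_guv("membrane lost in frame: no foreground on either side", "segmentation")
  }
  structure(list(labels = labels, left_label = as.integer(left),
                 right_label = as.integer(right), center_col = cc),
            class = "guv_labeled")
}

# minimum-distance pixel pair between two labeled components;
# chunked brute force over all pixel pairs
nearest_pair <- function(labels, a, b, chunk = 2048L) {
  pa <- which(labels == a, arr.ind = TRUE)
  pb <- which(labels == b, arr.ind = TRUE)
  best <- Inf; best_a <- NULL; best_b <- NULL
  for (s in seq(1L, nrow(pa), by = chunk)) {
    ii <- s:min(s + chunk - 1L, nrow(pa))
    d2 <- outer(pa[ii, 1], pb[, 1], "-")^2 + outer(pa[ii, 2], pb[, 2], "-")^2
    m <- which.min(d2)
    if (d2[m] < best) {
      best <- d2[m]
      ai <- ((m - 1L) %% length(ii)) + 1L
      bi <- ((m - 1L) %/% length(ii)) + 1L
      best_a <- pa[ii[ai], ]
      best_b <- pb[bi, ]
    }
  }
  list(dist = sqrt(best), a = best_a, b = best_b)
}

#' Measure the pore width from labeled membrane elements
#'
#' When the left and right scans of [directional_label()] select different
#' components, the pore size (2r, a diameter) is the Euclidean distance
#' between the edges of the pore: the pair of pixels, one in each element,
#' at minimum distance from each other. For a pore at the bottom of an
#' equatorially projected vesicle this is the gap chord. When both scans
#' select the same element the pore is closed and the diameter is 0.
#'
#' If only one side of the membrane was found, the pore cannot be measured
#' against the image border; the frame is flagged open but its diameter is
#' marked invalid (`NA`) with a warning, signalling an off-frame pore.
#'
#' @param labeled A `guv_labeled` object from [directional_label()].
#' @param pixel_size Micrometers per pixel.
#' @return A one-row [tibble::tibble()] with columns `is_open`,
#'   `pore_diameter_um` (0 when closed, `NA` when invalid), `valid`, and list
#'   column `edge_points` (2 x 2 matrix of row/col endpoints, or `NULL`).
#' @export
measure_pore <- function(labeled, pixel_size) {
  check_positive(pixel_size, "pixel_size")
  l <- labeled$left_label; r <- labeled$right_label
  if (l != 0L && l == r) {
    return(tibble::tibble(is_open = FALSE, pore_diameter_um = 0,
                          valid = TRUE, edge_points = list(NULL)))
  }
  if (l == 0L || r == 0L) {
    warn_guv(paste0("membrane found on one side only; pore extends to the ",
                    "image border and its diameter is not reported"),
             "segmentation")
    return(tibble::tibble(is_open = TRUE, pore_diameter_um = NA_real_,
                          valid = FALSE, edge_points = list(NULL)))
  }
  np <- nearest_pair(labeled$labels, l, r)
  tibble::tibble(
    is_open = TRUE,
    pore_diameter_um = pixel_size * np$dist,
    valid = TRUE,
    edge_points = list(rbind(np$a, np$b))
  )
}

#' Reference membrane area from the first frame
#'
#' The speck-removal threshold is defined relative to the GUV membrane area
#' in the first frame (vesicle closed), taken as the largest connected
#' component of the first frame's bottom-half binary mask.
#'
#' @param mask Bottom-half binary mask of the first frame.
#' @return Area in pixels of the largest component.
#' @export
reference_membrane_area <- function(mask) {
  labels <- label_components(mask)
  if (max(labels) == 0L) {
    stop_guv("no membrane found in the first frame", "segmentation")
  }
  max(tabulate(labels[labels > 0L]))
}

#' Segment one frame and measure its pore
#'
#' Runs the per-frame chain: Sobel gradient, isodata thresholding,
#' bottom-half restriction, speck removal, directional labeling and pore
#' measurement.
#'
#' @param frame Numeric intensity matrix.
#' @param pixel_size Micrometers per pixel.
#' @param reference_area Membrane reference area in pixels.
#' @param sensitivity Speck-removal sensitivity, 0..100.
#' @return As [measure_pore()], plus attribute `"mask"` (the despeckled
#'   bottom-half mask) and `"labeled"`.
#' @export
segment_frame <- function(frame, pixel_size, reference_area, sensitivity = 50) {
  g <- sobel_gradient(frame)
  thr <- isodata_threshold(g)
  mask <- bottom_half(g > thr)
  mask <- remove_specks(mask, reference_area, sensitivity)
  lab <- directional_label(mask)
  res <- measure_pore(lab, pixel_size)
  attr(res, "mask") <- mask
  attr(res, "labeled") <- lab
  res
}
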