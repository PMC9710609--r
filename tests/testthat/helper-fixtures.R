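# drawing helpers and independent brute-force oracles shared across tests

acq <- function(fps = 360, ps = 0.25, visc = 1) {
  acquisition_params(frame_rate = fps, pixel_size = ps, viscosity = visc)
}

draw_disk <- function(h, w, cy, cx, r) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rows - cy)^2 + (cols - cx)^2 <= r^2
}

draw_ring <- function(h, w, cy, cx, r, width = 2) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  d2 <- (rows - cy)^2 + (cols - cx)^2
  d2 <= r^2 & d2 > (r - width)^2
}

# intensity stack (list of identical frames) holding one bright ring on black
ring_stack <- function(h = 400, w = 400, cy = 200, cx = 200, r = 50,
                       width = 3, n = 3, level = 200) {
  fr <- matrix(0, h, w)
  fr[draw_ring(h, w, cy, cx, r, width)] <- level
  frame_stack(array(rep(fr, n), dim = c(h, w, n)), bit_depth = 8L,
              params = acq())
}

# brute-force grayscale morphological envelope (opening) with a disc
# structuring element; pixels outside the image are ignored, matching the
# package's background estimator
brute_opening <- function(img, radius) {
  h <- nrow(img); w <- ncol(img)
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  shift_acc <- function(x, worst, better) {
    out <- matrix(worst, h, w)
    for (k in seq_len(nrow(offs))) {
      dr <- offs$dr[k]; dc <- offs$dc[k]
      r1 <- max(1, 1 + dr):min(h, h + dr)
      c1 <- max(1, 1 + dc):min(w, w + dc)
      out[r1 - dr, c1 - dc] <- better(out[r1 - dr, c1 - dc], x[r1, c1])
    }
    out
  }
  er <- shift_acc(img, Inf, pmin)
  shift_acc(er, -Inf, pmax)
}

# residual of the isodata fixed-point equation at threshold T
isodata_residual <- function(x, T) {
  x <- as.numeric(x)
  abs(T - (mean(x[x <= T]) + mean(x[x > T])) / 2)
}

# brute-force minimum pairwise distance between two pixel sets
brute_min_dist <- function(mask_a, mask_b) {
  pa <- which(mask_a, arr.ind = TRUE)
  pb <- which(mask_b, arr.ind = TRUE)
  best <- Inf
  for (i in seq_len(nrow(pa))) {
    d <- sqrt((pa[i, 1] - pb[, 1])^2 + (pa[i, 2] - pb[, 2])^2)
    best <- min(best, min(d))
  }
  best
}

# hand convolution of 3x3 Sobel kernels with replicated borders
brute_sobel <- function(frame) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  ky <- t(kx)
  h <- nrow(frame); w <- ncol(frame)
  pad <- frame[c(1, seq_len(h), h), c(1, seq_len(w), w)]
  gx <- matrix(0, h, w); gy <- gx
  for (i in seq_len(h)) for (j in seq_len(w)) {
    nb <- pad[i:(i + 2), j:(j + 2)]
    gx[i, j] <- sum(nb * kx)
    gy[i, j] <- sum(nb * ky)
  }
  sqrt(gx^2 + gy^2)
}

# small, quick-to-render synthetic study: ~30 frames at 116 px
quick_spec <- function(R_true = 12, r_max = 0.3 * R_true, ...) {
  synthetic_spec(R_true = R_true, gamma_true = 40, r_max = r_max, ...)
}

# ground-truth trace turned into the measurement table the dynamics layer
# expects, bypassing imaging (for dynamics-only tests)
truth_measurements <- function(truth) {
  tibble::tibble(
    is_open = truth$r_true > 0,
    pore_diameter_um = 2 * truth$r_true,
    valid = TRUE
  )
}
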