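test_that("Sobel gradient matches hand convolution and its symmetries", {
  # constant frame: zero gradient (up to FFT round-off in the convolution)
  expect_lt(max(abs(sobel_gradient(matrix(17, 9, 9)))), 1e-8)

  # vertical step edge: maximal response at the step, magnitude scales with h
  for (h in c(40, 80)) {
    f <- matrix(0, 5, 5); f[, 3:5] <- h
    g <- sobel_gradient(f)
    expect_equal(g, brute_sobel(f), tolerance = 1e-10)
    # the two columns bracketing the step carry the maximal response 4h
    expect_equal(g[3, 2], 4 * h)
    expect_equal(g[3, 3], 4 * h)
    expect_equal(max(g), 4 * h)
  }
  f1 <- matrix(0, 5, 5); f1[, 3:5] <- 40
  f2 <- matrix(0, 5, 5); f2[, 3:5] <- 80
  expect_equal(2 * sobel_gradient(f1), sobel_gradient(f2))

  set.seed(3)
  r <- matrix(runif(12 * 17), 12, 17)
  expect_equal(sobel_gradient(t(r)), t(sobel_gradient(r)), tolerance = 1e-9)
  expect_error(sobel_gradient(matrix(0, 2, 5)), "3 x 3")
})

test_that("isodata threshold is the intermeans fixed point", {
  # two-valued image: threshold is the midpoint after one iteration
  two <- matrix(c(rep(10, 100), rep(200, 100)), 10, 20)
  expect_equal(isodata_threshold(two), 105)

  expect_error(isodata_threshold(matrix(5, 4, 4)), "constant")

  # random frames: fixed-point residual within half a gray level, and the
  # partition agrees with the best candidate from an exhaustive scan
  set.seed(11)
  for (k in 1:10) {
    x <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
    T <- isodata_threshold(x)
    expect_lte(isodata_residual(x, T), 0.5)
    # the exhaustive scan finds no materially better fixed point, and its
    # best candidate sits within a few gray levels of ours (the intermeans
    # map can have several near-fixed points on discrete data)
    cands <- min(x):(max(x) - 1)
    res_all <- vapply(cands, function(tc) isodata_residual(x, tc), numeric(1))
    best <- cands[which.min(res_all)]
    expect_lte(isodata_residual(x, T), min(res_all) + 0.5)
    expect_lte(abs(T - best), 3)
  }

  # shifting every pixel shifts the threshold
  set.seed(12)
  x <- matrix(sample(0:200, 256, replace = TRUE), 16, 16)
  expect_equal(isodata_threshold(x + 30), isodata_threshold(x) + 30,
               tolerance = 1)
})

test_that("bottom-half restriction keeps the lower rows (extra row when odd)", {
  m100 <- matrix(seq_len(100 * 4), 100, 4)
  b <- bottom_half(m100)
  expect_equal(nrow(b), 50)
  expect_equal(b[1, ], m100[51, ])

  m101 <- matrix(seq_len(101 * 4), 101, 4)
  b1 <- bottom_half(m101)
  expect_equal(nrow(b1), 51)
  expect_equal(b1[1, ], m101[51, ])

  expect_equal(nrow(bottom_half(bottom_half(m100))), 25)
})

test_that("connected components use 8-connectivity and deterministic labels", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE   # diagonal pair: one component
  m[5, 5] <- TRUE                    # isolated pixel: another
  lab <- label_components(m)
  expect_equal(max(lab), 2L)
  expect_equal(lab[2, 2], lab[3, 3])
  expect_equal(lab[2, 2], 1L)        # first-pixel order
  expect_equal(lab[5, 5], 2L)
  expect_equal(max(label_components(matrix(FALSE, 4, 4))), 0L)
})

test_that("speck removal drops elements below the area threshold, strictly", {
  m <- matrix(FALSE, 60, 80)
  m[draw_ring(60, 80, 10, 40, 28, 4)] <- TRUE   # large membrane piece
  big_area <- sum(m)
  m[5, 5] <- TRUE; m[50, 70] <- TRUE; m[30, 3] <- TRUE   # specks
  out <- remove_specks(m, reference_area = big_area, sensitivity = 50)
  expect_equal(sum(out), big_area)
  expect_false(out[5, 5])

  # sensitivity 100 maps to a 0% threshold: identity
  expect_equal(remove_specks(m, big_area, 100), m)

  # area exactly at the threshold survives ("smaller than" removal)
  m2 <- matrix(FALSE, 40, 40)
  m2[draw_disk(40, 40, 12, 12, 8)] <- TRUE
  m2[30:32, 30:34] <- TRUE           # 15 px block
  thr_area <- 15
  ref <- thr_area / 0.075            # sensitivity 50 -> 7.5% of reference
  out2 <- remove_specks(m2, ref, 50)
  expect_true(all(out2[30:32, 30:34]))
  m2[38, 38] <- TRUE                 # 1 px: below the threshold, removed
  expect_false(remove_specks(m2, ref, 50)[38, 38])

  expect_error(remove_specks(m2, 1e6, 0), "sensitivity too low")
  expect_error(remove_specks(matrix(FALSE, 8, 8), 100, 50), "no membrane")
})

test_that("speck removal is monotone: foreground only shrinks", {
  set.seed(21)
  for (k in 1:5) {
    m <- matrix(runif(900) > 0.7, 30, 30)
    prev <- m
    for (s in c(90, 60, 30, 5)) {
      out <- tryCatch(remove_specks(m, 50, s), guvpore_error = function(e) NULL)
      if (is.null(out)) break
      expect_true(all(prev | !out))      # subset of input
      expect_lte(sum(out), sum(prev))
      prev <- out
    }
  }
})

test_that("directional labeling tells closed from open membranes", {
  # unbroken semicircular arc spanning the bottom half: closed
  h <- 40; w <- 80
  arc <- matrix(FALSE, h, w)
  arc[draw_ring(h, w, 1, 40, 32, 3)] <- TRUE
  lab <- directional_label(arc)
  expect_equal(lab$left_label, lab$right_label)

  # cut a gap at the bottom of the arc: open
  gap <- arc
  gap[, 37:44] <- FALSE
  labg <- directional_label(gap)
  expect_gt(labg$left_label, 0L)
  expect_gt(labg$right_label, 0L)
  expect_true(labg$left_label != labg$right_label)

  # single foreground pixel at top-center belongs to both sides
  one <- matrix(FALSE, 10, 10)
  one[1, 6] <- TRUE
  lab1 <- directional_label(one)
  expect_equal(lab1$left_label, 1L)
  expect_equal(lab1$right_label, 1L)

  expect_error(directional_label(matrix(FALSE, 10, 10)), "membrane lost")
})

test_that("pore width equals the brute-force minimum component distance", {
  # two tips at (60,40) and (60,52): 12 px * 0.5 um/px -> 6 um
  m <- matrix(FALSE, 128, 100)
  m[55:60, 30:40] <- TRUE
  m[55:60, 52:62] <- TRUE
  lab <- directional_label(m)
  meas <- measure_pore(lab, pixel_size = 0.5)
  expect_true(meas$is_open)
  expect_equal(meas$pore_diameter_um, 6)
  a <- m & col(m) <= 45
  b <- m & col(m) > 45
  expect_equal(meas$pore_diameter_um / 0.5, brute_min_dist(a, b))

  # randomly drawn two-arc fixtures against the oracle
  set.seed(31)
  for (k in 1:6) {
    mm <- matrix(FALSE, 64, 64)
    gap_half <- sample(2:10, 1)
    mm[draw_ring(64, 64, 2, 32, 26, 3) &
         col(matrix(0, 64, 64)) < 32 - gap_half] <- TRUE
    mm[draw_ring(64, 64, 2, 32, 26, 3) &
         col(matrix(0, 64, 64)) > 32 + gap_half] <- TRUE
    lab2 <- directional_label(mm)
    meas2 <- measure_pore(lab2, pixel_size = 1)
    a <- lab2$labels == lab2$left_label
    b <- lab2$labels == lab2$right_label
    expect_equal(meas2$pore_diameter_um, brute_min_dist(a, b))
  }

  # closed arc: zero diameter, no endpoints
  closed <- matrix(FALSE, 40, 80)
  closed[draw_ring(40, 80, 1, 40, 30, 3)] <- TRUE
  mc <- measure_pore(directional_label(closed), 0.5)
  expect_false(mc$is_open)
  expect_equal(mc$pore_diameter_um, 0)
  expect_null(mc$edge_points[[1]])

  # one-sided membrane: open but invalid, with a warning
  half <- matrix(FALSE, 40, 80)
  half[draw_ring(40, 80, 1, 40, 30, 3) & col(matrix(0, 40, 80)) < 38] <- TRUE
  expect_warning(mh <- measure_pore(directional_label(half), 0.5),
                 "one side")
  expect_true(mh$is_open)
  expect_true(is.na(mh$pore_diameter_um))
  expect_false(mh$valid)

  # 1 px gap: smallest resolvable pore, still matches the oracle
  tiny <- matrix(FALSE, 20, 21)
  tiny[10, 1:10] <- TRUE
  tiny[10, 12:21] <- TRUE
  lt <- directional_label(tiny)
  mt <- measure_pore(lt, 0.5)
  expect_gte(mt$pore_diameter_um, 0.5)
  expect_equal(mt$pore_diameter_um / 0.5,
               brute_min_dist(lt$labels == lt$left_label,
                              lt$labels == lt$right_label))
})

test_that("per-frame segmentation is deterministic and translation-equivariant", {
  spec <- quick_spec(seed = 5)
  truth <- generate_trace(spec)
  stack <- render_stack(truth, spec)
  i <- which(truth$r_true > 1.5)[4]
  frame <- stack$frames[, , i]
  ref <- reference_membrane_area(bottom_half({
    g <- sobel_gradient(stack$frames[, , 1]); g > isodata_threshold(g)
  }))

  m1 <- segment_frame(frame, 0.25, ref, 50)
  m2 <- segment_frame(frame, 0.25, ref, 50)
  expect_identical(m1$pore_diameter_um, m2$pore_diameter_um)
  expect_identical(m1$edge_points[[1]], m2$edge_points[[1]])

  # shift the frame a few pixels; the endpoints shift along, the width
  # changes by less than a pixel
  dx <- 3L; dy <- 2L
  h <- nrow(frame); w <- ncol(frame)
  shifted <- matrix(median(frame), h, w)
  shifted[(1 + dy):h, (1 + dx):w] <- frame[1:(h - dy), 1:(w - dx)]
  m3 <- segment_frame(shifted, 0.25, ref, 50)
  expect_lt(abs(m3$pore_diameter_um - m1$pore_diameter_um), 0.25)
  shift_obs <- m3$edge_points[[1]] - m1$edge_points[[1]]
  expect_true(all(abs(shift_obs[, 1] - dy) <= 1))
  expect_true(all(abs(shift_obs[, 2] - dx) <= 1))
})
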