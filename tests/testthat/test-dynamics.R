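geo_const <- function(R) suppressWarnings(radius_gate(R, R))

test_that("the transformed ordinate R^2 ln r follows the closed forms", {
  params <- acq(fps = 1000)
  meas <- tibble::tibble(
    is_open = c(FALSE, TRUE, TRUE, TRUE, FALSE),
    pore_diameter_um = c(0, 2, 2 * exp(1), 4, 0),
    valid = TRUE
  )
  tr <- build_trace(meas, geo_const(10), params)
  expect_equal(tr$time_ms, 0:4)
  expect_equal(tr$y[2], 0)              # r = 1 um -> ln 1 = 0, any R
  expect_equal(tr$y[3], 100)            # R = 10, r = e -> R^2 = 100
  expect_true(all(is.na(tr$y[c(1, 5)])))

  expect_error(
    build_trace(tibble::tibble(is_open = FALSE, pore_diameter_um = 0,
                               valid = TRUE)[rep(1, 4), ],
                geo_const(10), params),
    "no pore")
})

test_that("a generated ground-truth trace rebuilds to an exact line", {
  spec <- quick_spec(seed = 1)
  truth <- generate_trace(spec)
  tr <- build_trace(truth_measurements(truth), geo_const(spec$R_true),
                    attr(truth, "spec") |>
                      (\(s) acquisition_params(s$frame_rate, s$pixel_size,
                                               s$viscosity))())
  slow <- truth$stage == "slow"
  fit <- lm(tr$y[slow] ~ tr$time_ms[slow])
  expect_equal(unname(coef(fit)[2]), attr(truth, "slope_true"),
               tolerance = 1e-9)
  expect_lt(max(abs(residuals(fit))), 1e-8)
})

test_that("smoothing is a shrinking-window moving average on open frames", {
  params <- acq(fps = 1000)
  lin <- tibble::tibble(is_open = TRUE, valid = TRUE)[rep(1, 11), ]
  lin$pore_diameter_um <- 2 * (20 - seq_len(11))
  tr <- build_trace(lin, geo_const(10), params)

  expect_equal(smooth_trace(tr, 1)$smoothed, tr$radius_um)   # identity

  cst <- lin; cst$pore_diameter_um <- 6
  trc <- build_trace(cst, geo_const(10), params)
  expect_equal(smooth_trace(trc, 5)$smoothed, trc$radius_um) # constants

  sm <- smooth_trace(tr, 5)$smoothed                          # linear interior
  expect_equal(sm[3:9], tr$radius_um[3:9])
  expect_equal(sm[1], tr$radius_um[1])                        # shrunk to width 1

  expect_error(smooth_trace(tr, 13), "longer")
  expect_error(smooth_trace(tr, 4), "odd")
})

test_that("linear-region detection finds the slow-closure stage", {
  # steep rise, exact line of slope -2 (20 points), steep fall
  t <- 0:29
  y <- c(300, 420, 350, 380, 320,
         50 - 2 * (0:19),
         -500, -1100, -1800, -2600, -3500)
  reg <- detect_linear_region(y, t)
  expect_equal(reg$start, 6L)
  expect_equal(reg$end, 25L)
  expect_false(reg$fallback)

  # a pure exact line is selected whole
  y2 <- 7 - 3 * t
  reg2 <- detect_linear_region(y2, t)
  expect_equal(c(reg2$start, reg2$end), c(1L, 30L))

  # equally long candidates: the latest-starting window wins
  y3 <- c(900, 10 - 3 * (0:9), 700, -200, 650, 5 - 3 * (0:9), 800)
  t3 <- seq_along(y3)
  reg3 <- detect_linear_region(y3, t3)
  expect_equal(reg3$start, 15L)
  expect_equal(reg3$end, 24L)

  # pure noise: fallback with a warning
  set.seed(8)
  yn <- rnorm(12)
  expect_warning(regn <- detect_linear_region(yn, 1:12), "fall")
  expect_true(regn$fallback)

  expect_error(detect_linear_region(1:5, 1:5), "too short")
})

test_that("slope converts to edge tension by gamma = (3 pi / 2) eta |s|", {
  t <- seq(0, 40, by = 2)

  fit1 <- fit_edge_tension(1000 - 8.531 * t, t, manual_region(1, length(t)),
                           viscosity = 1)
  expect_lt(abs(fit1$gamma_pN - 40.2) / 40.2, 0.001)
  expect_equal(fit1$slope, -8.531, tolerance = 1e-10)
  expect_equal(fit1$intercept, 1000, tolerance = 1e-8)
  expect_equal(fit1$r_squared, 1)

  fit2 <- fit_edge_tension(5 - 1 * t, t, manual_region(1, length(t)), 1)
  expect_equal(fit2$gamma_pN, 3 * pi / 2, tolerance = 1e-10)

  # gamma is linear in viscosity
  fit3 <- fit_edge_tension(5 - 1 * t, t, manual_region(1, length(t)), 2)
  expect_equal(fit3$gamma_pN, 2 * fit2$gamma_pN)

  # and invariant under a shift of the time origin
  fit4 <- fit_edge_tension(5 - 1 * t, t + 1234, manual_region(1, length(t)), 1)
  expect_equal(fit4$gamma_pN, fit2$gamma_pN, tolerance = 1e-10)

  expect_error(fit_edge_tension(5 + 2 * t, t, manual_region(1, length(t)), 1),
               "not closing")
  set.seed(9)
  expect_warning(
    fit_edge_tension(-0.05 * t + rnorm(length(t)), t,
                     manual_region(1, length(t)), 1),
    "determination")
})

test_that("tidy and glance summarise the fit in broom conventions", {
  t <- seq(0, 30, by = 2)
  fit <- fit_edge_tension(100 - 4 * t, t, manual_region(1, length(t)), 1)
  td <- tidy(fit)
  expect_equal(td$term, c("intercept", "slope"))
  expect_equal(td$estimate, c(100, -4), tolerance = 1e-10)
  gl <- glance(fit)
  expect_equal(gl$gamma_pN, 1.5 * pi * 4, tolerance = 1e-10)
  expect_equal(gl$n_points, length(t))
})

test_that("stage classification recovers the four stages of a synthetic trace", {
  spec <- quick_spec(seed = 4, t_growth = 12, t_stable = 18)
  truth <- generate_trace(spec)
  params <- acquisition_params(spec$frame_rate, spec$pixel_size, spec$viscosity)
  tr <- build_trace(truth_measurements(truth), geo_const(spec$R_true), params)
  tr <- smooth_trace(tr, 5)
  st <- classify_stages(tr)

  bounds <- function(x, lev) range(which(x == lev))
  for (lev in c("growth", "stable", "slow")) {
    expect_lte(max(abs(bounds(st$stage, lev) - bounds(truth$stage, lev))), 2)
  }

  # monotone decreasing trace: growth is empty
  dec <- tibble::tibble(is_open = TRUE, valid = TRUE)[rep(1, 12), ]
  dec$pore_diameter_um <- 2 * exp(seq(2, 0.5, length.out = 12))
  trd <- smooth_trace(build_trace(dec, geo_const(10), acq(1000)), 1)
  std <- suppressWarnings(classify_stages(trd))
  expect_equal(sum(std$stage == "growth"), 0L)

  # flat trace: everything stable, nothing to fit
  flat <- tibble::tibble(is_open = TRUE, valid = TRUE)[rep(1, 10), ]
  flat$pore_diameter_um <- 5
  trf <- smooth_trace(build_trace(flat, geo_const(10), acq(1000)), 1)
  stf <- classify_stages(trf)
  expect_true(all(stf$stage == "stable"))
})
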