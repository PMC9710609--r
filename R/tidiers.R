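#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the edge-tension regression
#'
#' Returns the regression coefficients of the linear fit of R^2 ln r versus
#' time over the selected region, one row per term, in broom convention.
#'
#' @param x A `guv_edge_tension` object.
#' @param ... Unused.
#' @return A tibble with columns `term` (`"intercept"` in um^2,
#'   `"slope"` in um^2/ms), `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @method tidy guv_edge_tension
#' @export
tidy.guv_edge_tension <- function(x, ...) {
  cf <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = unname(cf[, 1]),
    std.error = unname(cf[, 2]),
    statistic = unname(cf[, 3]),
    p.value = unname(cf[, 4])
  )
}

#' One-row summary of an edge-tension analysis
#'
#' @param x A `guv_edge_tension` object.
#' @param ... Unused.
#' @return A one-row tibble with the edge tension (pN), the fit slope and
#'   intercept, the determination coefficient, the number of fitted points,
#'   the region bounds and source, and (when the object came from
#'   [pore_analyze()]) the vesicle radii and the 5% gate flag.
#' @method glance guv_edge_tension
#' @export
glance.guv_edge_tension <- function(x, ...) {
  out <- tibble::tibble(
    gamma_pN = x$gamma_pN,
    slope = x$slope,
    intercept = x$intercept,
    r.squared = x$r_squared,
    n_points = x$n_points,
    region_start = x$region$start,
    region_end = x$region$end,
    region_source = x$region$source
  )
  if (!is.null(x$geometry)) {
    out$radius_before_um <- x$geometry$radius_before
    out$radius_after_um <- x$geometry$radius_after
    out$radius_deviation <- x$geometry$deviation
    out$exceeds_radius_gate <- x$geometry$exceeds_gate
  }
  out
}
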