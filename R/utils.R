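#' @importFrom rlang abort warn %||%
#' @importFrom stats rnorm lm coef
#' @importFrom utils write.table packageVersion
NULL

# abort with a guvpore-classed condition so callers can catch by class
stop_guv <- function(msg, class, ...) {
  abort(msg, class = c(paste0("guvpore_error_", class), "guvpore_error"), ...)
}

warn_guv <- function(msg, class = "general") {
  warn(msg, class = c(paste0("guvpore_warning_", class), "guvpore_warning"))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# full-scale value of a bit depth (8 -> 255, 16 -> 65535)
scale_max <- function(bit_depth) 2^bit_depth - 1

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_positive <- function(x, name) {
  if (!is_scalar_num(x) || x <= 0) {
    stop_guv(sprintf("`%s` must be a single positive number", name), "params")
  }
  invisible(x)
}
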