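#' Round half away from zero
#'
#' Base R's \code{round()} rounds half to even ("banker's rounding"); the
#' gait-period unification rule and the label-noise injection count both use
#' conventional half-up rounding, so it is pinned down here.
#'
#' @param x numeric vector.
#' @return \code{x} rounded to the nearest integer, ties away from zero.
#' @keywords internal
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_plantar <- function(msg, class) {
  stop(structure(
    class = c(class, "plantarssl_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
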