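#' Round half away from zero
#'
#' Presentation rounding used throughout the package: ties go away from zero
#' (so 88.235 -> 88.24), unlike base [round()] which rounds half to even.
#' A tiny guard absorbs binary-representation error on decimal ties.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(88.235, 2)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(..., class = "lodgedetect_input_error") {
  rlang::abort(paste0(...), class = c(class, "lodgedetect_error"))
}

check_fraction <- function(x, name, lo = 0, hi = 1, closed_lo = TRUE, closed_hi = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (closed_lo) x >= lo else x > lo) &&
    (if (closed_hi) x <= hi else x < hi)
  if (!ok) {
    stop_input(sprintf(
      "`%s` must be a finite number in %s%g, %g%s, got %s",
      name, if (closed_lo) "[" else "(", lo, hi, if (closed_hi) "]" else ")",
      paste(format(x), collapse = ", ")
    ), class = "lodgedetect_parameter_error")
  }
  invisible(x)
}

band_names <- function() c("blue", "green", "red", "nir")

class_names <- function() c("background", "nonlodged_maize", "lodged_maize")
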