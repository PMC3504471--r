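# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounding convention used for all reported ages and percentages: ties go
#' away from zero (so 60.5 -> 61, -60.5 -> -61), unlike base \code{round()}'s
#' round-half-even. Reproduces printed values such as 201/217 gestational days.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# scalar positive check with informative message
assert_pos <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_input("`%s` must be finite and > 0", name)
  }
  invisible(x)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
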