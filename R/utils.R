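#' Round half away from zero
#'
#' Fixed-point rounding with ties going away from zero, the convention used
#' when reporting percentages to one decimal. Base `round()` rounds ties to
#' even, which would report 97.05 as 97.0 rather than 97.1.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# 256-level MATLAB-style jet lookup table, rows = RGB in 0..255
jet_lut <- function(n = 256) {
  ramp <- grDevices::colorRamp(c(
    "#00007F", "#0000FF", "#007FFF", "#00FFFF",
    "#7FFF7F", "#FFFF00", "#FF7F00", "#FF0000", "#7F0000"
  ))
  round(ramp(seq(0, 1, length.out = n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
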