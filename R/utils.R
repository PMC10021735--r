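#' Round half away from zero
#'
#' Reporting-layer rounding for distance tables: halves round up (73.085 ->
#' 73.09), unlike [round()]'s round-half-to-even. Full precision is kept
#' everywhere internally; use this only when printing.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2, the table convention).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  z <- abs(x) * scale
  # relative epsilon so a decimal half stored just below .5 in binary
  # (73.085 * 100 = 7308.4999...) still rounds up
  sign(x) * floor(z + 0.5 + 1e-9 * pmax(z, 1)) / scale
}

euclid <- function(p, q) sqrt(sum((p - q)^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
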