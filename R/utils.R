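#' Round half away from zero
#'
#' The rounding rule used for report tables (2-decimal percentages).
#' Chained statistics (group means, SDs, distances) always use the
#' unrounded values.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Event names with hyphens, as used in written tables (DM-CHG etc.).
.hyphen <- function(x) gsub("_", "-", x, fixed = TRUE)
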