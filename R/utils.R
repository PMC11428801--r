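# Physical constants (SI units); temperature defaults to 298.15 K throughout.
.GAS_CONSTANT <- 8.314   # J mol^-1 K^-1
.FARADAY      <- 96485   # C mol^-1
.LN10         <- log(10)

# log10(sum(10^x)) with max-shift, safe for |x| up to thousands of log units
lse10 <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log10(sum(10^(x - m)))
}

# RT/(zF) in volts per natural-log unit
nernst_factor <- function(temperature = 298.15, z = 2) {
  .GAS_CONSTANT * temperature / (z * .FARADAY)
}

#' Round half away from zero
#'
#' Rounds to a fixed number of decimals with ties going away from zero
#' (so -0.1705 becomes -0.171), the convention used for tabulated potentials,
#' as opposed to the banker's rounding of [round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals.
#' @examples
#' round_half_away(c(-0.1705, 0.0495), 3)
#' @export
round_half_away <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# number of set bits for each of the masks 0 .. 2^n - 1
bit_counts <- function(n) {
  masks <- 0:(2^n - 1)
  counts <- integer(length(masks))
  for (i in seq_len(n)) {
    counts <- counts + as.integer(bitwAnd(masks, bitwShiftL(1L, i - 1L)) > 0L)
  }
  counts
}

# indices (1-based site positions) of the bits set in a single mask
mask_bits <- function(mask, n) {
  which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) > 0L)
}
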