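# One-dimensional low-discrepancy sequence. The first dimension of a Sobol
# sequence is the van der Corput radical-inverse sequence in base 2; a seeded
# random digital (XOR) shift randomizes the points while preserving dyadic
# equidistribution, so for n = 2^m every dyadic interval of width 2^-m
# contains exactly one point.

.SOBOL_BITS <- 30L

# Bit-reverse non-negative integers (< 2^30) over .SOBOL_BITS bits.
reverse_bits <- function(i, nbits = .SOBOL_BITS) {
  x <- as.integer(i)
  if (any(x < 0L)) stop("indices must be non-negative")
  r <- integer(length(x))
  for (b in seq_len(nbits)) {
    r <- bitwShiftL(r, 1L) + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  r
}

# n points of the digitally shifted radical-inverse sequence in [0, 1).
sobol_unit <- function(n, seed = NULL) {
  stopifnot(n >= 1, n < 2^.SOBOL_BITS)
  shift <- 0L
  if (!is.null(seed)) {
    shift <- with_local_seed(seed,
      as.integer(floor(stats::runif(1) * 2^.SOBOL_BITS)))
  }
  idx <- reverse_bits(seq_len(n) - 1L)
  bitwXor(idx, shift) / 2^.SOBOL_BITS
}

#' Sample stenosis severities from a low-discrepancy sequence
#'
#' Draws \code{n} stenosis severities from a (digitally shifted) Sobol
#' sequence scaled affinely to \code{[lo, hi]}, giving a near-uniform,
#' stratified coverage of the severity window. With \code{n = 1024} and the
#' default window each of ten equal-width bins receives 102-103 samples.
#'
#' @param n number of severities to draw.
#' @param lo,hi severity bounds (fractional radius reduction), 0 <= lo < hi <= 1.
#' @param seed integer seed for the digital shift; the sequence is fully
#'   reproducible for a fixed seed.
#' @return numeric vector of length \code{n} in \code{[lo, hi)}.
#' @export
sample_severities <- function(n, lo = 0.3, hi = 0.8, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) stop("n must be >= 1")
  if (!(lo >= 0 && hi <= 1 && lo < hi)) {
    stop("severity bounds must satisfy 0 <= lo < hi <= 1")
  }
  lo + (hi - lo) * sobol_unit(n, seed = seed)
}
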