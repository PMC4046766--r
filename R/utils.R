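# Internal helpers shared across modules.

#' Round half away from zero to a fixed number of decimals
#'
#' Display rounding for percentage tables: 3.25 rounds to 3.3, unlike
#' [base::round()] which rounds to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Strand as a validated character vector of "+"/"-"
check_strand <- function(strand) {
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  strand
}

# 5'-most coordinate of an aligned interval, strand aware.
five_prime_of <- function(start, end, strand) {
  ifelse(strand == "+", start, end)
}

# Reverse complement of a plain character DNA string.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Extract a subsequence of `genome` (DNAString) as a character string in the
# orientation of `strand`; coordinates 1-based inclusive on the plus strand.
extract_oriented <- function(genome, start, end, strand) {
  s <- as.character(Biostrings::subseq(genome, start = start, end = end))
  if (strand == "-") s <- revcomp(s) else s
}

# Derive a stream-specific 32-bit seed from a base seed so that independent
# random stages do not share a stream.
derive_seed <- function(seed, offset) {
  # double arithmetic keeps the product exact (< 2^53) before the modulus
  as.integer((as.numeric(seed) %% 2147483647 * 7919 +
                as.numeric(offset) * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
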