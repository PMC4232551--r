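#' Reverse-complement a DNA string
#'
#' @param x character scalar over `A`, `C`, `G`, `T`, `N`.
#' @return character scalar, the reverse complement.
#' @examples
#' revcomp("GAATTC")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Random DNA sequence
#'
#' Draws `n` bases uniformly from `A`, `C`, `G`, `T` using the current RNG
#' stream.
#'
#' @param n number of bases.
#' @return character scalar of length `n`.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## integer vector <-> string helpers used throughout (utf8ToInt is the
## cheapest per-base representation available in base R)
.s2i <- function(x) utf8ToInt(x)
.i2s <- function(x) intToUtf8(x)

## substring by internal 0-based half-open coordinates
.sub0 <- function(x, start, end) substr(x, start + 1L, end)

`%||%` <- function(a, b) if (is.null(a)) b else a

## sample one element of a vector, safe for length-1 vectors (for which
## base sample() would draw from 1:x)
.sample1 <- function(v) if (length(v) == 1L) v else sample(v, 1L)
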