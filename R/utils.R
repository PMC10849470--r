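#' @importFrom stats median sd dnorm pnorm rnorm rpois p.adjust runif setNames optim
#' @importFrom utils adist write.table read.delim
#' @importFrom methods is
NULL

# Internal coordinate convention: 0-based, half-open [start, end).
# Conversion to 1-based inclusive happens only at GTF emission.

#' Reverse-complement a nucleotide string
#'
#' @param x character scalar (A/C/G/T).
#' @return character scalar.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Random nucleotide sequence
#'
#' @param n length in bases.
#' @param gc GC content in (0, 1).
#' @return character scalar of length-`n`.
#' @keywords internal
random_dna <- function(n, gc = 0.41) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# substring on 0-based half-open interval
substr0 <- function(x, start, end) substr(x, start + 1L, end)

# byte-wise mismatch positions (0-based) between equal-length strings
mismatch_pos0 <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  which(charToRaw(a) != charToRaw(b)) - 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
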