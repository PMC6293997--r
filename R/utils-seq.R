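#' Sequence utilities
#'
#' Small vectorised helpers for nucleotide strings used throughout the
#' package.  Sequences are plain upper-case character scalars/vectors over
#' `{A,C,G,T,N}`; circular coordinates are 1-based inclusive.
#'
#' @param x character vector of nucleotide sequences.
#' @return `revcomp()` the reverse complement; `at_fraction()` the fraction of
#'   A+T bases in `[0, 1]`.
#' @examples
#' revcomp("GAATTC")
#' at_fraction("ATAT")
#' @name seq-utils
NULL

#' @rdname seq-utils
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @rdname seq-utils
#' @export
at_fraction <- function(x) {
  f <- Biostrings::letterFrequency(Biostrings::DNAStringSet(x), c("A", "T"))
  unname(rowSums(f) / nchar(x))
}

#' AT percentage of a sequence segment at printed precision
#'
#' Computes `100 * (A + T) / length` rounded half-away-from-zero to `digits`
#' decimals, the convention used in published minicircle feature tables.
#'
#' @param x character vector of nucleotide sequences.
#' @param digits decimals to keep (default 1).
#' @return numeric vector of AT percentages.
#' @export
segment_at_percent <- function(x, digits = 1) {
  round_half_up(100 * at_fraction(x), digits)
}

# round half away from zero (R's round() is banker's rounding)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

random_dna <- function(n, at = 0.5) {
  if (n <= 0) return("")
  p <- c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE, prob = p),
        collapse = "")
}

# position on a circle of length L, mapped into 1..L
canonical_pos <- function(p, L) as.integer(((p - 1L) %% L) + 1L)

# forward arc length from `from` to `to` inclusive on a circle of length L
arc_len <- function(from, to, L) {
  as.integer(((to - from) %% L) + 1L)
}

# wrap-aware substring of a circular sequence (start/end 1-based inclusive;
# end < start walks through the origin)
subseq_circular <- function(seq, start, end) {
  L <- nchar(seq)
  start <- canonical_pos(start, L)
  end <- canonical_pos(end, L)
  if (start <= end) {
    substr(seq, start, end)
  } else {
    paste0(substr(seq, start, L), substr(seq, 1L, end))
  }
}

# independent deterministic sub-stream seeds derived from one global seed
substream_seed <- function(seed, stream) {
  (as.integer(seed) + 97561L * as.integer(stream)) %% 2147480009L
}

phred_to_int <- function(qual) utf8ToInt(qual) - 33L
int_to_phred <- function(q) intToUtf8(q + 33L)
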