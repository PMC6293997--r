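#' Sliding-window quality trimming of a single read
#'
#' Re-implements the published trimming rule: after removing 3' adapter
#' read-through, bases are cut inward from each end until the first window of
#' `trim_window` bases whose mean Phred quality is at least `trim_min_q`
#' (windows truncated at the read end use the mean of the remaining bases).
#' The retained interval is contiguous and sequence and qualities are cut
#' identically.  With `trim_both_ends = FALSE` only the 5' (leading) scan is
#' applied, the single-direction semantics of common trimmers.
#'
#' @param seq read sequence (character scalar).
#' @param qual Phred+33 quality string of the same length.
#' @param cfg a [pipeline_config()].
#' @param adapter optional adapter sequence to strip from the 3' end before
#'   quality trimming.
#' @return list with `seq` and `qual` (possibly empty strings).
#' @examples
#' r <- trim_read("ACGTACGT", "IIIII###", pipeline_config())
#' r$seq
#' @export
trim_read <- function(seq, qual, cfg = pipeline_config(), adapter = NULL) {
  stopifnot(nchar(seq) == nchar(qual))
  if (nchar(seq) == 0L) return(list(seq = "", qual = ""))
  if (!is.null(adapter) && nzchar(adapter)) {
    cut <- adapter_cut_at(seq, adapter)
    if (!is.na(cut)) {
      seq <- substr(seq, 1L, cut - 1L)
      qual <- substr(qual, 1L, cut - 1L)
      if (nchar(seq) == 0L) return(list(seq = "", qual = ""))
    }
  }
  q <- phred_to_int(qual)
  keep <- trim_interval(q, cfg$trim_window, cfg$trim_min_q,
                        cfg$trim_both_ends)
  if (keep[1] > keep[2]) return(list(seq = "", qual = ""))
  list(seq = substr(seq, keep[1], keep[2]),
       qual = substr(qual, keep[1], keep[2]))
}

# first position of the 3' adapter contamination, or NA; matches either a
# full internal adapter occurrence or a terminal suffix of >= 5 nt equal to
# an adapter prefix
adapter_cut_at <- function(seq, adapter) {
  hit <- find_occurrences(seq, adapter)
  if (length(hit)) return(hit[1])
  n <- nchar(seq)
  max_len <- min(nchar(adapter) - 1L, n)
  if (max_len < 5L) return(NA_integer_)
  for (len in seq(max_len, 5L)) {
    if (substr(seq, n - len + 1L, n) == substr(adapter, 1L, len)) {
      return(n - len + 1L)
    }
  }
  NA_integer_
}

trim_interval <- function(q, w, min_q, both_ends = TRUE) {
  n <- length(q)
  cs <- c(0, cumsum(q))
  ends <- pmin(seq_len(n) + w - 1L, n)
  lead_mean <- (cs[ends + 1L] - cs[seq_len(n)]) / (ends - seq_len(n) + 1L)
  from <- which(lead_mean >= min_q)
  if (length(from) == 0L) return(c(1L, 0L))
  start <- from[1]
  if (!both_ends) return(c(start, n))
  begins <- pmax(seq_len(n) - w + 1L, 1L)
  trail_mean <- (cs[seq_len(n) + 1L] - cs[begins]) / (seq_len(n) - begins + 1L)
  to <- which(trail_mean >= min_q)
  end <- to[length(to)]
  c(start, end)
}

#' Trim both mates of every read pair
#'
#' @param pairs read-pair tibble (`id`, `seq1`, `qual1`, `seq2`, `qual2`).
#' @param cfg a [pipeline_config()].
#' @param adapter adapter sequence stripped from 3' ends (default none).
#' @return the pairs tibble with trimmed sequences/qualities, in input order.
#' @export
trim_pairs <- function(pairs, cfg = pipeline_config(), adapter = NULL) {
  for (m in 1:2) {
    s <- paste0("seq", m); q <- paste0("qual", m)
    trimmed <- purrr::map2(pairs[[s]], pairs[[q]],
                           function(x, y) trim_read(x, y, cfg, adapter))
    pairs[[s]] <- vapply(trimmed, `[[`, character(1), "seq")
    pairs[[q]] <- vapply(trimmed, `[[`, character(1), "qual")
  }
  pairs
}

#' Discard pairs with a short mate
#'
#' A pair survives iff both mates are at least `min_mate_len` nt after
#' trimming.  Surviving pairs keep their input order; the counts report is
#' attached as attribute `"report"`.
#'
#' @param pairs trimmed read-pair tibble.
#' @param cfg a [pipeline_config()].
#' @return the surviving pairs, with `attr(, "report")` a one-row tibble of
#'   `n_in`, `n_out`, `fraction_surviving`.
#' @export
filter_pairs <- function(pairs, cfg = pipeline_config()) {
  keep <- nchar(pairs$seq1) >= cfg$min_mate_len &
    nchar(pairs$seq2) >= cfg$min_mate_len
  out <- pairs[keep, , drop = FALSE]
  attr(out, "report") <- tibble::tibble(
    n_in = nrow(pairs), n_out = nrow(out),
    fraction_surviving = ifelse(nrow(pairs) > 0, nrow(out) / nrow(pairs), NA)
  )
  out
}
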