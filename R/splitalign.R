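#' Build an exact k-mer seed index over a reference set
#'
#' Indexes every forward-strand k-mer of every reference.  For the circular
#' virus, k-mers spanning the position-1 boundary are indexed by virtually
#' extending the sequence, so wrap-crossing reads seed normally; reads are
#' mapped in both orientations against the forward index.
#'
#' @param refs reference tibble ([combine_refs()]).
#' @param cfg a [pipeline_config()] (uses `seed_k`).
#' @return a `seed_index` object.
#' @export
build_seed_index <- function(refs, cfg = pipeline_config()) {
  validate_refs(refs)
  k <- cfg$seed_k
  if (k > min(nchar(refs$seq))) {
    stop("seed_k longer than the shortest reference", call. = FALSE)
  }
  # circular references are virtually extended so both seeding and extension
  # can run through the origin; coordinates are canonicalised afterwards
  ext <- ifelse(refs$is_circular, pmin(nchar(refs$seq), 3000L), 0L)
  eval_seqs <- ifelse(ext > 0L,
                      paste0(refs$seq, substr(refs$seq, 1L, ext)),
                      refs$seq)
  tabs <- lapply(seq_len(nrow(refs)), function(i) {
    npos <- nchar(refs$seq[i]) - (if (refs$is_circular[i]) 0L else k - 1L)
    data.table::data.table(
      kmer = substring(eval_seqs[i], seq_len(npos), seq_len(npos) + k - 1L),
      ref_i = i, pos = seq_len(npos)
    )
  })
  kt <- data.table::rbindlist(tabs)
  data.table::setkey(kt, kmer)
  structure(
    list(kmers = kt, refs = refs, eval_seqs = eval_seqs, k = k,
         virus_i = which(refs$role == "virus"),
         virus_len = nchar(refs$seq[refs$role == "virus"])),
    class = "seed_index"
  )
}

#' Map a single read with the seed-and-extend split aligner
#'
#' Seeds at every read position, groups seed hits into candidate diagonals,
#' extends each to the best segment with identity at least `min_identity`
#' and read span at least `min_split_segment`, and reports either one
#' segment, or a split pair chosen to maximise total matched bases when no
#' single segment explains `read length - min_split_segment + 1` bases.
#' Ties break by reference id, then start coordinate.  Wrap alignments on
#' the circular virus are split at the origin into canonical intervals
#' (`wrap_join = TRUE` on the continuation row).
#'
#' @param index a [build_seed_index()] object.
#' @param read read sequence (character scalar).
#' @param cfg a [pipeline_config()].
#' @return tibble of aligned segments: `ref`, `start`, `end` (1-based
#'   inclusive, forward strand), `strand`, `read_start`, `read_end`,
#'   `identity`, `seg_id`, `order_index`, `wrap_join`; zero rows when
#'   unmappable.
#' @export
map_read <- function(index, read, cfg = pipeline_config()) {
  out <- map_mates(index, tibble::tibble(uid = "r", seq = read), cfg)
  out$uid <- NULL
  out
}

# batch mapper over a tibble(uid, seq); returns segment rows per uid
map_mates <- function(index, reads, cfg) {
  k <- index$k
  min_seg <- cfg$min_split_segment
  empty <- tibble::tibble(
    uid = character(), ref = character(), start = integer(), end = integer(),
    strand = character(), read_start = integer(), read_end = integer(),
    identity = numeric(), seg_id = integer(), order_index = integer(),
    wrap_join = logical()
  )
  reads <- reads[nchar(reads$seq) >= max(k, cfg$min_mate_len), , drop = FALSE]
  if (nrow(reads) == 0L) return(empty)

  oriented <- list("+" = reads$seq, "-" = revcomp(reads$seq))
  cand_list <- list()
  for (str in c("+", "-")) {
    seqs <- oriented[[str]]
    lens <- nchar(seqs)
    npos <- pmax(lens - k + 1L, 0L)
    dt <- data.table::data.table(
      ridx = rep(seq_along(seqs), npos),
      off = unlist(lapply(npos, seq_len), use.names = FALSE)
    )
    dt[, kmer := substring(seqs[ridx], off, off + k - 1L)]
    hits <- index$kmers[dt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(hits) == 0L) next
    hits[, diag := pos - off]
    cand <- hits[, .(nhits = .N), by = .(ridx, ref_i, diag)]
    cand[, strand := str]
    cand_list[[str]] <- cand
  }
  if (length(cand_list) == 0L) return(empty)
  cand <- data.table::rbindlist(cand_list)
  # deterministic candidate order; cap noise candidates per read+strand
  data.table::setorder(cand, ridx, strand, -nhits, ref_i, diag)
  cand <- cand[, head(.SD, 12L), by = .(ridx, strand)]

  cand_seqs <- ifelse(cand$strand == "+", oriented[["+"]][cand$ridx],
                      oriented[["-"]][cand$ridx])
  segm <- cpp_eval_candidates(cand_seqs, index$eval_seqs, cand$ref_i,
                              cand$diag, cfg$min_identity, min_seg)
  ok <- segm[, 1] > 0L
  if (!any(ok)) return(empty)
  segs <- data.table::data.table(
    ridx = cand$ridx[ok], strand = cand$strand[ok], ref_i = cand$ref_i[ok],
    diag = cand$diag[ok], os = segm[ok, 1], oe = segm[ok, 2],
    matches = segm[ok, 3]
  )
  # drop duplicate placements found from both seed clusters of one diagonal
  segs <- unique(segs, by = c("ridx", "strand", "ref_i", "diag", "os", "oe"))
  refs_id <- index$refs$id
  ref_rank <- rank(refs_id)
  segs[, rank := ref_rank[ref_i]]
  segs[, n := .N, by = ridx]

  # fast path: unique placement entirely inside canonical coordinates
  vlen <- index$virus_len
  circ <- index$refs$is_circular[segs$ref_i]
  plain <- segs$n == 1L & !(circ & (segs$diag + segs$oe > vlen))
  fast <- segs[plain]
  out_fast <- NULL
  if (nrow(fast)) {
    rlen_f <- nchar(reads$seq[fast$ridx])
    out_fast <- tibble::tibble(
      uid = reads$uid[fast$ridx],
      ref = refs_id[fast$ref_i],
      start = fast$diag + fast$os, end = fast$diag + fast$oe,
      strand = fast$strand,
      read_start = ifelse(fast$strand == "+", fast$os,
                          rlen_f - fast$oe + 1L),
      read_end = ifelse(fast$strand == "+", fast$oe, rlen_f - fast$os + 1L),
      identity = fast$matches / (fast$oe - fast$os + 1L),
      seg_id = 1L, order_index = 1L, wrap_join = FALSE
    )
  }

  out_slow <- NULL
  slow <- segs[!plain]
  if (nrow(slow)) {
    groups <- split(slow, by = "ridx")
    rows <- vector("list", length(groups))
    n_out <- 0L
    for (g in groups) {
      ri <- g$ridx[1]
      rlen <- nchar(reads$seq[ri])
      chosen <- choose_segments(g, rlen, min_seg)
      if (is.null(chosen)) next
      n_out <- n_out + 1L
      rows[[n_out]] <- finalize_segments(chosen, reads$uid[ri], rlen,
                                         oriented, ri, index, refs_id)
    }
    if (n_out) out_slow <- dplyr::bind_rows(rows[seq_len(n_out)])
  }
  out <- dplyr::bind_rows(out_fast, out_slow)
  if (is.null(out) || nrow(out) == 0L) return(empty)
  tibble::as_tibble(out)
}

# pick the best single segment, or the best split pair when no single
# segment explains rlen - min_seg + 1 bases.  Segments may come from either
# read orientation, so pairing and trimming happen in original read
# coordinates (rs, re); oriented coordinates are adjusted alongside.
choose_segments <- function(s, rlen, min_seg) {
  s$rs <- ifelse(s$strand == "+", s$os, rlen - s$oe + 1L)
  s$re <- ifelse(s$strand == "+", s$oe, rlen - s$os + 1L)
  s <- s[order(s$rank, s$diag, s$strand, s$rs), ]
  span <- s$re - s$rs + 1L
  best1 <- order(-s$matches, s$rank, s$diag + s$os, s$strand)[1]
  if (span[best1] >= rlen - min_seg + 1L || nrow(s) == 1L) {
    return(s[best1, ])
  }
  # trim `x` read bases from the breakpoint-proximal end of a segment row
  trim_right <- function(seg, x) {    # read-interval right end
    seg$re <- seg$re - x
    if (seg$strand == "+") seg$oe <- seg$oe - x else seg$os <- seg$os + x
    seg
  }
  trim_left <- function(seg, x) {     # read-interval left end
    seg$rs <- seg$rs + x
    if (seg$strand == "+") seg$os <- seg$os + x else seg$oe <- seg$oe - x
    seg
  }
  best_pair <- NULL
  best_score <- -1L
  for (i in seq_len(nrow(s) - 1L)) {
    for (j in seq(i + 1L, nrow(s))) {
      a <- s[i, ]; b <- s[j, ]
      if (a$rs > b$rs) { tmp <- a; a <- b; b <- tmp }
      ov <- max(0L, a$re - b$rs + 1L)
      if (ov > 10L) next
      # trim the shared (microhomology) span at its midpoint
      cut_a <- ov %/% 2L
      cut_b <- ov - cut_a
      if ((a$re - cut_a) - a$rs + 1L < min_seg) next
      if (b$re - (b$rs + cut_b) + 1L < min_seg) next
      score <- a$matches + b$matches - ov
      if (score > best_score) {
        best_score <- score
        best_pair <- rbind(trim_right(a, cut_a), trim_left(b, cut_b))
      }
    }
  }
  if (is.null(best_pair) || best_score <= s$matches[best1]) {
    return(s[best1, ])
  }
  best_pair
}

# canonicalise chosen segments: wrap split on circular refs, conversion to
# original read coordinates, per-row identity recomputation
finalize_segments <- function(chosen, uid, rlen, oriented, ri, index,
                              refs_id) {
  vlen <- index$virus_len
  out <- list()
  seg_id <- 0L
  for (r in seq_len(nrow(chosen))) {
    cs <- chosen[r, ]
    seg_id <- seg_id + 1L
    circular <- index$refs$is_circular[cs$ref_i]
    pieces <- list(c(cs$os, cs$oe))
    if (circular) {
      rs <- cs$diag + cs$os
      re <- cs$diag + cs$oe
      if (rs > vlen) {
        cs$diag <- cs$diag - vlen
      } else if (re > vlen) {
        ob <- vlen - cs$diag
        pieces <- list(c(cs$os, ob), c(ob + 1L, cs$oe))
      }
    }
    for (p in seq_along(pieces)) {
      os <- pieces[[p]][1]; oe <- pieces[[p]][2]
      d <- cs$diag - (if (p == 2L) vlen else 0L)
      oseq <- oriented[[cs$strand]][ri]
      m <- seg_matches(oseq, index$eval_seqs[cs$ref_i],
                       d + if (p == 2L) vlen else 0L, os, oe)
      if (cs$strand == "+") {
        rs <- os; re <- oe
      } else {
        rs <- rlen - oe + 1L; re <- rlen - os + 1L
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        uid = uid, ref = refs_id[cs$ref_i],
        start = d + os, end = d + oe, strand = cs$strand,
        read_start = rs, read_end = re,
        identity = m / (oe - os + 1L),
        seg_id = seg_id, wrap_join = p == 2L
      )
    }
  }
  res <- dplyr::bind_rows(out)
  res <- res[order(res$read_start), , drop = FALSE]
  res$order_index <- seq_len(nrow(res))
  res
}

seg_matches <- function(oriented_seq, eval_seq, diag, os, oe) {
  sum(utf8ToInt(substr(oriented_seq, os, oe)) ==
        utf8ToInt(substr(eval_seq, diag + os, diag + oe)))
}

#' Map all read pairs and build the alignment store
#'
#' Both mates are mapped independently; mate linkage is preserved so
#' junction-window read recovery can always pull the partner.  The store
#' supports interval queries ([store_overlapping_reads()]) and split-read
#' queries ([store_split_reads()]), and round-trips losslessly through TSV
#' ([write_store_tsv()]).
#'
#' @param index a [build_seed_index()] object.
#' @param pairs trimmed, filtered read-pair tibble.
#' @param cfg a [pipeline_config()].
#' @return an `alignment_store` list: `$segments` (one row per aligned
#'   segment, `read_id` + `mate` identify the mate), `$pairs`, `$refs`.
#' @export
map_pairs <- function(index, pairs, cfg = pipeline_config()) {
  mates <- dplyr::bind_rows(
    tibble::tibble(uid = paste0(pairs$id, "/1"), seq = pairs$seq1),
    tibble::tibble(uid = paste0(pairs$id, "/2"), seq = pairs$seq2)
  )
  segs <- map_mates(index, mates, cfg)
  if (nrow(segs)) {
    segs$read_id <- sub("/[12]$", "", segs$uid)
    segs$mate <- as.integer(sub("^.*/", "", segs$uid))
    segs$uid <- NULL
    segs <- segs[order(segs$read_id, segs$mate, segs$order_index), ]
    segs <- dplyr::select(segs, "read_id", "mate", "ref", "start", "end",
                          "strand", "read_start", "read_end", "identity",
                          "seg_id", "order_index", "wrap_join")
  } else {
    segs <- tibble::tibble(
      read_id = character(), mate = integer(), ref = character(),
      start = integer(), end = integer(), strand = character(),
      read_start = integer(), read_end = integer(), identity = numeric(),
      seg_id = integer(), order_index = integer(), wrap_join = logical()
    )
  }
  structure(list(segments = tibble::as_tibble(segs), pairs = pairs,
                 refs = index$refs),
            class = "alignment_store")
}

#' @rdname map_pairs
#' @param store an `alignment_store`.
#' @param ref,start,end query interval (1-based inclusive).
#' @return `store_overlapping_reads()`: read ids with any segment
#'   overlapping the interval; `store_split_reads()`: mate keys
#'   (`read_id`, `mate`) with two or more alignment segments.
#' @export
store_overlapping_reads <- function(store, ref, start, end) {
  s <- store$segments
  hit <- s$ref == ref & s$start <= end & s$end >= start
  unique(s$read_id[hit])
}

#' @rdname map_pairs
#' @export
store_split_reads <- function(store) {
  s <- store$segments
  dplyr::filter(
    dplyr::summarise(dplyr::group_by(s, .data$read_id, .data$mate),
                     n_seg = max(.data$seg_id), .groups = "drop"),
    .data$n_seg >= 2L
  )
}
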