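#' Recover reads around selected junctions, with their mates
#'
#' A read is recovered iff any of its aligned segments overlaps the recovery
#' locus around either side of any selected junction (a `recovery_window`-nt
#' window centred on the side, or `recovery_window` on each side under the
#' `"each_side"` toggle); windows are truncated at linear reference ends and
#' wrap-aware on the circular virus.  The mate of a recovered read is always
#' included, aligned or not.  With `sides = "host"` only host-side windows
#' are used — the mode the pipeline uses for per-locus targeted assembly,
#' since every replicon shares the near-origin viral arc.
#'
#' @param store an `alignment_store` from [map_pairs()].
#' @param junctions filtered junction tibble.
#' @param cfg a [pipeline_config()].
#' @param sides `"both"` (default, the published semantics) or `"host"`.
#' @return the recovered read pairs (a subset of `store$pairs`, input order,
#'   deduplicated by read id).
#' @export
recover_reads <- function(store, junctions, cfg = pipeline_config(),
                          sides = c("both", "host")) {
  sides <- match.arg(sides)
  if (nrow(junctions) == 0L) return(store$pairs[0, , drop = FALSE])
  role <- setNames(store$refs$role, store$refs$id)
  lens <- setNames(nchar(store$refs$seq), store$refs$id)
  circ <- setNames(store$refs$is_circular, store$refs$id)
  half <- if (cfg$recovery_mode == "centered") cfg$recovery_window %/% 2L
  else cfg$recovery_window

  wins <- list()
  add_window <- function(ref, pos) {
    if (sides == "host" && role[[ref]] != "host") return()
    L <- lens[[ref]]
    lo <- pos - half
    hi <- pos + half
    if (circ[[ref]] && (lo < 1L || hi > L)) {
      if (hi - lo + 1L >= L) {
        wins[[length(wins) + 1L]] <<- c(ref, 1L, L)
      } else {
        wins[[length(wins) + 1L]] <<- c(ref, canonical_pos(lo, L), L)
        wins[[length(wins) + 1L]] <<- c(ref, 1L, canonical_pos(hi, L))
      }
    } else {
      wins[[length(wins) + 1L]] <<- c(ref, max(1L, lo), min(L, hi))
    }
  }
  for (i in seq_len(nrow(junctions))) {
    add_window(junctions$ref_a[i], junctions$pos_a[i])
    add_window(junctions$ref_b[i], junctions$pos_b[i])
  }
  if (length(wins) == 0L) return(store$pairs[0, , drop = FALSE])
  hit_ids <- unique(unlist(lapply(wins, function(w) {
    store_overlapping_reads(store, w[1], as.integer(w[2]), as.integer(w[3]))
  })))
  store$pairs[store$pairs$id %in% hit_ids, , drop = FALSE]
}

#' Greedy overlap-layout-consensus assembly of a small read set
#'
#' Desk-scale assembler for targeted junction loci: exact k-mer seeded
#' suffix/prefix overlaps of at least `min_overlap` nt with at most one
#' mismatch per `max_overlap_mm_per` overlap bases, greedy extension
#' merging the longest overlap first (ties to the lexicographically smallest
#' read id), per-column majority consensus over the final layout, and a
#' `min_scaffold_len * read length` floor on reported scaffolds.  Both read
#' orientations are considered; the model is substitution-only (no indels),
#' matching short-read data at these scales.  Deterministic for a fixed
#' input.
#'
#' @param reads read-pair tibble (both mates are assembled) or a tibble with
#'   columns `id` and `seq` of single sequences.
#' @param cfg a [pipeline_config()].
#' @return scaffold tibble: `id`, `seq`, `n_reads`, `mean_depth`.
#' @export
assemble_reads <- function(reads, cfg = pipeline_config()) {
  if (all(c("seq1", "seq2") %in% names(reads))) {
    seqs <- c(setNames(reads$seq1, paste0(reads$id, "/1")),
              setNames(reads$seq2, paste0(reads$id, "/2")))
  } else {
    seqs <- setNames(reads$seq, reads$id)
  }
  seqs <- seqs[nchar(seqs) >= cfg$min_overlap]
  empty <- tibble::tibble(id = character(), seq = character(),
                          n_reads = integer(), mean_depth = numeric())
  if (length(seqs) == 0L) return(empty)
  seqs <- seqs[order(names(seqs))]
  rcs <- setNames(revcomp(seqs), names(seqs))
  rl_max <- max(nchar(seqs))

  k <- min(cfg$seed_k, cfg$min_overlap %/% 2L + 1L)
  kt <- read_kmer_table(seqs, k)
  used <- setNames(rep(FALSE, length(seqs)), names(seqs))
  scaffolds <- list()

  for (seed_id in names(seqs)) {
    if (used[[seed_id]]) next
    used[[seed_id]] <- TRUE
    contig <- assemble_from_seed(seed_id, seqs, rcs, kt, used, cfg, k)
    used <- contig$used
    if (nchar(contig$seq) >= cfg$min_scaffold_len * rl_max &&
          nrow(contig$layout) > 1L) {
      scaffolds[[length(scaffolds) + 1L]] <- contig
    }
  }
  if (length(scaffolds) == 0L) return(empty)

  # consensus by per-column majority over the layout
  cons <- vapply(scaffolds, function(sc) {
    layout_consensus(sc$layout, seqs, rcs, nchar(sc$seq))
  }, character(1))
  n_reads <- vapply(scaffolds, function(sc) nrow(sc$layout), integer(1))
  depth <- vapply(seq_along(scaffolds), function(i) {
    sum(nchar(seqs[scaffolds[[i]]$layout$uid])) / nchar(cons[i])
  }, numeric(1))
  ord <- order(-nchar(cons), cons)
  out <- tibble::tibble(
    id = sprintf("scf%02d", seq_along(ord)),
    seq = cons[ord],
    n_reads = n_reads[ord],
    mean_depth = depth[ord]
  )
  # drop scaffolds fully contained in a longer one (either orientation)
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (i == 1L) next
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      if (grepl(out$seq[i], out$seq[j], fixed = TRUE) ||
            grepl(revcomp(out$seq[i]), out$seq[j], fixed = TRUE)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  out$id <- sprintf("scf%02d", seq_len(nrow(out)))
  out
}

read_kmer_table <- function(seqs, k) {
  tabs <- lapply(c("+", "-"), function(o) {
    s <- if (o == "+") seqs else revcomp(seqs)
    npos <- pmax(nchar(s) - k + 1L, 0L)
    data.table::data.table(
      uid = rep(names(seqs), npos),
      orient = o,
      pos = unlist(lapply(npos, seq_len), use.names = FALSE),
      kmer = unlist(purrr::map2(s, npos, function(x, np) {
        substring(x, seq_len(np), seq_len(np) + k - 1L)
      }), use.names = FALSE)
    )
  })
  kt <- data.table::rbindlist(tabs)
  data.table::setkey(kt, kmer)
  kt
}

# grow one contig from a seed read by repeated best-overlap extension on the
# right end, in both contig orientations
assemble_from_seed <- function(seed_id, seqs, rcs, kt, used, cfg, k) {
  layout <- tibble::tibble(uid = seed_id, orient = "+",
                           off = 1L)
  cseq <- seqs[[seed_id]]
  for (pass in 1:2) {
    repeat {
      step <- extend_right(cseq, seqs, rcs, kt, used, cfg, k)
      if (is.null(step)) break
      used[step$absorbed] <- TRUE
      layout <- dplyr::bind_rows(layout, tibble::tibble(
        uid = step$absorbed, orient = step$orient, off = step$off
      ))
      cseq <- step$seq
    }
    # flip to extend the other end
    L <- nchar(cseq)
    cseq <- revcomp(cseq)
    layout$off <- L - (layout$off + nchar(seqs[layout$uid]) - 1L) + 1L
    layout$orient <- ifelse(layout$orient == "+", "-", "+")
  }
  list(seq = cseq, layout = layout, used = used)
}

# one extension step: find unused reads overlapping the contig's right end,
# absorb contained ones, and extend with the longest-overlap dovetail
extend_right <- function(cseq, seqs, rcs, kt, used, cfg, k) {
  L <- nchar(cseq)
  tail_len <- min(L, max(nchar(seqs)) + 10L)
  tail_seq <- substr(cseq, L - tail_len + 1L, L)
  np <- nchar(tail_seq) - k + 1L
  if (np < 1L) return(NULL)
  q <- data.table::data.table(
    kmer = substring(tail_seq, seq_len(np), seq_len(np) + k - 1L),
    qpos = seq_len(np)
  )
  hits <- kt[q, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L) return(NULL)
  hits <- hits[!used[hits$uid], ]
  if (nrow(hits) == 0L) return(NULL)
  # read start offset in contig coordinates
  hits[, off := (L - tail_len) + qpos - pos + 1L]
  cand <- unique(hits[, .(uid, orient, off)])
  cand <- cand[cand$off > 1L & cand$off <= L, ]
  if (nrow(cand) == 0L) return(NULL)

  best <- NULL
  data.table::setorder(cand, off, uid, orient)
  c_uid <- cand$uid
  c_orient <- cand$orient
  c_off <- cand$off
  seen <- character(0)
  cont_uid <- character(0)
  cont_orient <- character(0)
  cont_off <- integer(0)
  for (i in seq_along(c_uid)) {
    uid <- c_uid[i]; orient <- c_orient[i]; off <- c_off[i]
    if (uid %in% seen) next
    rseq <- if (orient == "+") seqs[[uid]] else rcs[[uid]]
    rlen <- nchar(rseq)
    ov <- min(L - off + 1L, rlen)
    if (ov < cfg$min_overlap) next
    mm <- cpp_hamming(substr(cseq, off, off + ov - 1L), substr(rseq, 1L, ov))
    if (mm > ov %/% cfg$max_overlap_mm_per) next
    seen <- c(seen, uid)
    if (off + rlen - 1L <= L) {
      # record the verified placement, not any other row of the same read
      cont_uid <- c(cont_uid, uid)
      cont_orient <- c(cont_orient, orient)
      cont_off <- c(cont_off, off)
    } else if (is.null(best) || ov > best$ov ||
                 (ov == best$ov && uid < best$uid)) {
      best <- list(uid = uid, orient = orient, off = off, ov = ov,
                   rseq = rseq, rlen = rlen)
    }
  }
  if (is.null(best) && length(cont_uid) == 0L) return(NULL)
  if (is.null(best)) {
    # only contained reads: absorb them without extending
    return(list(absorbed = cont_uid, orient = cont_orient, off = cont_off,
                seq = cseq))
  }
  list(
    absorbed = c(cont_uid, best$uid),
    orient = c(cont_orient, best$orient),
    off = c(cont_off, best$off),
    seq = paste0(cseq, substr(best$rseq, best$ov + 1L, best$rlen))
  )
}

layout_consensus <- function(layout, seqs, rcs, total_len) {
  base_row <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  li <- lapply(seq_len(nrow(layout)), function(i) {
    s <- if (layout$orient[i] == "+") seqs[[layout$uid[i]]] else
      rcs[[layout$uid[i]]]
    b <- strsplit(s, "")[[1]]
    pos <- layout$off[i] + seq_along(b) - 1L
    ok <- pos >= 1L & pos <= total_len & b %in% names(base_row)
    (pos[ok] - 1L) * 4L + base_row[b[ok]]
  })
  counts <- matrix(tabulate(unlist(li, use.names = FALSE),
                            nbins = 4L * total_len), nrow = 4L)
  filled <- colSums(counts) > 0L
  cons <- rep("N", total_len)
  cons[filled] <- c("A", "C", "G", "T")[apply(counts[, filled, drop = FALSE],
                                              2L, which.max)]
  paste(cons, collapse = "")
}
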