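#' Tile a scaffold with local alignments to the references
#'
#' Aligns the scaffold against every reference with the same seed-and-extend
#' machinery as read mapping, then selects a maximal-scoring chain of
#' non-overlapping blocks (block score = matched bases; overlaps beyond the
#' microhomology tolerance are forbidden, smaller overlaps are trimmed at
#' their midpoint on both the scaffold and the reference interval).  Blocks
#' crossing the virus origin are split into canonical intervals.
#'
#' @param scaffold one-row scaffold tibble (`id`, `seq`) or a list with
#'   `id`/`seq`.
#' @param refs reference tibble.
#' @param cfg a [pipeline_config()].
#' @param index optional pre-built [build_seed_index()] over `refs`.
#' @param min_block minimum block length (nt) retained in the tiling.
#' @return a `scaffold_annotation` list: `$scaffold_id`, `$seq`, `$blocks`
#'   (tibble `s_start`, `s_end`, `ref`, `r_start`, `r_end`, `strand`,
#'   `identity`, `wrap_join`), `$n_junctions` (virus/host transitions) and
#'   `$class` (see [classify_scaffold()]).
#' @export
segment_scaffold <- function(scaffold, refs, cfg = pipeline_config(),
                             index = NULL, min_block = 20L) {
  if (is.null(index)) index <- build_seed_index(refs, cfg)
  seq <- scaffold$seq[[1]]
  id <- scaffold$id[[1]]
  blocks <- scaffold_blocks(seq, index, cfg, min_block)
  ann <- structure(list(scaffold_id = id, seq = seq, blocks = blocks,
                        n_junctions = count_junction_transitions(blocks, refs),
                        class = NA_character_),
                   class = "scaffold_annotation")
  ann$class <- classify_scaffold(ann, refs)
  ann
}

scaffold_blocks <- function(seq, index, cfg, min_block) {
  empty <- tibble::tibble(
    s_start = integer(), s_end = integer(), ref = character(),
    r_start = integer(), r_end = integer(), strand = character(),
    identity = numeric(), wrap_join = logical()
  )
  k <- index$k
  n <- nchar(seq)
  if (n < k) return(empty)
  oriented <- c("+" = seq, "-" = revcomp(seq))
  cand_all <- list()
  for (str in c("+", "-")) {
    s <- oriented[[str]]
    np <- nchar(s) - k + 1L
    dt <- data.table::data.table(
      off = seq_len(np),
      kmer = substring(s, seq_len(np), seq_len(np) + k - 1L)
    )
    hits <- index$kmers[dt, on = "kmer", nomatch = NULL,
                        allow.cartesian = TRUE]
    if (nrow(hits) == 0L) next
    hits[, diag := pos - off]
    cand <- hits[, .(nhits = .N), by = .(ref_i, diag)]
    cand <- cand[cand$nhits >= 3L, ]
    cand[, strand := str]
    cand_all[[str]] <- cand
  }
  if (length(cand_all) == 0L) return(empty)
  cand <- data.table::rbindlist(cand_all)
  data.table::setorder(cand, -nhits, ref_i, diag, strand)
  cand <- head(cand, 40L)

  segm <- cpp_eval_candidates(oriented[cand$strand], index$eval_seqs,
                              cand$ref_i, cand$diag, cfg$min_identity,
                              min_block)
  ok <- segm[, 1] > 0L
  if (!any(ok)) return(empty)
  segs <- tibble::tibble(
    ref_i = cand$ref_i[ok], diag = cand$diag[ok], strand = cand$strand[ok],
    os = segm[ok, 1], oe = segm[ok, 2], matches = segm[ok, 3]
  )
  # scaffold-frame coordinates
  segs$s_start <- ifelse(segs$strand == "+", segs$os, n - segs$oe + 1L)
  segs$s_end <- ifelse(segs$strand == "+", segs$oe, n - segs$os + 1L)
  segs <- dplyr::distinct(segs, .data$ref_i, .data$diag, .data$strand,
                          .data$os, .data$oe, .keep_all = TRUE)

  chain <- chain_blocks(segs, tol = 2L * cfg$junction_cluster_tol)
  if (nrow(chain) == 0L) return(empty)
  chain <- trim_chain_overlaps(chain)
  blocks_from_chain(chain, n, oriented, index, min_block)
}

# maximal-scoring chain of blocks, non-overlapping in scaffold coordinates
# beyond `tol` (microhomology); O(n^2) DP, deterministic
chain_blocks <- function(segs, tol) {
  segs <- segs[order(segs$s_start, segs$s_end, segs$ref_i, segs$diag), ,
               drop = FALSE]
  m <- nrow(segs)
  score <- segs$matches
  best <- score
  prev <- rep(0L, m)
  for (i in seq_len(m)) {
    if (i == 1L) next
    for (j in seq_len(i - 1L)) {
      ov <- segs$s_end[j] - segs$s_start[i] + 1L
      if (ov > tol) next
      cand <- best[j] + score[i] - max(0L, ov)
      if (cand > best[i]) {
        best[i] <- cand
        prev[i] <- j
      }
    }
  }
  i <- which.max(best)
  idx <- integer(0)
  while (i > 0L) {
    idx <- c(i, idx)
    i <- prev[i]
  }
  segs[idx, , drop = FALSE]
}

# trim residual scaffold overlaps between consecutive chained blocks at the
# midpoint, adjusting reference intervals consistently
trim_chain_overlaps <- function(chain) {
  if (nrow(chain) < 2L) return(chain)
  for (i in seq_len(nrow(chain) - 1L)) {
    ov <- chain$s_end[i] - chain$s_start[i + 1L] + 1L
    if (ov <= 0L) next
    cut_a <- ov %/% 2L
    cut_b <- ov - cut_a
    chain$s_end[i] <- chain$s_end[i] - cut_a
    chain$s_start[i + 1L] <- chain$s_start[i + 1L] + cut_b
  }
  chain
}

# convert chained (trimmed) candidate segments into canonical reference
# blocks: recompute oriented/reference intervals from the trimmed scaffold
# interval, recompute identity, and split virus blocks at the origin
blocks_from_chain <- function(chain, n, oriented, index, min_block) {
  vlen <- index$virus_len
  refs_id <- index$refs$id
  rows <- list()
  for (i in seq_len(nrow(chain))) {
    b <- chain[i, ]
    if (b$s_end - b$s_start + 1L < min_block) next
    circular <- index$refs$is_circular[b$ref_i]
    # oriented coordinates of the trimmed scaffold interval
    if (b$strand == "+") {
      os <- b$s_start; oe <- b$s_end
    } else {
      os <- n - b$s_end + 1L; oe <- n - b$s_start + 1L
    }
    # split at the origin when the block runs through it
    pieces <- list(c(os, oe))
    d <- b$diag
    if (circular) {
      if (d + os > vlen) {
        d <- d - vlen
      } else if (d + oe > vlen) {
        ob <- vlen - d
        pieces <- list(c(os, ob), c(ob + 1L, oe))
      }
    }
    for (p in seq_along(pieces)) {
      po <- pieces[[p]]
      dd <- if (p == 2L) d - vlen else d
      m <- seg_matches(oriented[[b$strand]], index$eval_seqs[b$ref_i],
                       b$diag, po[1], po[2])
      if (b$strand == "+") {
        ss <- po[1]; se <- po[2]
      } else {
        ss <- n - po[2] + 1L; se <- n - po[1] + 1L
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        s_start = ss, s_end = se, ref = refs_id[b$ref_i],
        r_start = dd + po[1], r_end = dd + po[2], strand = b$strand,
        identity = m / (po[2] - po[1] + 1L),
        wrap_join = circular && dd + po[1] == 1L && p == 2L
      )
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(
      s_start = integer(), s_end = integer(), ref = character(),
      r_start = integer(), r_end = integer(), strand = character(),
      identity = numeric(), wrap_join = logical()
    ))
  }
  out <- dplyr::bind_rows(rows)
  out[order(out$s_start), , drop = FALSE]
}

count_junction_transitions <- function(blocks, refs) {
  if (nrow(blocks) < 2L) return(0L)
  role <- setNames(refs$role, refs$id)
  r <- role[blocks$ref]
  sum(r[-1] != r[-length(r)])
}

#' Classify a scaffold annotation
#'
#' `hybrid` when the block tiling contains both virus and host blocks;
#' `defective` when all blocks are viral and their total reference span is
#' shorter than the full genome; `host_only` when all blocks are host;
#' `unclassified` otherwise (no blocks, or full-genome virus).
#'
#' @param ann a `scaffold_annotation`.
#' @param refs reference tibble.
#' @return a classification string.
#' @export
classify_scaffold <- function(ann, refs) {
  b <- ann$blocks
  if (nrow(b) == 0L) return("unclassified")
  role <- setNames(refs$role, refs$id)
  r <- role[b$ref]
  vlen <- nchar(refs$seq[refs$role == "virus"])
  if (any(r == "virus") && any(r == "host")) return("hybrid")
  if (all(r == "virus")) {
    span <- sum(b$r_end - b$r_start + 1L)
    if (span < vlen) return("defective") else return("unclassified")
  }
  if (all(r == "host")) return("host_only")
  "unclassified"
}

# canonical molecule orientation: flip the annotation so virus blocks are on
# the forward strand (majority by length)
canonical_orientation <- function(ann, refs) {
  b <- ann$blocks
  role <- setNames(refs$role, refs$id)
  v <- b[role[b$ref] == "virus", , drop = FALSE]
  if (nrow(v) == 0L) return(ann)
  wt <- tapply(v$s_end - v$s_start + 1L, v$strand, sum)
  major <- names(wt)[which.max(wt)]
  if (major == "+") return(ann)
  n <- nchar(ann$seq)
  ann$seq <- revcomp(ann$seq)
  b2 <- b
  b2$s_start <- n - b$s_end + 1L
  b2$s_end <- n - b$s_start + 1L
  b2$strand <- ifelse(b$strand == "+", "-", "+")
  b2 <- b2[order(b2$s_start), , drop = FALSE]
  ann$blocks <- b2
  ann
}

#' Reconstruct the circular molecule behind a hybrid or defective scaffold
#'
#' Two closure routes, tried in order.  (1) End overlap: when the scaffold's
#' ends overlap by at least `min_overlap` nt (one mismatch per
#' `max_overlap_mm_per` allowed) the scaffold traversed the whole circle and
#' the overlap is collapsed once.  (2) Two terminal virus/host junctions:
#' the circle is the annotated host block plus the viral arc running between
#' the two virus-side junction coordinates through the origin, both taken
#' from the references — the coordinate-string reconstruction used for
#' published minicircle tables.  The returned circle is rotated so the base
#' aligning to virus position 1 comes first; candidates that do not cover
#' virus position 1 are anchored at the lowest covered virus coordinate and
#' flagged.  A candidate with no closure evidence raises a "linear
#' candidate" error.
#'
#' @param ann a `scaffold_annotation` (or merged candidate annotation).
#' @param refs reference tibble.
#' @param cfg a [pipeline_config()].
#' @param index optional shared [build_seed_index()].
#' @return a `minicircle_candidate` list: `$seq`, `$length`, `$arc_start`,
#'   `$arc_end`, `$viral_len`, `$host_ref`, `$host_start`, `$host_end`,
#'   `$host_strand`, `$host_len`, `$host_span` (host positions inside the
#'   rotated circle), `$class`, `$route`, `$anchored_at_origin`,
#'   `$scaffold_ids`.
#' @export
circularize_candidate <- function(ann, refs, cfg = pipeline_config(),
                                  index = NULL) {
  ann <- canonical_orientation(ann, refs)
  n <- nchar(ann$seq)
  if (!is.na(n) && n > 0L) {
    w <- min(600L, n - 1L)
    ov <- cpp_best_overlap(substr(ann$seq, n - w + 1L, n),
                           substr(ann$seq, 1L, w),
                           cfg$min_overlap, cfg$max_overlap_mm_per)
    if (ov[1] > 0L && ov[1] < n) {
      circ <- substr(ann$seq, 1L, n - ov[1])
      cand <- annotate_circle_seq(circ, refs, cfg, index,
                                  scaffold_ids = ann$scaffold_id)
      cand$route <- "end_overlap"
      return(cand)
    }
  }
  two_junction_circle(ann, refs, cfg)
}

# route 2: reference-coordinate reconstruction from a virus-host-virus block
# pattern with two terminal junctions
two_junction_circle <- function(ann, refs, cfg) {
  role <- setNames(refs$role, refs$id)
  b <- ann$blocks
  if (ann$n_junctions != 2L || ann$class != "hybrid") {
    stop("linear candidate: no closure evidence", call. = FALSE)
  }
  r <- role[b$ref]
  hosti <- which(r == "host")
  viri <- which(r == "virus")
  if (length(hosti) == 0L || min(hosti) == 1L || max(hosti) == nrow(b)) {
    stop("linear candidate: host block not flanked by virus blocks",
         call. = FALSE)
  }
  vseq <- refs$seq[refs$role == "virus"]
  L <- nchar(vseq)
  a <- b$r_end[max(viri[viri < min(hosti)])]
  bb <- b$r_start[min(viri[viri > max(hosti)])]
  hs <- min(b$r_start[hosti])
  he <- max(b$r_end[hosti])
  host_ref <- b$ref[hosti[1]]
  host_strand <- b$strand[hosti[1]]
  build_reference_circle(refs, a, bb, host_ref, hs, he, host_strand, cfg,
                         scaffold_ids = ann$scaffold_id, route = "junctions")
}

build_reference_circle <- function(refs, a, b, host_ref, hs, he,
                                   host_strand, cfg,
                                   scaffold_ids, route) {
  vseq <- refs$seq[refs$role == "virus"]
  L <- nchar(vseq)
  hseq_full <- refs$seq[match(host_ref, refs$id)]
  host_mol <- substr(hseq_full, hs, he)
  if (host_strand == "-") host_mol <- revcomp(host_mol)
  vlen <- arc_len(b, a, L)
  anchored <- !arc_contains(b, a, 1L, 1L, L)
  if (!anchored) {
    seq <- paste0(substr(vseq, 1L, a), host_mol, substr(vseq, b, L))
    host_span <- c(a + 1L, a + nchar(host_mol))
  } else {
    seq <- paste0(subseq_circular(vseq, b, a), host_mol)
    host_span <- c(vlen + 1L, vlen + nchar(host_mol))
  }
  structure(list(
    seq = seq, length = nchar(seq), arc_start = b, arc_end = a,
    viral_len = vlen, host_ref = host_ref, host_start = hs, host_end = he,
    host_strand = host_strand, host_len = he - hs + 1L,
    host_span = host_span, class = "hybrid", route = route,
    anchored_at_origin = !anchored, scaffold_ids = scaffold_ids
  ), class = "minicircle_candidate")
}

# annotate an already-closed circle sequence (end-overlap route): blocks are
# recomputed on the circle, then the canonical rotation is applied
annotate_circle_seq <- function(circ, refs, cfg, index = NULL,
                                scaffold_ids = character()) {
  ann <- segment_scaffold(list(id = "circle", seq = circ), refs, cfg, index)
  ann <- canonical_orientation(ann, refs)
  circ <- ann$seq
  role <- setNames(refs$role, refs$id)
  b <- ann$blocks
  vb <- b[role[b$ref] == "virus", , drop = FALSE]
  n <- nchar(circ)
  if (nrow(vb)) {
    origin_row <- vb[vb$r_start == 1L, , drop = FALSE]
    rot <- if (nrow(origin_row)) {
      origin_row$s_start[1]
    } else {
      vb$s_start[which.min(vb$r_start)]
    }
    if (rot > 1L) {
      circ <- paste0(substr(circ, rot, n), substr(circ, 1L, rot - 1L))
      ann <- segment_scaffold(list(id = "circle", seq = circ), refs, cfg,
                              index)
      ann <- canonical_orientation(ann, refs)
      b <- ann$blocks
    }
  }
  hosti <- which(role[b$ref] == "host")
  viri <- which(role[b$ref] == "virus")
  host_ref <- if (length(hosti)) b$ref[hosti[1]] else NA_character_
  hs <- if (length(hosti)) min(b$r_start[hosti]) else NA_integer_
  he <- if (length(hosti)) max(b$r_end[hosti]) else NA_integer_
  host_strand <- if (length(hosti)) b$strand[hosti[1]] else NA_character_
  host_span <- if (length(hosti)) {
    c(min(b$s_start[hosti]), max(b$s_end[hosti]))
  } else {
    c(NA_integer_, NA_integer_)
  }
  # viral arc on the circle: from the start of the trailing virus block
  # through the origin to the end of the leading virus run
  L <- nchar(refs$seq[refs$role == "virus"])
  lead_vir <- viri[viri < ifelse(length(hosti), min(hosti), Inf)]
  a <- if (length(lead_vir)) b$r_end[max(lead_vir)] else
    suppressWarnings(max(b$r_end[viri]))
  trail_vir <- viri[viri > ifelse(length(hosti), max(hosti), -Inf)]
  bb <- if (length(trail_vir)) b$r_start[min(trail_vir)] else
    suppressWarnings(min(b$r_start[viri]))
  vlen <- if (length(hosti)) arc_len(bb, a, L) else
    sum(b$s_end[viri] - b$s_start[viri] + 1L)
  cls <- classify_scaffold(ann, refs)
  structure(list(
    seq = circ, length = nchar(circ), arc_start = bb, arc_end = a,
    viral_len = vlen, host_ref = host_ref, host_start = hs, host_end = he,
    host_strand = host_strand,
    host_len = if (length(hosti)) he - hs + 1L else 0L,
    host_span = host_span, class = cls, route = "end_overlap",
    anchored_at_origin = FALSE, scaffold_ids = scaffold_ids
  ), class = "minicircle_candidate")
}

#' Merge single-junction partial scaffolds into circular candidates
#'
#' Two scaffolds carrying one virus/host junction each are parts of the same
#' circular molecule when their junction-free host ends map to the same host
#' locus approaching each other (overlapping, abutting, or separated by at
#' most `gap_tol` nt, filled from the host reference) with consistent
#' orientation.  Merged pairs are reconstructed like two-junction
#' candidates; scaffolds compatible with several partners are flagged
#' ambiguous and not merged; singletons pass through flagged incomplete.
#'
#' @param anns list of single-junction `scaffold_annotation` objects.
#' @param refs reference tibble.
#' @param cfg a [pipeline_config()].
#' @param gap_tol maximum reference gap (nt) bridged between the two host
#'   blocks.
#' @return list with `$merged` (list of `minicircle_candidate`),
#'   `$unmerged` (annotations, `attr(,"incomplete") = TRUE`) and
#'   `$ambiguous` (scaffold ids).
#' @export
merge_partial_scaffolds <- function(anns, refs, cfg = pipeline_config(),
                                    gap_tol = 1200L) {
  if (length(anns) == 0L) {
    return(list(merged = list(), unmerged = list(), ambiguous = character()))
  }
  role <- setNames(refs$role, refs$id)
  info <- purrr::map(anns, function(ann) {
    ann <- canonical_orientation(ann, refs)
    b <- ann$blocks
    r <- role[b$ref]
    hosti <- which(r == "host")
    viri <- which(r == "virus")
    if (ann$n_junctions != 1L || length(hosti) == 0L || length(viri) == 0L) {
      return(NULL)
    }
    host_first <- min(hosti) < min(viri)
    list(
      ann = ann,
      side = if (host_first) "b" else "a",   # b: host->virus, a: virus->host
      host_ref = b$ref[hosti[1]],
      host_strand = b$strand[hosti[1]],
      hs = min(b$r_start[hosti]), he = max(b$r_end[hosti]),
      a = if (!host_first) b$r_end[max(viri[viri < min(hosti)])] else
        NA_integer_,
      b = if (host_first) b$r_start[min(viri[viri > max(hosti)])] else
        NA_integer_
    )
  })
  usable <- !vapply(info, is.null, logical(1))
  pairs <- list()
  for (i in which(usable)) {
    for (j in which(usable)) {
      if (i == j) next
      A <- info[[i]]; B <- info[[j]]
      if (A$side != "a" || B$side != "b") next
      if (A$host_ref != B$host_ref || A$host_strand != B$host_strand) next
      ok <- if (A$host_strand == "+") {
        A$hs <= B$hs + gap_tol && A$he <= B$he + gap_tol &&
          B$hs - A$he - 1L <= gap_tol
      } else {
        B$hs <= A$hs + gap_tol && B$he <= A$he + gap_tol &&
          A$hs - B$he - 1L <= gap_tol
      }
      if (ok) pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  cnt <- table(unlist(pairs))
  ambiguous_idx <- as.integer(names(cnt)[cnt > 1L])
  merged <- list()
  used <- integer(0)
  for (p in pairs) {
    if (any(p %in% ambiguous_idx) || any(p %in% used)) next
    A <- info[[p[1]]]; B <- info[[p[2]]]
    hs <- min(A$hs, B$hs); he <- max(A$he, B$he)
    merged[[length(merged) + 1L]] <- build_reference_circle(
      refs, A$a, B$b, A$host_ref, hs, he, A$host_strand, cfg,
      scaffold_ids = c(A$ann$scaffold_id, B$ann$scaffold_id),
      route = "merged_partials"
    )
    used <- c(used, p)
  }
  unmerged <- lapply(setdiff(seq_along(anns), used), function(i) {
    a <- anns[[i]]
    attr(a, "incomplete") <- TRUE
    a
  })
  list(merged = merged, unmerged = unmerged,
       ambiguous = vapply(anns[intersect(ambiguous_idx, seq_along(anns))],
                          function(a) a$scaffold_id, character(1)))
}

#' Compute the feature record of a reconstructed minicircle
#'
#' The published characterization-table row: total/viral/host lengths (the
#' additivity `viral + host = total` holds exactly by construction), viral
#' percentage, per-segment AT percentages, the viral coordinate string in
#' 1-based inclusive virus coordinates, the host locus, ORF-freedom of the
#' host segment, and (when an alignment store and control region are given)
#' the read-depth copy number relative to a single-copy control.
#'
#' @param cand a `minicircle_candidate`.
#' @param refs reference tibble.
#' @param cfg a [pipeline_config()].
#' @param store optional `alignment_store` for copy-number estimation.
#' @param control optional single-copy control region
#'   `list(ref=, start=, end=)`.
#' @return a one-row tibble (`id`, `total_length`, `viral_length`,
#'   `viral_percent`, `host_length`, `viral_coords`, `at_viral`, `at_host`,
#'   `host_locus`, `orf_free_host`, `copy_number_rel`, `route`).
#' @export
annotate_features <- function(cand, refs, cfg = pipeline_config(),
                              store = NULL, control = NULL) {
  L <- nchar(refs$seq[refs$role == "virus"])
  total <- cand$length
  if (!is.na(cand$host_span[1])) {
    host_seq <- substr(cand$seq, cand$host_span[1], cand$host_span[2])
    viral_seq <- paste0(substr(cand$seq, 1L, cand$host_span[1] - 1L),
                        substr(cand$seq, cand$host_span[2] + 1L, total))
  } else {
    host_seq <- ""
    viral_seq <- cand$seq
  }
  cn <- NA_real_
  if (!is.null(store) && !is.null(control) && !is.na(cand$host_ref)) {
    cn <- estimate_copy_number(
      store, list(ref = cand$host_ref, start = cand$host_start,
                  end = cand$host_end), control)
  }
  tibble::tibble(
    id = paste(cand$scaffold_ids, collapse = "/"),
    total_length = total,
    viral_length = cand$viral_len,
    viral_percent = 100 * cand$viral_len / total,
    host_length = cand$host_len,
    viral_coords = viral_coord_string(cand$arc_start, cand$arc_end, L),
    at_viral = segment_at_percent(viral_seq),
    at_host = if (nzchar(host_seq)) segment_at_percent(host_seq) else
      NA_real_,
    host_locus = if (!is.na(cand$host_ref)) {
      paste0(cand$host_ref, ":", cand$host_start, "-", cand$host_end)
    } else {
      NA_character_
    },
    orf_free_host = if (nzchar(host_seq)) {
      nrow(orf_scan(host_seq, circular = FALSE,
                    min_codons = cfg$orf_min_codons)) == 0L
    } else {
      NA
    },
    copy_number_rel = cn,
    route = cand$route
  )
}

#' Scan a sequence for open reading frames
#'
#' All ATG-to-stop frames on both strands; wrap-aware when `circular` so
#' ORFs running through position 1 are found.  An ORF is reported when it
#' spans at least `min_codons` codons (stop codon excluded).
#'
#' @param seq nucleotide string.
#' @param circular treat the sequence as circular.
#' @param min_codons minimum ORF length in codons.
#' @return tibble (`strand`, `start`, `end`, `codons`); coordinates are on
#'   the forward strand of `seq`, `end` wrapped into `1..length` for
#'   origin-spanning ORFs.
#' @export
orf_scan <- function(seq, circular = FALSE, min_codons = 100L) {
  L <- nchar(seq)
  out <- list()
  stops <- c("TAA", "TAG", "TGA")
  for (str in c("+", "-")) {
    s <- if (str == "+") seq else revcomp(seq)
    walk <- if (circular) paste0(s, s) else s
    n <- nchar(walk)
    for (frame in 0:2) {
      starts <- seq.int(1L + frame, n - 2L, by = 3L)
      codons <- substring(walk, starts, starts + 2L)
      open_at <- NA_integer_
      for (ci in seq_along(codons)) {
        cd <- codons[ci]
        if (is.na(open_at) && cd == "ATG" && starts[ci] <= L) {
          open_at <- ci
        } else if (!is.na(open_at) && cd %in% stops) {
          ncod <- ci - open_at
          span <- 3L * (ncod + 1L)
          if (ncod >= min_codons && span <= L) {
            p1 <- starts[open_at]
            p2 <- starts[ci] + 2L
            if (str == "-") {
              tmp1 <- L - canonical_pos(p2, L) + 1L
              tmp2 <- L - canonical_pos(p1, L) + 1L
              p1 <- tmp1; p2 <- tmp2
            } else {
              p1 <- canonical_pos(p1, L); p2 <- canonical_pos(p2, L)
            }
            out[[length(out) + 1L]] <- tibble::tibble(
              strand = str, start = p1, end = p2, codons = ncod
            )
          }
          open_at <- NA_integer_
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(strand = character(), start = integer(),
                          end = integer(), codons = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$start, .data$strand)
}

#' In-silico restriction digestion of a circular molecule
#'
#' Wrap-aware, double-stranded search for the recognition site; a circle cut
#' at k sites yields k fragments whose lengths sum to the circle length.
#'
#' @param seq circular nucleotide string.
#' @param site recognition site (default EcoRI, `GAATTC`).
#' @return list with `uncut` (no site), `sites` (cut positions) and
#'   `fragments` (integer lengths, site order).
#' @export
digest_circular <- function(seq, site = "GAATTC") {
  pos <- sort(unique(c(find_occurrences(seq, site, circular = TRUE),
                       find_occurrences(seq, revcomp(site), circular = TRUE))))
  L <- nchar(seq)
  if (length(pos) == 0L) {
    return(list(uncut = TRUE, sites = integer(0), fragments = integer(0)))
  }
  frags <- if (length(pos) == 1L) L else
    c(diff(pos), L - pos[length(pos)] + pos[1])
  list(uncut = FALSE, sites = pos, fragments = as.integer(frags))
}

#' Predict an inverse-PCR product on a (circular) template
#'
#' Exact primer sites are located wrap-aware: the forward primer on the
#' forward strand, the reverse primer as its reverse complement.  The
#' product runs from the 5' end of the forward primer around the circle to
#' the 3' end of the reverse primer.  On a linear template the primers must
#' converge (forward site upstream of the reverse site) — outward-facing
#' primers on a linear molecule give no product, the negative-control logic
#' of inverse-PCR validation.  Multiple site combinations are all returned
#' and flagged ambiguous.
#'
#' @param seq template sequence.
#' @param primer_fwd,primer_rev primer sequences (>= 15 nt).
#' @param circular is the template circular?
#' @return tibble (`seq`, `length`, `fwd_pos`, `rev_pos`, `ambiguous`);
#'   zero rows when there is no product.
#' @export
inverse_pcr <- function(seq, primer_fwd, primer_rev, circular = TRUE) {
  if (nchar(primer_fwd) < 15L || nchar(primer_rev) < 15L) {
    stop("primers must be at least 15 nt", call. = FALSE)
  }
  L <- nchar(seq)
  f <- find_occurrences(seq, toupper(primer_fwd), circular = circular)
  rsite <- revcomp(toupper(primer_rev))
  r <- find_occurrences(seq, rsite, circular = circular)
  empty <- tibble::tibble(seq = character(), length = integer(),
                          fwd_pos = integer(), rev_pos = integer(),
                          ambiguous = logical())
  if (length(f) == 0L || length(r) == 0L) return(empty)
  combos <- expand.grid(f = f, r = r)
  out <- list()
  for (i in seq_len(nrow(combos))) {
    fp <- combos$f[i]
    rp <- combos$r[i]
    r_end <- rp + nchar(rsite) - 1L
    if (circular) {
      prod <- subseq_circular(seq, fp, canonical_pos(r_end, L))
    } else {
      if (r_end > L || fp > rp) next
      prod <- substr(seq, fp, r_end)
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      seq = prod, length = nchar(prod), fwd_pos = fp, rev_pos = rp
    )
  }
  if (length(out) == 0L) return(empty)
  res <- dplyr::bind_rows(out)
  res$ambiguous <- nrow(res) > 1L
  res
}

#' Read-depth copy number relative to a single-copy control
#'
#' Median per-base alignment depth over the region divided by the median
#' depth over the control region, emulating qPCR quantification normalised
#' to a single-copy gene.  Median, not mean, for robustness to pile-ups at
#' assembly edges.  Returns `NA` (not detected) when the control has zero
#' median depth.
#'
#' @param store an `alignment_store`.
#' @param region,control `list(ref=, start=, end=)`, each >= 200 nt.
#' @return a single numeric copy number (possibly `NA`).
#' @export
estimate_copy_number <- function(store, region, control) {
  stopifnot(region$end - region$start + 1L >= 200L,
            control$end - control$start + 1L >= 200L)
  md <- function(rg) {
    w <- rg$end - rg$start + 1L
    delta <- integer(w + 1L)
    s <- store$segments
    s <- s[s$ref == rg$ref & s$start <= rg$end & s$end >= rg$start, ,
           drop = FALSE]
    if (nrow(s)) {
      lo <- pmax(s$start, rg$start) - rg$start + 1L
      hi <- pmin(s$end, rg$end) - rg$start + 1L
      for (i in seq_along(lo)) {
        delta[lo[i]] <- delta[lo[i]] + 1L
        delta[hi[i] + 1L] <- delta[hi[i] + 1L] - 1L
      }
    }
    median(cumsum(delta[seq_len(w)]))
  }
  c_med <- md(control)
  if (c_med == 0) return(NA_real_)
  md(region) / c_med
}
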