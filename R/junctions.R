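#' Call breakpoint junctions from split alignments
#'
#' Every mate with two or more alignment segments contributes one junction
#' per adjacent segment pair (origin-wrap continuations on the circular
#' virus are not junctions).  For each event the breakpoint is re-derived
#' against the read: the split point is slid across the region between the
#' two segments and placed where total matched bases are maximal; the
#' plateau of equally good placements is the junction microhomology — the
#' span within which the breakpoint cannot be localised because both sides
#' share identical flanks.  Each side of a junction is `(ref, pos, dir)`:
#' `dir = "L"` means the joined segment occupies reference positions
#' `<= pos`, `dir = "R"` that it occupies positions `>= pos`.  The reported
#' placement is the leftmost on the virus side (side a), sides are ordered
#' virus first for virus-host junctions (lexicographically otherwise), and
#' junctions agreeing within `junction_cluster_tol` on both sides are merged
#' with support accumulated (the modal placement represents the cluster).
#'
#' @param store an `alignment_store` from [map_pairs()].
#' @param refs reference tibble; defaults to the store's own references.
#' @param cfg a [pipeline_config()].
#' @return a junction tibble: `ref_a`, `pos_a`, `dir_a`, `ref_b`, `pos_b`,
#'   `dir_b`, `support`, `microhomology`, `jtype` (virus-host, virus-virus
#'   or host-host).
#' @export
call_junctions <- function(store, refs = store$refs, cfg = pipeline_config()) {
  s <- store$segments
  empty <- tibble::tibble(
    ref_a = character(), pos_a = integer(), dir_a = character(),
    ref_b = character(), pos_b = integer(), dir_b = character(),
    support = integer(), microhomology = integer(), jtype = character()
  )
  if (nrow(s) == 0L) return(empty)
  s <- dplyr::arrange(s, .data$read_id, .data$mate, .data$order_index)
  n <- nrow(s)
  same_mate <- s$read_id[-n] == s$read_id[-1] & s$mate[-n] == s$mate[-1]
  boundary <- which(same_mate & s$seg_id[-n] != s$seg_id[-1])
  if (length(boundary) == 0L) return(empty)

  reads <- setNames(c(store$pairs$seq1, store$pairs$seq2),
                    c(paste0(store$pairs$id, "/1"),
                      paste0(store$pairs$id, "/2")))
  role <- setNames(refs$role, refs$id)
  raw <- purrr::map(boundary, function(i) {
    a <- s[i, ]; b <- s[i + 1L, ]
    read <- reads[[paste0(a$read_id, "/", a$mate)]]
    junction_event(a, b, read, refs, role)
  })
  raw <- dplyr::bind_rows(raw)
  if (nrow(raw) == 0L) return(empty)

  key <- paste(raw$ref_a, raw$dir_a, raw$ref_b, raw$dir_b)
  merged <- purrr::map(split(raw, key), function(g) {
    g <- dplyr::arrange(g, .data$pos_a, .data$pos_b)
    g$cl <- cumsum(c(TRUE, diff(g$pos_a) > cfg$junction_cluster_tol |
                       abs(diff(g$pos_b)) > cfg$junction_cluster_tol))
    dplyr::summarise(
      dplyr::group_by(g, .data$cl),
      ref_a = .data$ref_a[1], pos_a = modal_value(.data$pos_a),
      dir_a = .data$dir_a[1],
      ref_b = .data$ref_b[1],
      pos_b = .data$pos_b[which(.data$pos_a == modal_value(.data$pos_a))[1]],
      dir_b = .data$dir_b[1], support = dplyr::n(),
      microhomology = modal_value(.data$microhomology),
      jtype = .data$jtype[1], .groups = "drop"
    )[, -1]
  })
  out <- dplyr::bind_rows(merged)
  dplyr::arrange(out, .data$jtype, .data$ref_a, .data$pos_a, .data$ref_b,
                 .data$pos_b)
}

modal_value <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  as.integer(names(tab)[1])
}

# re-derive one breakpoint event from the read sequence: slide the split
# point across the inter-segment region, maximise matched bases, report the
# canonical (leftmost virus-side) placement within the optimal plateau
junction_event <- function(a, b, read, refs, role) {
  rlen <- nchar(read)
  ref_seq <- setNames(refs$seq, refs$id)
  circ <- setNames(refs$is_circular, refs$id)

  # predicted reference base for read position p under a stored segment
  predict_base <- function(seg, p) {
    rs <- ref_seq[[seg$ref]]
    L <- nchar(rs)
    if (seg$strand == "+") {
      q <- seg$start + (p - seg$read_start)
      if (circ[[seg$ref]]) q <- canonical_pos(q, L)
      if (any(q < 1L | q > L)) {
        out <- rep(NA_character_, length(q))
        inb <- q >= 1L & q <= L
        out[inb] <- vapply(q[inb], function(x) substr(rs, x, x), character(1))
        return(out)
      }
      vapply(q, function(x) substr(rs, x, x), character(1))
    } else {
      q <- seg$end - (p - seg$read_start)
      if (circ[[seg$ref]]) q <- canonical_pos(q, L)
      out <- rep(NA_character_, length(q))
      inb <- q >= 1L & q <= L
      out[inb] <- chartr("ACGT", "TGCA",
                         vapply(q[inb], function(x) substr(rs, x, x),
                                character(1)))
      out
    }
  }
  ref_pos <- function(seg, p) {
    rs <- ref_seq[[seg$ref]]
    L <- nchar(rs)
    q <- if (seg$strand == "+") seg$start + (p - seg$read_start) else
      seg$end - (p - seg$read_start)
    if (circ[[seg$ref]]) q <- canonical_pos(q, L)
    q
  }

  wlo <- max(1L, min(a$read_end, b$read_start) - 25L)
  whi <- min(rlen, max(a$read_end, b$read_start) + 25L)
  if (whi <= wlo) return(NULL)
  pos <- wlo:whi
  rb <- strsplit(substr(read, wlo, whi), "")[[1]]
  ma <- rb == predict_base(a, pos)
  mb <- rb == predict_base(b, pos)
  ma[is.na(ma)] <- FALSE
  mb[is.na(mb)] <- FALSE
  # breakpoint after read position p: A explains [wlo..p], B explains
  # (p..whi]; p ranges over wlo-1 .. whi
  score <- c(0L, cumsum(ma)) + rev(c(0L, cumsum(rev(mb))))
  plateau <- which(score == max(score)) - 1L + (wlo - 1L)
  plateau <- plateau[plateau >= wlo - 1L & plateau <= whi]
  # contiguous run containing the stored boundary region
  if (length(plateau) > 1L) {
    runs <- split(plateau, cumsum(c(TRUE, diff(plateau) != 1L)))
    lens <- vapply(runs, length, integer(1))
    plateau <- runs[[which.max(lens)]]
  }

  side_at <- function(p) {
    side_a <- c(a$ref, ref_pos(a, p), if (a$strand == "+") "L" else "R")
    side_b <- c(b$ref, ref_pos(b, p + 1L), if (b$strand == "+") "R" else "L")
    list(a = side_a, b = side_b)
  }
  # order sides: virus first, else lexicographic by (ref, pos, dir)
  probe <- side_at(plateau[1])
  a_virus <- role[[probe$a[1]]] == "virus"
  b_virus <- role[[probe$b[1]]] == "virus"
  swap <- (b_virus && !a_virus) ||
    (a_virus == b_virus &&
       paste(probe$b[1], probe$b[3]) < paste(probe$a[1], probe$a[3]))
  # leftmost placement on (ordered) side a across the plateau
  cand <- lapply(plateau, side_at)
  pos_of_a <- vapply(cand, function(x) {
    as.integer(if (swap) x$b[2] else x$a[2])
  }, integer(1))
  pick <- cand[[which.min(pos_of_a)]]
  side_a <- if (swap) pick$b else pick$a
  side_b <- if (swap) pick$a else pick$b
  av <- role[[side_a[1]]] == "virus"
  bv <- role[[side_b[1]]] == "virus"
  tibble::tibble(
    ref_a = side_a[1], pos_a = as.integer(side_a[2]), dir_a = side_a[3],
    ref_b = side_b[1], pos_b = as.integer(side_b[2]), dir_b = side_b[3],
    microhomology = length(plateau) - 1L,
    jtype = if (av && bv) "virus-virus" else if (av || bv) "virus-host"
    else "host-host"
  )
}

#' Filter junctions by read support and virus involvement
#'
#' Retains junctions with support of at least `min_junction_support`
#' distinct reads and at least one side on the virus reference (the
#' published selection rule); host-host junctions are always removed,
#' virus-virus junctions are retained but labelled by `jtype` so downstream
#' classification can separate defective replicons from hybrids.
#'
#' @param junctions junction tibble from [call_junctions()].
#' @param cfg a [pipeline_config()].
#' @return the filtered junction tibble.
#' @export
filter_junctions <- function(junctions, cfg = pipeline_config()) {
  dplyr::filter(
    junctions,
    .data$support >= cfg$min_junction_support,
    .data$jtype %in% c("virus-host", "virus-virus")
  )
}

#' Export junction sides as BED intervals
#'
#' One zero-based half-open interval per junction side, for genome-browser
#' inspection.
#'
#' @param junctions junction tibble.
#' @return a BED-style tibble (`chrom`, `start`, `end`, `name`, `score`,
#'   `strand`).
#' @export
junctions_to_bed <- function(junctions) {
  n <- nrow(junctions)
  if (n == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character(),
                          score = integer(), strand = character()))
  }
  jid <- sprintf("junction%03d", seq_len(n))
  dplyr::bind_rows(
    tibble::tibble(chrom = junctions$ref_a, start = junctions$pos_a - 1L,
                   end = junctions$pos_a, name = paste0(jid, "_a"),
                   score = junctions$support,
                   strand = ifelse(junctions$dir_a == "L", "+", "-")),
    tibble::tibble(chrom = junctions$ref_b, start = junctions$pos_b - 1L,
                   end = junctions$pos_b, name = paste0(jid, "_b"),
                   score = junctions$support,
                   strand = ifelse(junctions$dir_b == "L", "+", "-"))
  )
}
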