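#' Simulate a circular virus genome
#'
#' Generates a random circular genome of `cfg$virus_length` nt with the
#' rolling-circle replication origin motif placed at position 1 of the
#' coordinate frame (the conventional start at the stem-loop region) and
#' exactly one EcoRI site (`GAATTC`).  Both the motif and the restriction
#' site occur exactly once on the forward strand, wrap-aware.
#'
#' @param cfg a [simulation_config()].
#' @return a one-row reference tibble (`id`, `seq`, `role`, `is_circular`).
#' @examples
#' v <- sim_virus_genome(simulation_config(seed = 1))
#' nchar(v$seq)
#' @export
sim_virus_genome <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  L <- cfg$virus_length
  motif <- cfg$origin_motif
  if (nchar(motif) + nchar("GAATTC") > L) {
    stop("invalid config: virus genome too short for origin motif + EcoRI site",
         call. = FALSE)
  }
  withr::local_seed(substream_seed(cfg$seed, 1L))
  seq <- random_dna(L, at = 0.60)
  substr(seq, 1L, nchar(motif)) <- motif
  seq <- scrub_motif(seq, motif, keep_at = 1L)
  seq <- scrub_motif(seq, "GAATTC", keep_at = NULL)
  # plant the single EcoRI site away from the origin motif
  p <- sample(seq(nchar(motif) + 10L, L - 20L), 1L)
  substr(seq, p, p + 5L) <- "GAATTC"
  seq <- scrub_motif(seq, motif, keep_at = 1L, protect = c(p, p + 5L))
  stopifnot(count_occurrences(seq, motif, circular = TRUE) == 1L,
            count_occurrences(seq, "GAATTC", circular = TRUE) == 1L)
  tibble::tibble(id = "virus", seq = seq, role = "virus", is_circular = TRUE)
}

# mutate middle base of every occurrence of `motif` except the one starting
# at `keep_at`, wrap-aware; never touches positions inside `protect`
scrub_motif <- function(seq, motif, keep_at = NULL, protect = NULL) {
  L <- nchar(seq)
  k <- nchar(motif)
  repeat {
    occ <- find_occurrences(seq, motif, circular = TRUE)
    occ <- setdiff(occ, keep_at)
    if (length(occ) == 0L) return(seq)
    for (o in occ) {
      mid <- canonical_pos(o + k %/% 2L, L)
      if (!is.null(protect) && mid >= protect[1] && mid <= protect[2]) {
        mid <- canonical_pos(o, L)
      }
      cur <- substr(seq, mid, mid)
      substr(seq, mid, mid) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
  }
}

find_occurrences <- function(seq, motif, circular = FALSE) {
  hay <- if (circular) paste0(seq, substr(seq, 1L, nchar(motif) - 1L)) else seq
  hits <- stringr::str_locate_all(hay, stringr::fixed(motif))[[1]][, 1]
  as.integer(hits[hits <= nchar(seq)])
}

count_occurrences <- function(seq, motif, circular = FALSE) {
  length(find_occurrences(seq, motif, circular))
}

#' Simulate a host genome with catalogued AT-rich intergenic windows
#'
#' Generates `cfg$n_host_chrom` linear chromosomes.  Four non-overlapping
#' 2-kb "intergenic" windows per chromosome are rewritten with an A+T
#' fraction within one percentage point of `cfg$host_at_fraction`; minicircle
#' host fragments are drawn from these catalogued windows, emulating the
#' AT-rich, apparently random intergenic origin of captured host DNA.
#'
#' @param cfg a [simulation_config()].
#' @return a reference tibble of host chromosomes with the window catalogue
#'   attached as attribute `"windows"` (see [at_windows()]).
#' @export
sim_host_genome <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  withr::local_seed(substream_seed(cfg$seed, 2L))
  win_len <- 2000L
  n_win <- 4L
  chroms <- character(cfg$n_host_chrom)
  wins <- vector("list", cfg$n_host_chrom)
  for (i in seq_len(cfg$n_host_chrom)) {
    seq <- random_dna(cfg$host_chrom_length, at = cfg$host_background_at)
    zone <- cfg$host_chrom_length %/% n_win
    starts <- integer(n_win)
    for (w in seq_len(n_win)) {
      lo <- (w - 1L) * zone + 1L
      hi <- w * zone - win_len
      s <- sample(seq(lo, max(lo, hi)), 1L)
      wseq <- random_dna_at_target(win_len, cfg$host_at_fraction, tol = 0.01)
      substr(seq, s, s + win_len - 1L) <- wseq
      starts[w] <- s
    }
    chroms[i] <- seq
    wins[[i]] <- tibble::tibble(
      ref_id = paste0("chr", i), start = starts, end = starts + win_len - 1L
    )
  }
  refs <- tibble::tibble(
    id = paste0("chr", seq_len(cfg$n_host_chrom)),
    seq = chroms, role = "host", is_circular = FALSE
  )
  windows <- dplyr::bind_rows(wins)
  windows$at_percent <- vapply(seq_len(nrow(windows)), function(j) {
    100 * at_fraction(substr(refs$seq[match(windows$ref_id[j], refs$id)],
                             windows$start[j], windows$end[j]))
  }, numeric(1))
  attr(refs, "windows") <- windows
  refs
}

random_dna_at_target <- function(n, at, tol) {
  repeat {
    s <- random_dna(n, at = at)
    if (abs(at_fraction(s) - at) <= tol) return(s)
  }
}

#' @rdname sim_host_genome
#' @param host a host reference tibble from [sim_host_genome()].
#' @export
at_windows <- function(host) {
  w <- attr(host, "windows")
  if (is.null(w)) stop("no AT-window catalogue attached", call. = FALSE)
  w
}

#' Combine virus and host references into one reference set
#'
#' @param virus one-row virus reference tibble ([sim_virus_genome()]).
#' @param host host reference tibble ([sim_host_genome()]).
#' @return a reference tibble with exactly one circular virus sequence.
#' @export
combine_refs <- function(virus, host) {
  refs <- dplyr::bind_rows(virus, host)
  validate_refs(refs)
  attr(refs, "windows") <- attr(host, "windows")
  refs
}

validate_refs <- function(refs) {
  stopifnot(is.data.frame(refs),
            all(c("id", "seq", "role", "is_circular") %in% names(refs)))
  if (anyDuplicated(refs$id)) {
    stop("duplicate reference ids", call. = FALSE)
  }
  if (sum(refs$role == "virus") != 1L) {
    stop("reference set must contain exactly one virus sequence",
         call. = FALSE)
  }
  if (!refs$is_circular[refs$role == "virus"]) {
    stop("virus reference must be circular", call. = FALSE)
  }
  if (any(refs$is_circular[refs$role == "host"])) {
    stop("host references must be linear", call. = FALSE)
  }
  invisible(refs)
}

virus_row <- function(refs) refs[refs$role == "virus", ]

#' Simulate one hybrid minicircle template
#'
#' Builds a circular template joining a viral arc that runs through the
#' replication origin (so every minicircle retains the origin and intergenic
#' region) to a host fragment drawn from a catalogued AT-rich window.  Each
#' of the two junctions may carry planted microhomology: the flanks of the
#' breakpoint share `mh` identical bases, making its position ambiguous
#' within that span.  Truth coordinates are exact and returned alongside.
#'
#' @param virus one-row virus reference tibble.
#' @param host host reference tibble with an AT-window catalogue.
#' @param cfg a [simulation_config()].
#' @param viral_arc optional explicit `c(arc_start, arc_end)` on the virus
#'   (wrap through the origin, e.g. `c(2435, 172)`); sampled when `NULL`.
#' @param host_len optional explicit host fragment length (nt).
#' @param mh optional explicit `c(mh1, mh2)` planted microhomology at the
#'   virus-to-host and host-to-virus junctions.
#' @param window_idx optional row index into the AT-window catalogue.
#' @param id template id.
#' @return a one-row template tibble; see Details for columns.
#' @details Columns: `id`, `class` (`"hybrid"`), `seq`, `length`,
#'   `copy_number`, `viral_coords` (printed 1-based string), `viral_len`,
#'   `arc_start`/`arc_end` (virus arc through the origin), `host_ref`,
#'   `host_start`, `host_end`, `host_strand`, `host_len`, `mh1`, `mh2`.
#'   The template sequence starts at the arc start, runs through the origin
#'   to the arc end, then through the host fragment; its length equals
#'   `viral_len + host_len - mh1 - mh2` (overlapping bases counted once).
#' @export
sim_minicircle <- function(virus, host, cfg = simulation_config(),
                           viral_arc = NULL, host_len = NULL, mh = NULL,
                           window_idx = NULL, id = "mc1") {
  L <- cfg$virus_length
  vseq <- virus$seq[1]
  wins <- at_windows(host)
  tb <- cfg$minicircle_total_bounds
  hb <- cfg$host_fragment_bounds

  if (is.null(viral_arc)) {
    # arc [b..L]+[1..a] must contain the conserved intergenic span
    a <- sample(seq(cfg$intergenic_span[2], 330L), 1L)
    vmin <- max(332L, a + (L - cfg$intergenic_span[1] + 1L))
    vmax <- min(763L, tb[2] - hb[1] + 6L)
    vlen <- sample(seq(vmin, max(vmin, vmax)), 1L)
    b <- L + 1L + a - vlen
  } else {
    b <- as.integer(viral_arc[1]); a <- as.integer(viral_arc[2])
    vlen <- arc_len(b, a, L)
  }
  if (!arc_contains(b, a, 1L, nchar(cfg$origin_motif), L)) {
    stop("invalid config: viral arc does not cover the origin", call. = FALSE)
  }
  if (is.null(mh)) {
    mh <- sample(seq(cfg$microhomology_range[1], cfg$microhomology_range[2]),
                 2L, replace = TRUE)
  }
  mh <- as.integer(mh)
  explicit_host_len <- !is.null(host_len)
  # the host interval length (maximal, microhomology bases included) must
  # itself be in bounds AND leave the final circle length
  # vlen + host_len - mh1 - mh2 inside the total bounds
  lo <- max(hb[1], tb[1] - vlen + sum(mh))
  hi <- min(hb[2], tb[2] - vlen + sum(mh))
  if (is.null(host_len)) {
    if (lo > hi) {
      stop("invalid config: host fragment bounds incompatible with total ",
           "length bounds for this viral arc", call. = FALSE)
    }
    host_len <- sample(seq(lo, hi), 1L)
  }
  host_len <- as.integer(host_len)
  if (host_len < 1L) stop("impossible geometry", call. = FALSE)
  if (explicit_host_len) {
    lo <- host_len
    hi <- host_len
  }
  if (is.null(window_idx)) window_idx <- sample(nrow(wins), 1L)
  win <- wins[window_idx, ]
  strand <- sample(c("+", "-"), 1L)
  wseq_fwd <- substr(host$seq[match(win$ref_id, host$id)], win$start, win$end)
  wseq <- if (strand == "+") wseq_fwd else revcomp(wseq_fwd)

  # plant microhomology by choosing the fragment so its flanks repeat the
  # viral flanks; fall back to shorter microhomology when no site exists
  j1_flank <- function(m) subseq_circular(vseq, a - m + 1L, a)   # virus tail
  j2_flank <- function(m) subseq_circular(vseq, b, b + m - 1L)   # virus head
  wlen <- nchar(wseq)
  ws <- NA_integer_
  m1 <- mh[1]
  repeat {
    cand <- if (m1 == 0L) {
      seq_len(wlen - host_len + 1L)
    } else {
      hits <- find_occurrences(wseq, j1_flank(m1))
      hits[hits <= wlen - host_len + 1L]
    }
    if (length(cand) > 0L) { ws <- sample_one(cand); break }
    m1 <- m1 - 1L
    if (m1 < 0L) stop("cannot place host fragment", call. = FALSE)
  }
  m2 <- mh[2]
  we <- NA_integer_
  repeat {
    lo_e <- ws + lo - 1L
    hi_e <- min(wlen, ws + hi - 1L)
    cand <- if (m2 == 0L) {
      ws + host_len - 1L
    } else {
      hits <- find_occurrences(wseq, j2_flank(m2)) + m2 - 1L
      hits[hits >= lo_e & hits <= hi_e]
    }
    cand <- cand[cand <= wlen]
    if (length(cand) > 0L) {
      we <- cand[which.min(abs(cand - (ws + host_len - 1L)))]
      break
    }
    m2 <- m2 - 1L
    if (m2 < 0L) stop("cannot place host fragment", call. = FALSE)
  }
  host_len <- we - ws + 1L

  frag <- substr(wseq, ws, we)
  viral_part <- subseq_circular(vseq, canonical_pos(b + m2, L), a)
  seq <- paste0(viral_part, substr(frag, m1 + 1L, host_len))
  # host coordinates on the forward strand of the chromosome
  if (strand == "+") {
    hs <- win$start + ws - 1L
    he <- win$start + we - 1L
  } else {
    he <- win$end - ws + 1L
    hs <- win$end - we + 1L
  }
  cn <- exp(runif(1, log(cfg$copy_number_range[1]),
                  log(cfg$copy_number_range[2])))
  total <- nchar(seq)
  tibble::tibble(
    id = id, class = "hybrid", seq = seq, length = total,
    copy_number = cn,
    viral_coords = viral_coord_string(b, a, L),
    viral_len = vlen, arc_start = b, arc_end = a,
    host_ref = win$ref_id, host_start = hs, host_end = he,
    host_strand = strand, host_len = host_len,
    mh1 = m1, mh2 = m2,
    # junction boundaries in template coordinates: "after position q";
    # virus-to-host at the end of the viral part, host-to-virus at the wrap
    junc_tpos = list(c(vlen - m2, total))
  )
}

sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# does the forward arc [b..a] (wrap-aware) contain the interval [s..e]?
arc_contains <- function(b, a, s, e, L) {
  off_s <- (s - b) %% L
  off_e <- (e - b) %% L
  alen <- arc_len(b, a, L)
  off_s < alen && off_e < alen && off_s <= off_e
}

# printed coordinate string for a viral arc through the origin,
# e.g. "1-172 ... 2435-2845" (ascending canonical intervals)
viral_coord_string <- function(b, a, L) {
  if (b <= a) {
    paste0(b, "–", a)
  } else {
    paste0("1–", a, " … ", b, "–", L)
  }
}

#' Simulate a defective (virus-only) circular template
#'
#' A deletion derivative of the helper virus: the retained intervals are
#' concatenated in the given order into a circle with no host-derived DNA.
#' At least one interval must cover the replication origin.
#'
#' @param virus one-row virus reference tibble.
#' @param retained list of `c(start, end)` 1-based inclusive intervals on the
#'   virus genome, in circle order.
#' @param cfg a [simulation_config()] (origin motif and copy-number model).
#' @param id template id.
#' @param copy_number optional explicit copy number.
#' @return a one-row template tibble with `class = "defective"` and empty
#'   host fields.
#' @export
sim_defective <- function(virus, retained, cfg = simulation_config(),
                          id = "def1", copy_number = NULL) {
  vseq <- virus$seq[1]
  L <- nchar(vseq)
  motif_len <- nchar(cfg$origin_motif)
  covers <- vapply(retained, function(iv) {
    arc_contains(iv[1], iv[2], 1L, motif_len, L)
  }, logical(1))
  if (!any(covers)) {
    stop("invalid config: no retained interval covers the origin",
         call. = FALSE)
  }
  seq <- paste(vapply(retained, function(iv) {
    subseq_circular(vseq, iv[1], iv[2])
  }, character(1)), collapse = "")
  if (is.null(copy_number)) {
    copy_number <- exp(runif(1, log(cfg$copy_number_range[1]),
                             log(cfg$copy_number_range[2])))
  }
  ivs <- vapply(retained, function(iv) paste0(iv[1], "–", iv[2]),
                character(1))
  # a junction sits after interval i unless the next interval (circularly)
  # starts right where interval i ends + 1 on the virus circle
  ends_at <- cumsum(vapply(retained, function(iv) arc_len(iv[1], iv[2], L),
                           integer(1)))
  jt <- integer(0)
  k <- length(retained)
  for (i in seq_len(k)) {
    nxt <- retained[[if (i == k) 1L else i + 1L]]
    if (canonical_pos(retained[[i]][2] + 1L, L) != canonical_pos(nxt[1], L)) {
      jt <- c(jt, ends_at[i])
    }
  }
  tibble::tibble(
    id = id, class = "defective", seq = seq, length = nchar(seq),
    copy_number = copy_number,
    viral_coords = paste(ivs, collapse = " … "),
    viral_len = nchar(seq), arc_start = NA_integer_, arc_end = NA_integer_,
    host_ref = NA_character_, host_start = NA_integer_,
    host_end = NA_integer_, host_strand = NA_character_, host_len = 0L,
    mh1 = 0L, mh2 = 0L,
    junc_tpos = list(jt)
  )
}

#' Simulate a paired-end sequencing library
#'
#' Draws sonication-style fragments from circular templates (wrap-aware
#' across the origin, expected fold-coverage proportional to copy number)
#' and whole-genome background fragments from every reference at
#' `background_depth`, then sequences each fragment as a 2 x `read_length`
#' pair with independent per-base substitution errors and 3' adapter
#' read-through when the fragment is shorter than the read.
#'
#' @param templates template tibble ([sim_minicircle()], [sim_defective()]);
#'   may be `NULL` or empty.
#' @param refs reference tibble ([combine_refs()]).
#' @param cfg a [simulation_config()].
#' @param ensure_junction_support when > 0, additional fragments are drawn
#'   until every planted junction of every template is spanned by at least
#'   this many reads with >= 16 nt on both sides of the breakpoint (the
#'   planted split-read support).
#' @return a `read_library` list: `$pairs` tibble (`id`, `seq1`, `qual1`,
#'   `seq2`, `qual2`), `$truth` per-read tibble (`id`, `src`, `class`,
#'   `frag_start`, `insert`, `strand`) and `$templates` (the input truth
#'   table).  A fixed seed yields byte-identical output.
#' @export
sim_read_library <- function(templates, refs, cfg = simulation_config(),
                             ensure_junction_support = cfg$min_junction_reads) {
  validate_refs(refs)
  withr::local_seed(substream_seed(cfg$seed, 3L))
  rl <- cfg$read_length
  if (is.null(templates)) templates <- empty_template_table()
  sources <- list()

  # copy number is relative to 1x chromosomal background; when background
  # sequencing is disabled templates are still sequenced at copy_number-fold
  depth_unit <- if (cfg$background_depth > 0) cfg$background_depth else 1
  for (i in seq_len(nrow(templates))) {
    t <- templates[i, ]
    depth <- depth_unit * cfg$template_depth * t$copy_number
    n <- rpois(1L, t$length * depth / (2 * rl))
    fr <- draw_fragments(n, t$length, cfg, circular = TRUE)
    if (ensure_junction_support > 0L && t$class %in% c("hybrid", "defective")) {
      fr <- top_up_junctions(fr, t, cfg, ensure_junction_support)
    }
    if (nrow(fr)) {
      fr$src <- t$id
      fr$class <- t$class
      sources[[length(sources) + 1L]] <- fr
    }
  }
  if (cfg$background_depth > 0) {
    for (i in seq_len(nrow(refs))) {
      len <- nchar(refs$seq[i])
      n <- rpois(1L, len * cfg$background_depth / (2 * rl))
      fr <- draw_fragments(n, len, cfg, circular = refs$is_circular[i])
      if (nrow(fr)) {
        fr$src <- refs$id[i]
        fr$class <- "background"
        sources[[length(sources) + 1L]] <- fr
      }
    }
  }
  if (length(sources) == 0L) {
    warning("no templates and no background: empty library")
    return(structure(list(pairs = empty_pair_table(),
                          truth = empty_truth_table(),
                          templates = templates),
                     class = "read_library"))
  }
  frags <- dplyr::bind_rows(sources)
  seqs <- c(setNames(templates$seq, templates$id),
            setNames(refs$seq, refs$id))
  frags$id <- sprintf("rd%06d", seq_len(nrow(frags)))
  pairs <- sequence_fragments(frags, seqs, cfg)
  truth <- tibble::tibble(
    id = frags$id, src = frags$src, class = frags$class,
    frag_start = frags$start, insert = frags$insert, strand = frags$strand
  )
  structure(list(pairs = pairs, truth = truth, templates = templates),
            class = "read_library")
}

empty_template_table <- function() {
  tibble::tibble(id = character(), class = character(), seq = character(),
                 length = integer(), copy_number = numeric(),
                 viral_coords = character(), viral_len = integer(),
                 arc_start = integer(), arc_end = integer(),
                 host_ref = character(), host_start = integer(),
                 host_end = integer(), host_strand = character(),
                 host_len = integer(), mh1 = integer(), mh2 = integer(),
                 junc_tpos = list())
}

empty_pair_table <- function() {
  tibble::tibble(id = character(), seq1 = character(), qual1 = character(),
                 seq2 = character(), qual2 = character())
}

empty_truth_table <- function() {
  tibble::tibble(id = character(), src = character(), class = character(),
                 frag_start = integer(), insert = integer(),
                 strand = character())
}

draw_fragments <- function(n, len, cfg, circular) {
  if (n <= 0L) {
    return(tibble::tibble(start = integer(), insert = integer(),
                          strand = character()))
  }
  ins <- pmax(40L, pmin(as.integer(round(rnorm(n, cfg$insert_mean,
                                               cfg$insert_sd))), len))
  if (circular) {
    start <- sample.int(len, n, replace = TRUE)
  } else {
    start <- vapply(ins, function(i) sample.int(max(1L, len - i + 1L), 1L),
                    integer(1))
  }
  tibble::tibble(start = start, insert = ins,
                 strand = sample(c("+", "-"), n, replace = TRUE))
}

# planted-junction template positions: boundary q means "between template
# positions q and q+1" (wrap at q = length)
template_junction_positions <- function(t) {
  if (!is.null(t$junc_tpos)) t$junc_tpos[[1]] else integer(0)
}

top_up_junctions <- function(fr, t, cfg, target) {
  rl <- cfg$read_length
  arm <- 16L
  len <- t$length
  for (q in template_junction_positions(t)) {
    spans <- function(st) {
      # read occupies template positions st..st+rl-1 (wrap); spans boundary q
      # with >= arm nt on both sides
      off <- (q - st) %% len
      off >= arm - 1L & off <= rl - arm - 1L
    }
    count_spanning <- function(fr) {
      if (nrow(fr) == 0L) return(0L)
      r1 <- ifelse(fr$strand == "+", fr$start,
                   canonical_pos(fr$start + fr$insert - rl, len))
      r2 <- ifelse(fr$strand == "+",
                   canonical_pos(fr$start + fr$insert - rl, len), fr$start)
      sum(spans(r1)) + sum(spans(r2))
    }
    have <- count_spanning(fr)
    while (have < target) {
      st <- canonical_pos(q - sample(seq(arm - 1L, rl - arm - 1L), 1L), len)
      add <- tibble::tibble(
        start = st,
        insert = pmax(rl, pmin(as.integer(round(
          rnorm(1, cfg$insert_mean, cfg$insert_sd))), len)),
        strand = "+"
      )
      fr <- dplyr::bind_rows(fr, add)
      have <- have + 1L
    }
  }
  fr
}

sequence_fragments <- function(frags, seqs, cfg) {
  rl <- cfg$read_length
  n <- nrow(frags)
  seq1 <- character(n); seq2 <- character(n)
  for (i in seq_len(n)) {
    src <- seqs[[frags$src[i]]]
    ins <- min(frags$insert[i], nchar(src))
    frag <- subseq_circular(src, frags$start[i], frags$start[i] + ins - 1L)
    if (frags$strand[i] == "-") frag <- revcomp(frag)
    if (ins >= rl) {
      r1 <- substr(frag, 1L, rl)
      r2 <- revcomp(substr(frag, ins - rl + 1L, ins))
    } else {
      fill <- substr(cfg$adapter_seq, 1L, rl - ins)
      fill <- paste0(fill, strrep("A", rl - ins - nchar(fill)))
      r1 <- paste0(frag, fill)
      r2 <- paste0(revcomp(frag), fill)
    }
    seq1[i] <- r1; seq2[i] <- r2
  }
  if (cfg$per_base_error > 0) {
    seq1 <- add_substitutions(seq1, cfg$per_base_error)
    seq2 <- add_substitutions(seq2, cfg$per_base_error)
  }
  qual <- int_to_phred(rep(cfg$quality_q, rl))
  tibble::tibble(id = frags$id, seq1 = seq1, qual1 = qual,
                 seq2 = seq2, qual2 = qual)
}

add_substitutions <- function(reads, rate) {
  n_err <- rpois(length(reads), nchar(reads) * rate)
  idx <- which(n_err > 0L)
  for (i in idx) {
    pos <- sample.int(nchar(reads[i]), min(n_err[i], nchar(reads[i])))
    for (p in pos) {
      cur <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
  }
  reads
}

#' Simulate a full infected-plant study dataset
#'
#' The default study conditions: one circular 2845-nt virus, five 200-kb host
#' chromosomes, eight hybrid minicircles with distinct host loci, two
#' defective (virus-only) circles, the intact helper virus at high copy
#' number, 1x whole-genome background, and a guaranteed planted split-read
#' support of at least `cfg$min_junction_reads` per junction.
#'
#' @param cfg a [simulation_config()].
#' @return a list with `$refs`, `$windows`, `$templates` (truth table) and
#'   `$library` (a `read_library`).
#' @export
sim_study <- function(cfg = simulation_config()) {
  virus <- sim_virus_genome(cfg)
  host <- sim_host_genome(cfg)
  refs <- combine_refs(virus, host)
  wins <- at_windows(host)
  withr::local_seed(substream_seed(cfg$seed, 4L))
  widx <- sample(nrow(wins), cfg$n_hybrids)
  hybrids <- purrr::map(seq_len(cfg$n_hybrids), function(i) {
    sim_minicircle(virus, host, cfg, window_idx = widx[i],
                   id = sprintf("hyb%02d", i))
  })
  L <- cfg$virus_length
  defectives <- purrr::map(seq_len(cfg$n_defectives), function(i) {
    a <- sample(200:500, 1L)
    alen <- sample(1100:1450, 1L)
    b <- L + 1L + a - alen
    sim_defective(virus, list(c(1L, a), c(b, L)), cfg,
                  id = sprintf("def%02d", i))
  })
  helper <- sim_defective(virus, list(c(1L, L)), cfg, id = "helper",
                          copy_number = cfg$helper_copy_number)
  helper$class <- "helper"
  templates <- dplyr::bind_rows(c(hybrids, defectives, list(helper)))
  library <- sim_read_library(templates, refs, cfg)
  list(refs = refs, windows = wins, templates = templates, library = library)
}
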