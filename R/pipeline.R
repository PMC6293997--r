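#' Run the full minicircle detection pipeline
#'
#' Orchestrates trimming, pair filtering, split-read alignment, junction
#' calling and filtering, targeted read recovery, per-locus greedy assembly,
#' scaffold annotation, partial-scaffold merging, circular reconstruction
#' and feature annotation, end to end and deterministically.  Virus-host
#' junction groups (clustered by host locus) are assembled from host-side
#' recovery windows — every replicon shares the near-origin viral arc, so
#' the unique host flank is what separates templates; virus-virus junction
#' groups use the published both-side windows.
#'
#' @param pairs read-pair tibble; when `NULL` a full study dataset is
#'   simulated with [sim_study()] under `sim_cfg`.
#' @param refs reference tibble (required when `pairs` is given).
#' @param sim_cfg a [simulation_config()] used when simulating.
#' @param cfg a [pipeline_config()].
#' @param seed seed for the deterministic sub-sampling of deep read groups.
#' @param keep_store keep the alignment store in the result (needed for
#'   copy-number estimation and read-level inspection).
#' @return a `minicircle_run` list; see [tidy.minicircle_run()],
#'   [glance.minicircle_run()], [compare_to_truth()] and
#'   [write_run_outputs()].
#' @export
run_pipeline <- function(pairs = NULL, refs = NULL,
                         sim_cfg = simulation_config(),
                         cfg = pipeline_config(), seed = sim_cfg$seed,
                         keep_store = TRUE) {
  truth <- NULL
  adapter <- sim_cfg$adapter_seq
  if (is.null(pairs)) {
    study <- sim_study(sim_cfg)
    pairs <- study$library$pairs
    refs <- study$refs
    truth <- study
  }
  if (is.null(refs)) {
    stop("refs are required before any stage runs", call. = FALSE)
  }
  validate_refs(refs)

  trimmed <- trim_pairs(pairs, cfg, adapter = adapter)
  filtered <- filter_pairs(trimmed, cfg)
  trim_report <- attr(filtered, "report")

  index <- build_seed_index(refs, cfg)
  store <- map_pairs(index, filtered, cfg)

  junctions_all <- call_junctions(store, refs, cfg)
  junctions <- filter_junctions(junctions_all, cfg)

  groups <- group_junctions(junctions)
  scaffolds <- list()
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    vh <- any(g$jtype == "virus-host")
    reads_g <- recover_reads(store, g, cfg,
                             sides = if (vh) "host" else "both")
    reads_g <- subsample_pairs(reads_g, cfg$max_group_pairs,
                               substream_seed(seed, 100L + gi))
    scf <- assemble_reads(reads_g, cfg)
    if (nrow(scf)) {
      scf$group <- gi
      scaffolds[[length(scaffolds) + 1L]] <- scf
    }
  }
  scaffolds <- if (length(scaffolds)) dplyr::bind_rows(scaffolds) else
    tibble::tibble(id = character(), seq = character(), n_reads = integer(),
                   mean_depth = numeric(), group = integer())
  if (nrow(scaffolds)) {
    scaffolds$id <- sprintf("scf%02d", seq_len(nrow(scaffolds)))
  }

  anns <- purrr::map(seq_len(nrow(scaffolds)), function(i) {
    segment_scaffold(scaffolds[i, ], refs, cfg, index)
  })
  classes <- vapply(anns, function(a) a$class, character(1))

  candidates <- list()
  partials <- list()
  for (a in anns) {
    if (a$class != "hybrid") next
    if (a$n_junctions >= 2L) {
      cand <- tryCatch(circularize_candidate(a, refs, cfg, index),
                       error = function(e) NULL)
      if (!is.null(cand) && cand$class == "hybrid") {
        candidates[[length(candidates) + 1L]] <- cand
      } else {
        partials[[length(partials) + 1L]] <- a
      }
    } else {
      partials[[length(partials) + 1L]] <- a
    }
  }
  mp <- merge_partial_scaffolds(partials, refs, cfg)
  candidates <- c(candidates, mp$merged)
  candidates <- dedupe_candidates(candidates, cfg)

  control <- pick_control_region(refs, candidates)
  records <- purrr::map(candidates, function(cand) {
    annotate_features(cand, refs, cfg, store = store, control = control)
  })
  records <- if (length(records)) dplyr::bind_rows(records) else
    annotate_features_empty()
  if (nrow(records)) {
    records$id <- sprintf("mc%02d", seq_len(nrow(records)))
  }

  counts <- tibble::tibble(
    pairs_in = nrow(pairs),
    pairs_surviving = trim_report$n_out,
    fraction_surviving = trim_report$fraction_surviving,
    mates_aligned = length(unique(paste(store$segments$read_id,
                                        store$segments$mate))),
    junctions_called = nrow(junctions_all),
    junctions_selected = nrow(junctions),
    scaffolds = nrow(scaffolds),
    hybrids = sum(classes == "hybrid"),
    defectives = sum(classes == "defective"),
    circles = nrow(records)
  )
  structure(list(
    refs = refs, cfg = cfg, sim_cfg = sim_cfg, seed = seed,
    counts = counts, trim_report = trim_report,
    junctions_all = junctions_all, junctions = junctions,
    scaffolds = scaffolds, annotations = anns, classes = classes,
    candidates = candidates, records = records,
    ambiguous = mp$ambiguous, truth = truth,
    store = if (keep_store) store else NULL
  ), class = "minicircle_run")
}

annotate_features_empty <- function() {
  tibble::tibble(id = character(), total_length = integer(),
                 viral_length = integer(), viral_percent = numeric(),
                 host_length = integer(), viral_coords = character(),
                 at_viral = numeric(), at_host = numeric(),
                 host_locus = character(), orf_free_host = logical(),
                 copy_number_rel = numeric(), route = character())
}

# cluster selected junctions into assembly groups: virus-host junctions by
# host locus (20-kb single-linkage), virus-virus junctions individually
group_junctions <- function(junctions, locus_tol = 20000L) {
  if (nrow(junctions) == 0L) return(list())
  groups <- list()
  vh <- junctions[junctions$jtype == "virus-host", , drop = FALSE]
  if (nrow(vh)) {
    vh <- vh[order(vh$ref_b, vh$pos_b), , drop = FALSE]
    cl <- cumsum(c(TRUE, vh$ref_b[-1] != vh$ref_b[-nrow(vh)] |
                     diff(vh$pos_b) > locus_tol))
    for (g in split(vh, cl)) groups[[length(groups) + 1L]] <- g
  }
  vv <- junctions[junctions$jtype == "virus-virus", , drop = FALSE]
  for (i in seq_len(nrow(vv))) {
    groups[[length(groups) + 1L]] <- vv[i, , drop = FALSE]
  }
  groups
}

subsample_pairs <- function(pairs, max_pairs, seed) {
  if (nrow(pairs) <= max_pairs) return(pairs)
  withr::local_seed(seed)
  pairs[sort(sample.int(nrow(pairs), max_pairs)), , drop = FALSE]
}

# a single-copy control region on the lexicographically first host
# chromosome, shifted until it avoids every candidate host locus
pick_control_region <- function(refs, candidates, width = 2000L) {
  host <- refs[refs$role == "host", , drop = FALSE]
  host <- host[order(host$id), , drop = FALSE]
  ref <- host$id[1]
  L <- nchar(host$seq[1])
  loci <- purrr::keep(candidates, function(c) {
    !is.na(c$host_ref) && c$host_ref == ref
  })
  start <- 1000L
  repeat {
    end <- start + width - 1L
    clash <- any(vapply(loci, function(c) {
      c$host_start <= end + 500L && c$host_end >= start - 500L
    }, logical(1)))
    if (!clash || end + 5000L > L) break
    start <- start + 5000L
  }
  list(ref = ref, start = start, end = start + width - 1L)
}

# collapse duplicate reconstructions of the same molecule (same host locus,
# same viral arc within the cluster tolerance)
dedupe_candidates <- function(candidates, cfg) {
  if (length(candidates) <= 1L) return(candidates)
  keep <- rep(TRUE, length(candidates))
  for (i in seq_along(candidates)) {
    if (!keep[i]) next
    for (j in seq_along(candidates)) {
      if (j <= i || !keep[j]) next
      a <- candidates[[i]]; b <- candidates[[j]]
      if (is.na(a$host_ref) || is.na(b$host_ref)) next
      if (a$host_ref == b$host_ref &&
            a$host_start <= b$host_end && a$host_end >= b$host_start &&
            abs(a$arc_start - b$arc_start) <= cfg$junction_cluster_tol &&
            abs(a$arc_end - b$arc_end) <= cfg$junction_cluster_tol) {
        keep[j] <- FALSE
      }
    }
  }
  candidates[keep]
}

#' Evaluate a simulated run against its planted truth
#'
#' Matches every planted hybrid template to reconstructed circles by host
#' locus overlap and reports per-template detection, junction coordinate
#' error (virus-side, modulo the planted microhomology span), length error,
#' plus aggregate sensitivity and precision for hybrid detection.
#'
#' @param run a `minicircle_run` produced on simulated data.
#' @param truth the simulation truth (defaults to the run's own).
#' @return list with `$per_template` and `$summary` tibbles.
#' @export
compare_to_truth <- function(run, truth = run$truth) {
  if (is.null(truth) || nrow(truth$templates) == 0L) {
    stop("no truth table available", call. = FALSE)
  }
  tpl <- truth$templates[truth$templates$class == "hybrid", , drop = FALSE]
  if (nrow(tpl) == 0L) stop("truth table has no hybrid templates",
                            call. = FALSE)
  cands <- run$candidates
  L <- nchar(run$refs$seq[run$refs$role == "virus"])
  per <- purrr::map(seq_len(nrow(tpl)), function(i) {
    t <- tpl[i, ]
    mh <- truth_junction_spans(t, run$refs)
    hit <- which(vapply(cands, function(c) {
      !is.na(c$host_ref) && c$host_ref == t$host_ref &&
        c$host_start <= t$host_end && c$host_end >= t$host_start
    }, logical(1)))
    if (length(hit) == 0L) {
      return(tibble::tibble(
        template = t$id, detected = FALSE, length_error = NA_integer_,
        arc_start_error = NA_integer_, arc_end_error = NA_integer_,
        mh_arc_start = mh[2], mh_arc_end = mh[1],
        microhomology = sum(mh)
      ))
    }
    c <- cands[[hit[1]]]
    d_circ <- function(x, y) {
      d <- abs(x - y)
      min(d, L - d)
    }
    tibble::tibble(
      template = t$id, detected = TRUE,
      length_error = c$length - t$length,
      arc_start_error = d_circ(c$arc_start, t$arc_start),
      arc_end_error = d_circ(c$arc_end, t$arc_end),
      mh_arc_start = mh[2], mh_arc_end = mh[1],
      microhomology = sum(mh)
    )
  })
  per <- dplyr::bind_rows(per)
  per$within_mh <- per$detected &
    per$arc_start_error <= per$mh_arc_start &
    per$arc_end_error <= per$mh_arc_end
  matched <- vapply(cands, function(c) {
    !is.na(c$host_ref) && any(
      tpl$host_ref == c$host_ref & tpl$host_start <= c$host_end &
        tpl$host_end >= c$host_start)
  }, logical(1))
  summary <- tibble::tibble(
    n_templates = nrow(tpl),
    n_detected = sum(per$detected),
    n_candidates = length(cands),
    n_false_positive = sum(!matched),
    sensitivity = sum(per$detected) / nrow(tpl),
    precision = if (length(cands)) sum(matched) / length(cands) else NA_real_,
    max_abs_length_error = max(abs(per$length_error), 0L, na.rm = TRUE),
    max_junction_error = max(c(per$arc_start_error, per$arc_end_error, 0L),
                             na.rm = TRUE)
  )
  list(per_template = per, summary = summary)
}

# actual breakpoint-ambiguity span at the two planted junctions of a hybrid
# template, measured from the references: the planted microhomology plus any
# chance flank identity, i.e. how far the true breakpoint can slide while
# describing the same molecule
truth_junction_spans <- function(t, refs, cap = 15L) {
  vseq <- refs$seq[refs$role == "virus"]
  L <- nchar(vseq)
  hseq <- refs$seq[match(t$host_ref, refs$id)]
  vb <- function(p) {
    p <- canonical_pos(p, L)
    substr(vseq, p, p)
  }
  # host molecule base at fragment offset i (1 = first base of the maximal
  # host interval); offsets outside the interval walk into the chromosome
  hmol <- function(i) {
    p <- if (t$host_strand == "+") t$host_start + i - 1L else
      t$host_end - i + 1L
    if (p < 1L || p > nchar(hseq)) return(NA_character_)
    b <- substr(hseq, p, p)
    if (t$host_strand == "-") b <- chartr("ACGT", "TGCA", b)
    b
  }
  run_len <- function(f) {
    j <- 0L
    while (j < cap && isTRUE(f(j + 1L))) j <- j + 1L
    j
  }
  a <- t$arc_end
  b <- t$arc_start
  hl <- t$host_len
  w1 <- run_len(function(j) vb(a + j) == hmol(t$mh1 + j)) +
    run_len(function(j) vb(a - j + 1L) == hmol(t$mh1 - j + 1L))
  w2 <- run_len(function(j) vb(b + t$mh2 - 1L + j) == hmol(hl + j)) +
    run_len(function(j) vb(b + t$mh2 - j) == hmol(hl - j + 1L))
  c(w1, w2)
}

#' Persist all stage outputs of a run
#'
#' Writes references and reconstructed circles as FASTA, the junction tables
#' as TSV and BED, scaffolds as FASTA with depth in the description, the
#' feature records as TSV, and a JSON manifest with per-file MD5 checksums
#' and the stage counts.  Re-running the same seed and configuration yields
#' byte-identical outputs.
#'
#' @param run a `minicircle_run`.
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest list.
#' @export
write_run_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_ref_fasta(run$refs, p("references.fasta"))
  write_store_tsv(run$junctions_all, p("junctions_all.tsv"))
  write_store_tsv(run$junctions, p("junctions_selected.tsv"))
  write_store_tsv(junctions_to_bed(run$junctions), p("junctions.bed"))
  if (nrow(run$scaffolds)) {
    scf <- Biostrings::DNAStringSet(setNames(
      run$scaffolds$seq,
      sprintf("%s depth=%.1f reads=%d", run$scaffolds$id,
              run$scaffolds$mean_depth, run$scaffolds$n_reads)))
    Biostrings::writeXStringSet(scf, p("scaffolds.fasta"))
  }
  if (length(run$candidates)) {
    circ <- Biostrings::DNAStringSet(setNames(
      vapply(run$candidates, `[[`, character(1), "seq"),
      run$records$id))
    Biostrings::writeXStringSet(circ, p("circles.fasta"))
  }
  write_store_tsv(run$records, p("minicircle_records.tsv"))
  files <- list.files(dir, full.names = TRUE)
  manifest <- list(
    seed = run$seed,
    counts = as.list(run$counts),
    checksums = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' @export
print.minicircle_run <- function(x, ...) {
  cat("<minicircle_run>\n")
  cat(sprintf("  read pairs: %d in, %d surviving (%.1f%%)\n",
              x$counts$pairs_in, x$counts$pairs_surviving,
              100 * x$counts$fraction_surviving))
  cat(sprintf("  junctions: %d called, %d selected\n",
              x$counts$junctions_called, x$counts$junctions_selected))
  cat(sprintf("  scaffolds: %d (%d hybrid, %d defective)\n",
              x$counts$scaffolds, x$counts$hybrids, x$counts$defectives))
  cat(sprintf("  reconstructed circles: %d\n", x$counts$circles))
  if (nrow(x$records)) {
    print(x$records[, c("id", "total_length", "viral_length",
                        "viral_percent", "host_length", "host_locus")])
  }
  invisible(x)
}

#' Tidy the minicircle records of a run
#'
#' @param x a `minicircle_run`.
#' @param ... unused.
#' @return the feature-record tibble, one row per reconstructed circle.
#' @export
tidy.minicircle_run <- function(x, ...) x$records

#' One-row summary of a pipeline run
#'
#' @param x a `minicircle_run`.
#' @param ... unused.
#' @return a one-row tibble of stage counts.
#' @export
glance.minicircle_run <- function(x, ...) x$counts
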