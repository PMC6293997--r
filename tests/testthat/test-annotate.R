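pcfg <- pipeline_config()

# reference-exact scaffold construction helpers
v_seq <- function() small_refs()$seq[small_refs()$role == "virus"]
h_seq <- function(id) small_refs()$seq[small_refs()$id == id]

test_that("a virus-host-virus scaffold tiles into ordered blocks", {
  scaffold <- paste0(substr(v_seq(), 1, 500),
                     substr(h_seq("chr1"), 30001, 30800),
                     substr(v_seq(), 2500, 2845))
  ann <- segment_scaffold(list(id = "s1", seq = scaffold), small_refs(),
                          pcfg, small_index())
  expect_equal(ann$blocks$ref, c("virus", "chr1", "virus"))
  expect_equal(ann$n_junctions, 2L)
  expect_equal(ann$class, "hybrid")
  expect_equal(ann$blocks$r_start, c(1L, 30001L, 2500L))
  expect_equal(ann$blocks$r_end, c(500L, 30800L, 2845L))
})

test_that("virus-only and single-junction scaffolds classify correctly", {
  v_only <- substr(v_seq(), 100, 900)
  ann <- segment_scaffold(list(id = "s2", seq = v_only), small_refs(),
                          pcfg, small_index())
  expect_equal(nrow(ann$blocks), 1L)
  expect_equal(ann$n_junctions, 0L)
  expect_equal(ann$class, "defective")

  broken <- paste0(substr(v_seq(), 1, 300),
                   substr(h_seq("chr1"), 30001, 30600))
  ann2 <- segment_scaffold(list(id = "s3", seq = broken), small_refs(),
                           pcfg, small_index())
  expect_equal(ann2$n_junctions, 1L)
  expect_equal(ann2$class, "hybrid")

  host_only <- substr(h_seq("chr2"), 1000, 1900)
  ann3 <- segment_scaffold(list(id = "s4", seq = host_only), small_refs(),
                           pcfg, small_index())
  expect_equal(ann3$class, "host_only")

  empty <- strrep("N", 400)
  ann4 <- segment_scaffold(list(id = "s5", seq = empty), small_refs(),
                           pcfg, small_index())
  expect_equal(ann4$class, "unclassified")
})

test_that("two single-junction partials from one circle merge; others do not", {
  refs <- small_refs()
  # planted circle: virus[2500..2845]+virus[1..300] arc + host 30001..30900
  partA <- paste0(substr(v_seq(), 1, 300),
                  substr(h_seq("chr1"), 30001, 30500))   # virus->host
  partB <- paste0(substr(h_seq("chr1"), 30401, 30900),
                  substr(v_seq(), 2500, 2845))           # host->virus
  annA <- segment_scaffold(list(id = "A", seq = partA), refs, pcfg,
                           small_index())
  annB <- segment_scaffold(list(id = "B", seq = partB), refs, pcfg,
                           small_index())
  mp <- merge_partial_scaffolds(list(annA, annB), refs, pcfg)
  expect_length(mp$merged, 1L)
  cand <- mp$merged[[1]]
  # coordinates may slide within chance microhomology at the junctions
  expect_lte(abs(cand$host_start - 30001L), 2L)
  expect_lte(abs(cand$host_end - 30900L), 2L)
  expect_lte(abs(cand$arc_start - 2500L), 2L)
  expect_lte(abs(cand$arc_end - 300L), 2L)
  # the reconstructed circle is the planted molecule, microhomology slides
  # included: exact length and exact sequence
  planted <- paste0(substr(v_seq(), 1, 300),
                    substr(h_seq("chr1"), 30001, 30900),
                    substr(v_seq(), 2500, 2845))
  expect_equal(cand$length, nchar(planted))
  expect_identical(cand$seq, planted)

  # partials from different host loci do not merge
  partC <- paste0(substr(h_seq("chr2"), 10001, 10500),
                  substr(v_seq(), 2500, 2845))
  annC <- segment_scaffold(list(id = "C", seq = partC), refs, pcfg,
                           small_index())
  mp2 <- merge_partial_scaffolds(list(annA, annC), refs, pcfg)
  expect_length(mp2$merged, 0L)
  expect_length(mp2$unmerged, 2L)
  expect_length(merge_partial_scaffolds(list(), refs, pcfg)$merged, 0L)
})

test_that("an end-overlapping scaffold circularises to the exact circle", {
  circle <- paste0(substr(v_seq(), 1, 287),
                   substr(h_seq("chr1"), 30001, 30700),
                   substr(v_seq(), 2496, 2845))   # 1337-nt planted circle
  expect_equal(nchar(circle), 1337L)
  # scaffold traverses the circle plus a 40-nt end duplication
  scaffold <- paste0(circle, substr(circle, 1, 40))
  ann <- segment_scaffold(list(id = "s1", seq = scaffold), small_refs(),
                          pcfg, small_index())
  cand <- circularize_candidate(ann, small_refs(), pcfg, small_index())
  expect_equal(cand$length, 1337L)
  expect_identical(cand$seq, circle)   # canonical rotation: virus 1 first
  # idempotence: re-annotating the canonical circle keeps it fixed
  ann2 <- segment_scaffold(list(id = "s1b", seq = cand$seq), small_refs(),
                           pcfg, small_index())
  cand2 <- circularize_candidate(ann2, small_refs(), pcfg, small_index())
  expect_lte(abs(cand2$length - 1337L), 1L)
})

test_that("candidates without closure evidence raise a linear error", {
  broken <- paste0(substr(v_seq(), 1, 300),
                   substr(h_seq("chr1"), 30001, 30600))
  ann <- segment_scaffold(list(id = "s3", seq = broken), small_refs(),
                          pcfg, small_index())
  expect_error(circularize_candidate(ann, small_refs(), pcfg, small_index()),
               "linear candidate")
})

test_that("feature arithmetic reproduces published rows and AT extremes", {
  r1 <- minicircle_arithmetic(580, 735, "44.1")
  expect_equal(r1$total_length, 1315L)
  expect_equal(r1$percent_at_printed_precision, 44.1)
  r2 <- minicircle_arithmetic(763, 478, "61.48")
  expect_equal(r2$total_length, 1241L)
  expect_equal(r2$percent_at_printed_precision, 61.48)
  expect_equal(segment_at_percent("ATAT"), 100.0)
  expect_equal(segment_at_percent("GCGC"), 0.0)
})

test_that("a reconstructed hybrid reports additive Table-style features", {
  circle <- paste0(substr(v_seq(), 1, 287),
                   substr(h_seq("chr1"), 30001, 30700),
                   substr(v_seq(), 2496, 2845))
  scaffold <- paste0(circle, substr(circle, 1, 40))
  ann <- segment_scaffold(list(id = "s1", seq = scaffold), small_refs(),
                          pcfg, small_index())
  cand <- circularize_candidate(ann, small_refs(), pcfg, small_index())
  rec <- annotate_features(cand, small_refs(), pcfg)
  expect_equal(rec$viral_length + rec$host_length, rec$total_length)
  expect_equal(rec$total_length, 1337L)
  expect_equal(rec$viral_coords, "1–287 … 2496–2845")
  expect_equal(rec$host_locus, "chr1:30001-30700")
  host_at <- segment_at_percent(substr(h_seq("chr1"), 30001, 30700))
  expect_equal(rec$at_host, host_at)
})

test_that("ORF scanning finds construction ORFs and respects circularity", {
  # ATG + 99 codons + TAA = an ORF of 100 codons (other frames and the
  # reverse strand may carry incidental ORFs; the constructed one must be
  # among the hits)
  withr::with_seed(51, {
    body <- paste(replicate(99, sample(c("GCT", "GAA", "TTT", "CAT"), 1)),
                  collapse = "")
    flank5 <- random_dna(30)
    flank3 <- random_dna(30)
  })
  orf <- paste0("ATG", body, "TAA")
  found <- orf_scan(paste0(flank5, orf, flank3), min_codons = 100)
  hit <- found[found$strand == "+" & found$start == 31L, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$codons, 100L)
  expect_equal(hit$end, 30L + nchar(orf))
  # the same ORF split across the origin of a circle is seen only when the
  # scan is wrap-aware
  cut <- 150L
  withr::with_seed(55, spacer <- random_dna(300))
  circ <- paste0(substr(orf, cut + 1L, nchar(orf)), spacer,
                 substr(orf, 1L, cut))
  linear <- orf_scan(circ, circular = FALSE, min_codons = 100)
  wrapped <- orf_scan(circ, circular = TRUE, min_codons = 100)
  has_100 <- function(x) any(x$strand == "+" & x$codons == 100L)
  expect_false(has_100(linear))
  expect_true(has_100(wrapped))
})

test_that("random AT-rich sequence is overwhelmingly ORF-free", {
  empty <- 0L
  withr::with_seed(52, {
    for (i in 1:100) {
      s <- random_dna(900, at = 0.7)
      if (nrow(orf_scan(s, min_codons = 100)) == 0L) empty <- empty + 1L
    }
  })
  expect_gte(empty, 95L)
})

test_that("in-silico digestion cuts circles correctly", {
  v <- small_virus()
  d <- digest_circular(v$seq, "GAATTC")
  expect_false(d$uncut)
  expect_equal(d$fragments, 2845L)
  # two sites 400 nt apart on a 1500-nt circle
  circle <- random_dna(1500, at = 0.5)
  circle <- gsub("GAATTC", "GAATTA", circle, fixed = TRUE)
  substr(circle, 100, 105) <- "GAATTC"
  substr(circle, 500, 505) <- "GAATTC"
  d2 <- digest_circular(circle, "GAATTC")
  expect_setequal(d2$fragments, c(400L, 1100L))
  expect_equal(sum(d2$fragments), 1500L)
  # no site: uncut marker
  d3 <- digest_circular(gsub("GAATTC", "GAATTA", circle, fixed = TRUE),
                        "GAATTC")
  expect_true(d3$uncut)
})

test_that("digest fragment lengths always sum to the circle length", {
  withr::with_seed(53, {
    for (i in 1:25) {
      circle <- random_dna(sample(800:3000, 1), at = runif(1, 0.4, 0.7))
      d <- digest_circular(circle, "GAATTC")
      if (!d$uncut) expect_equal(sum(d$fragments), nchar(circle))
    }
  })
})

test_that("inverse PCR walks the circle between convergent primers", {
  circle <- withr::with_seed(54, random_dna(1400, at = 0.6))
  fwd <- substr(circle, 901, 920)
  rev <- revcomp(substr(circle, 301, 320))
  prod <- inverse_pcr(circle, fwd, rev, circular = TRUE)
  expect_equal(nrow(prod), 1L)
  # product: from 901 around the origin to 320
  expect_equal(prod$length, arc_len(901L, 320L, 1400L))
  expect_identical(prod$seq, subseq_circular(circle, 901, 320))
  expect_false(prod$ambiguous)
  # same outward-facing primers on the linearised molecule: no product
  expect_equal(nrow(inverse_pcr(circle, fwd, rev, circular = FALSE)), 0L)
  # absent primer: no product
  expect_equal(nrow(inverse_pcr(circle, strrep("ACGT", 5), rev)), 0L)
  expect_error(inverse_pcr(circle, "ACGTACGTAC", rev), "15")
})

test_that("inverse PCR on a planted hybrid spans both junctions", {
  circle <- paste0(substr(v_seq(), 1, 287),
                   substr(h_seq("chr1"), 30001, 30700),
                   substr(v_seq(), 2496, 2845))
  # outward-facing primers inside the host block
  host_at <- 288L
  fwd <- substr(circle, host_at + 500L, host_at + 519L)
  rev <- revcomp(substr(circle, host_at + 100L, host_at + 119L))
  prod <- inverse_pcr(circle, fwd, rev, circular = TRUE)
  expect_equal(nrow(prod), 1L)
  gap <- (host_at + 500L) - (host_at + 119L) - 1L
  expect_equal(prod$length, nchar(circle) - gap)
  # the amplicon contains both virus/host junction points
  expect_true(grepl(substr(circle, 280, 295), prod$seq, fixed = TRUE))
})

test_that("copy number estimation recovers identity and degenerate cases", {
  sm <- small_mapped()
  region <- list(ref = "chr1", start = 1000L, end = 1999L)
  expect_equal(estimate_copy_number(sm$store, region, region), 1.0)
  bare <- list(ref = "chr2", start = 1L, end = 300L)
  expect_error(estimate_copy_number(sm$store, list(ref = "chr1", start = 1L,
                                                   end = 100L), region))
  t <- sm$template
  tpl_region <- list(ref = t$host_ref, start = t$host_start,
                     end = t$host_end)
  cn <- estimate_copy_number(sm$store, tpl_region, region)
  expect_gt(cn, 5)
})
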