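pcfg <- pipeline_config()

test_that("read recovery window arithmetic matches the interval oracle", {
  refs <- small_refs()
  hseq <- refs$seq[refs$id == "chr1"]
  # reads at 46000 (4 kb away) and at 38000 (7 kb away, i.e. 8 kb from the
  # downstream side of a junction at 50000 is not possible on a 50-kb
  # chromosome, so use 41500 = 8.5 kb)
  pairs <- tibble::tibble(
    id = c("near", "far"),
    seq1 = c(substr(hseq, 46000, 46075), substr(hseq, 41000, 41075)),
    qual1 = intToUtf8(rep(68L, 76)),
    seq2 = c(substr(hseq, 46300, 46375), substr(hseq, 41300, 41375)),
    qual2 = intToUtf8(rep(68L, 76))
  )
  store <- map_pairs(small_index(), pairs, pcfg)
  junction <- tibble::tibble(
    ref_a = "virus", pos_a = 100L, dir_a = "L",
    ref_b = "chr1", pos_b = 50000L, dir_b = "R",
    support = 20L, microhomology = 0L, jtype = "virus-host"
  )
  # centred +/- 5 kb: only the read within 5 kb is recovered
  rec <- recover_reads(store, junction, pcfg, sides = "host")
  expect_identical(rec$id, "near")
  # "10 kb each side" toggle recovers the farther read too
  cfg2 <- pipeline_config(recovery_mode = "each_side")
  rec2 <- recover_reads(store, junction, cfg2, sides = "host")
  expect_setequal(rec2$id, c("near", "far"))
})

test_that("the unaligned mate of a recovered read is present in the output", {
  refs <- small_refs()
  hseq <- refs$seq[refs$id == "chr1"]
  pairs <- tibble::tibble(
    id = "halfmapped",
    seq1 = substr(hseq, 46000, 46075),
    qual1 = intToUtf8(rep(68L, 76)),
    seq2 = strrep("N", 76),           # unmappable mate
    qual2 = intToUtf8(rep(68L, 76))
  )
  store <- map_pairs(small_index(), pairs, pcfg)
  junction <- tibble::tibble(
    ref_a = "virus", pos_a = 100L, dir_a = "L",
    ref_b = "chr1", pos_b = 46500L, dir_b = "R",
    support = 20L, microhomology = 0L, jtype = "virus-host"
  )
  rec <- recover_reads(store, junction, pcfg, sides = "host")
  expect_equal(nrow(rec), 1L)
  expect_identical(rec$seq2, pairs$seq2)
  expect_equal(nrow(recover_reads(store, junction[0, ], pcfg)), 0L)
})

tile_circle_reads <- function(template, depth = 30L, rl = 76L,
                              error = 0, seed = 1) {
  len <- nchar(template)
  n <- ceiling(len * depth / rl)
  withr::with_seed(seed, {
    starts <- sample.int(len, n, replace = TRUE)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    reads <- vapply(seq_len(n), function(i) {
      r <- subseq_circular(template, starts[i], starts[i] + rl - 1L)
      if (strands[i] == "-") r <- revcomp(r)
      if (error > 0) {
        nerr <- rbinom(1, rl, error)
        if (nerr > 0) {
          for (p in sample.int(rl, nerr)) {
            cur <- substr(r, p, p)
            substr(r, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
          }
        }
      }
      r
    }, character(1))
  })
  tibble::tibble(id = sprintf("t%04d", seq_along(reads)), seq = reads)
}

test_that("error-free reads from a circle assemble into one rotation of it", {
  template <- withr::with_seed(31, random_dna(1500, at = 0.6))
  reads <- tile_circle_reads(template, depth = 30)
  scf <- assemble_reads(reads, pcfg)
  expect_equal(nrow(scf), 1L)
  expect_gte(nchar(scf$seq), 1500L)
  tripled <- strrep(template, 3)  # a full traversal plus end overlap can
  # start anywhere on the circle, so containment needs two extra copies
  expect_true(grepl(scf$seq, tripled, fixed = TRUE) ||
                grepl(revcomp(scf$seq), tripled, fixed = TRUE))
  # circularity evidence: the scaffold ends overlap
  n <- nchar(scf$seq)
  ov <- minicircler:::cpp_best_overlap(substr(scf$seq, n - 400, n),
                                       substr(scf$seq, 1, 400),
                                       pcfg$min_overlap,
                                       pcfg$max_overlap_mm_per)
  expect_gte(ov[1], pcfg$min_overlap)
})

test_that("templates sharing no 31-mer assemble into separate scaffolds", {
  a <- withr::with_seed(32, random_dna(600, at = 0.3))
  b <- withr::with_seed(33, random_dna(600, at = 0.9))
  reads <- dplyr::bind_rows(tile_circle_reads(a, depth = 25, seed = 2),
                            tile_circle_reads(b, depth = 25, seed = 3))
  reads$id <- sprintf("t%04d", seq_len(nrow(reads)))
  scf <- assemble_reads(reads, pcfg)
  expect_equal(nrow(scf), 2L)
  in_template <- function(s, tmpl) {
    grepl(s, strrep(tmpl, 3), fixed = TRUE) ||
      grepl(revcomp(s), strrep(tmpl, 3), fixed = TRUE)
  }
  hits_a <- vapply(scf$seq, in_template, logical(1), tmpl = a)
  hits_b <- vapply(scf$seq, in_template, logical(1), tmpl = b)
  expect_true(all(xor(hits_a, hits_b)))
})

test_that("a single read does not make a scaffold", {
  reads <- tibble::tibble(id = "only", seq = random_dna(76))
  expect_equal(nrow(assemble_reads(reads, pcfg)), 0L)
  expect_equal(nrow(assemble_reads(reads[0, ], pcfg)), 0L)
})

test_that("consensus stays >= 99.9% identical at 1% error and 20x depth", {
  template <- withr::with_seed(34, random_dna(900, at = 0.6))
  reads <- tile_circle_reads(template, depth = 25, error = 0.01, seed = 4)
  scf <- assemble_reads(reads, pcfg)
  expect_gte(nrow(scf), 1L)
  # evaluate the consensus interior: scaffold ends are single-coverage
  # overhangs where majority voting cannot apply
  whole <- scf$seq[1]
  big <- substr(whole, 77, nchar(whole) - 76)
  # align the scaffold back to the doubled template by exact seed anchoring
  doubled <- strrep(template, 3)
  ident <- local({
    best <- 0
    for (cand in c(big, revcomp(big))) {
      for (off in seq(1, nchar(cand) - 40, by = 137)) {
        seedk <- substr(cand, off, off + 19)
        at <- regexpr(seedk, doubled, fixed = TRUE)
        if (at > 0) {
          start <- at - off + 1
          if (start >= 1 && start + nchar(cand) - 1 <= nchar(doubled)) {
            ref <- substr(doubled, start, start + nchar(cand) - 1)
            best <- max(best, mean(strsplit(cand, "")[[1]] ==
                                     strsplit(ref, "")[[1]]))
          }
        }
      }
    }
    best
  })
  expect_gte(ident, 0.999)
})

test_that("assembly is deterministic for identical input", {
  template <- withr::with_seed(35, random_dna(800, at = 0.6))
  reads <- tile_circle_reads(template, depth = 20, error = 0.005, seed = 5)
  s1 <- assemble_reads(reads, pcfg)
  s2 <- assemble_reads(reads, pcfg)
  expect_identical(s1, s2)
})
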