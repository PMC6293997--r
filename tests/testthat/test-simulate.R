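test_that("virus genome carries the origin at position 1 and one EcoRI site", {
  cfg <- small_cfg()
  v <- sim_virus_genome(cfg)
  expect_equal(nchar(v$seq), 2845L)
  expect_true(v$is_circular)
  expect_equal(substr(v$seq, 1, 9), "TAATATTAC")
  doubled <- paste0(v$seq, substr(v$seq, 1, 8))
  expect_equal(length(gregexpr("TAATATTAC", doubled, fixed = TRUE)[[1]]), 1L)
  expect_equal(length(gregexpr("GAATTC", doubled, fixed = TRUE)[[1]]), 1L)
})

test_that("tiny virus places the motif at position 1; impossible motif errors", {
  cfg <- simulation_config(seed = 3, virus_length = 30,
                           intergenic_span = c(25L, 5L))
  v <- sim_virus_genome(cfg)
  expect_equal(nchar(v$seq), 30L)
  expect_equal(substr(v$seq, 1, 9), "TAATATTAC")
  bad <- simulation_config(seed = 3, virus_length = 12,
                           intergenic_span = c(11L, 1L))
  expect_error(sim_virus_genome(bad), "invalid config")
  expect_error(simulation_config(seed = 3, virus_length = 10,
                                 intergenic_span = c(9L, 1L)),
               "invalid config")
})

test_that("virus generation is a pure function of the seed", {
  a <- sim_virus_genome(simulation_config(seed = 5))
  b <- sim_virus_genome(simulation_config(seed = 5))
  c <- sim_virus_genome(simulation_config(seed = 6))
  expect_identical(a$seq, b$seq)
  expect_gt(sum(strsplit(a$seq, "")[[1]] != strsplit(c$seq, "")[[1]]), 0L)
})

test_that("host genome has the requested shape and AT-rich windows", {
  cfg <- small_sim_config(host_at_fraction = 0.71)
  h <- sim_host_genome(cfg)
  expect_equal(nrow(h), 2L)
  expect_true(all(nchar(h$seq) == 50000L))
  expect_true(all(!h$is_circular))
  w <- at_windows(h)
  expect_true(all(w$at_percent >= 69 & w$at_percent <= 73))
  h2 <- sim_host_genome(cfg)
  expect_identical(h$seq, h2$seq)
})

test_that("explicit minicircle geometry reproduces interval arithmetic", {
  # viral arc 2435..172 spans 583 nt; with a 735-nt host fragment and no
  # microhomology the template is 1318 nt
  mc <- withr::with_seed(1, sim_minicircle(
    small_virus(), small_host(), small_cfg(),
    viral_arc = c(2435, 172), host_len = 735, mh = c(0, 0)))
  expect_equal(mc$viral_len, 583L)
  expect_equal(mc$host_len, 735L)
  expect_equal(mc$length, 1318L)
  expect_equal(mc$viral_coords, "1–172 … 2435–2845")
})

test_that("random minicircles respect length bounds, composition and origin", {
  cfg <- small_cfg()
  v <- small_virus()
  h <- small_host()
  vseq <- v$seq
  withr::with_seed(99, {
    for (i in 1:100) {
      mc <- sim_minicircle(v, h, cfg, id = paste0("m", i))
      expect_gte(mc$length, 1241L)
      expect_lte(mc$length, 1572L)
      expect_gte(mc$host_len, 735L)
      expect_lte(mc$host_len, 1058L)
      # composition: length = viral + host - total microhomology
      expect_equal(mc$length, mc$viral_len + mc$host_len - mc$mh1 - mc$mh2)
      # the full origin motif is retained
      expect_equal(substr(mc$seq,
                          arc_len(mc$arc_start, 2845L, 2845L) - mc$mh2 + 1L,
                          arc_len(mc$arc_start, 2845L, 2845L) - mc$mh2 + 9L),
                   "TAATATTAC")
      # host fragment really comes from the host reference
      hseq <- h$seq[match(mc$host_ref, h$id)]
      frag <- substr(hseq, mc$host_start, mc$host_end)
      if (mc$host_strand == "-") frag <- revcomp(frag)
      expect_equal(substr(frag, mc$mh1 + 1L, mc$host_len),
                   substr(mc$seq, mc$length - (mc$host_len - mc$mh1) + 1L,
                          mc$length))
    }
  })
})

test_that("defective templates are virus-only with correct arithmetic", {
  v <- small_virus()
  cfg <- small_cfg()
  d <- withr::with_seed(1, sim_defective(v, list(c(1, 500), c(2000, 2845)),
                                         cfg))
  expect_equal(d$length, 1346L)
  expect_equal(d$class, "defective")
  expect_true(is.na(d$host_ref))
  expect_equal(d$junc_tpos[[1]], 500L)
  full <- withr::with_seed(1, sim_defective(v, list(c(1, 2845)), cfg))
  expect_equal(full$length, 2845L)
  expect_length(full$junc_tpos[[1]], 0L)
  expect_error(sim_defective(v, list(c(500, 1500)), cfg), "origin")
})

test_that("library depth tracks copy number and covers the wrap", {
  cfg <- small_sim_config(seed = 21, per_base_error = 0)
  v <- sim_virus_genome(cfg)
  h <- sim_host_genome(cfg)
  refs <- combine_refs(v, h)
  mc <- withr::with_seed(2, sim_minicircle(v, h, cfg, id = "t1"))
  mc$copy_number <- 30
  lib <- sim_read_library(mc, refs, cfg, ensure_junction_support = 0)
  tr <- lib$truth[lib$truth$src == "t1", ]
  # mean per-base depth within 15% of the expected 30x
  depth <- sum(pmin(tr$insert, 2L * cfg$read_length)) / mc$length
  expect_lt(abs(depth - 30) / 30, 0.15)
  # fragments span the position-1 boundary of the circular template
  expect_true(any(tr$frag_start + tr$insert - 1L > mc$length))
})

test_that("error-free reads are exact template substrings", {
  cfg <- small_sim_config(seed = 22, per_base_error = 0,
                          background_depth = 0)
  v <- sim_virus_genome(cfg)
  h <- sim_host_genome(cfg)
  refs <- combine_refs(v, h)
  mc <- withr::with_seed(3, sim_minicircle(v, h, cfg, id = "t1"))
  lib <- sim_read_library(mc, refs, cfg, ensure_junction_support = 0)
  doubled <- paste0(mc$seq, mc$seq)
  ok <- vapply(seq_len(nrow(lib$pairs)), function(i) {
    r1 <- lib$pairs$seq1[i]
    grepl(r1, doubled, fixed = TRUE) ||
      grepl(revcomp(r1), doubled, fixed = TRUE) ||
      lib$truth$insert[i] < cfg$read_length  # adapter read-through
  }, logical(1))
  expect_true(all(ok))
})

test_that("a fixed seed reproduces byte-identical FASTQ", {
  cfg <- small_sim_config(seed = 23)
  v <- sim_virus_genome(cfg)
  h <- sim_host_genome(cfg)
  refs <- combine_refs(v, h)
  mc <- withr::with_seed(4, sim_minicircle(v, h, cfg, id = "t1"))
  f1 <- file.path(tempdir(), "libA")
  f2 <- file.path(tempdir(), "libB")
  write_pairs_fastq(sim_read_library(mc, refs, cfg)$pairs, f1)
  write_pairs_fastq(sim_read_library(mc, refs, cfg)$pairs, f2)
  for (m in c("_R1.fastq.gz", "_R2.fastq.gz")) {
    expect_identical(unname(tools::md5sum(paste0(f1, m))),
                     unname(tools::md5sum(paste0(f2, m))))
  }
})

test_that("empty simulation warns instead of failing", {
  cfg <- small_sim_config(seed = 2, background_depth = 0)
  refs <- small_refs()
  expect_warning(lib <- sim_read_library(NULL, refs, cfg), "empty")
  expect_equal(nrow(lib$pairs), 0L)
})
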