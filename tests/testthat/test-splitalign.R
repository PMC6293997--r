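pcfg <- pipeline_config()

test_that("the seed index answers wrap-aware virus k-mers", {
  refs <- small_refs()
  idx <- small_index()
  vseq <- refs$seq[refs$role == "virus"]
  # k-mer spanning positions 2840..2845/1..9, oracle = doubled linearisation
  kmer <- substr(paste0(vseq, vseq), 2840, 2840 + idx$k - 1L)
  hit <- idx$kmers[list(kmer), on = "kmer", nomatch = NULL]
  expect_true(any(hit$pos == 2840L & idx$refs$role[hit$ref_i] == "virus"))
  # absent k-mer gives no hits
  expect_equal(nrow(idx$kmers[list(strrep("N", idx$k)), on = "kmer",
                              nomatch = NULL]), 0L)
  expect_error(build_seed_index(refs[0, ], pcfg))
})

test_that("an exact host copy maps as one full-identity segment", {
  refs <- small_refs()
  idx <- small_index()
  hseq <- refs$seq[refs$id == "chr1"]
  read <- substr(hseq, 10001, 10076)
  seg <- map_read(idx, read, pcfg)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$ref, "chr1")
  expect_equal(seg$start, 10001L)
  expect_equal(seg$end, 10076L)
  expect_equal(seg$identity, 1.0)
  expect_equal(seg$strand, "+")
})

test_that("a chimeric read splits at the construction breakpoint", {
  refs <- small_refs()
  idx <- small_index()
  vseq <- refs$seq[refs$role == "virus"]
  hseq <- refs$seq[refs$id == "chr2"]
  read <- paste0(substr(vseq, 2800, 2845), substr(hseq, 30001, 30030))
  seg <- map_read(idx, read, pcfg)
  expect_equal(max(seg$seg_id), 2L)
  expect_equal(seg$read_end[seg$ref == "virus"], 46L)
  expect_equal(seg$read_start[seg$ref == "chr2"], 47L)
  expect_equal(seg$start[seg$ref == "virus"], 2800L)
  expect_equal(seg$start[seg$ref == "chr2"], 30001L)
})

test_that("segments never fall below the identity threshold", {
  refs <- small_refs()
  idx <- small_index()
  hseq <- refs$seq[refs$id == "chr1"]
  read <- substr(hseq, 20001, 20076)
  # five substitutions spread over the read: full-length identity 0.934
  withr::with_seed(9, {
    for (p in c(8L, 24L, 40L, 56L, 72L)) {
      cur <- substr(read, p, p)
      substr(read, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
    }
  })
  seg <- map_read(idx, read, pcfg)
  # the full-length placement (identity 71/76 = 0.934) must not be reported
  expect_true(all(seg$identity >= pcfg$min_identity))
  expect_true(all(seg$read_end - seg$read_start + 1L < 76L))
})

test_that("reverse-complement mapping mirrors segments and flips strand", {
  refs <- small_refs()
  idx <- small_index()
  vseq <- refs$seq[refs$role == "virus"]
  hseq <- refs$seq[refs$id == "chr2"]
  read <- paste0(substr(vseq, 1000, 1045), substr(hseq, 5001, 5030))
  fwd <- map_read(idx, read, pcfg)
  rev <- map_read(idx, revcomp(read), pcfg)
  expect_equal(nrow(fwd), nrow(rev))
  fwd <- fwd[order(fwd$ref, fwd$start), ]
  rev <- rev[order(rev$ref, rev$start), ]
  expect_equal(fwd$start, rev$start)
  expect_equal(fwd$end, rev$end)
  expect_true(all(fwd$strand != rev$strand))
  expect_equal(fwd$read_start, nchar(read) - rev$read_end + 1L)
})

test_that("stored identities equal recomputation from the references", {
  sm <- small_mapped()
  segs <- sm$store$segments
  refs <- sm$refs
  pairs <- sm$store$pairs
  reads <- setNames(c(pairs$seq1, pairs$seq2),
                    c(paste0(pairs$id, "/1"), paste0(pairs$id, "/2")))
  withr::with_seed(10, idx <- sample(nrow(segs), min(200, nrow(segs))))
  for (i in idx) {
    s <- segs[i, ]
    read <- reads[[paste0(s$read_id, "/", s$mate)]]
    frag <- substr(read, s$read_start, s$read_end)
    if (s$strand == "-") frag <- revcomp(frag)
    ref <- substr(refs$seq[match(s$ref, refs$id)], s$start, s$end)
    ident <- mean(strsplit(frag, "")[[1]] == strsplit(ref, "")[[1]])
    expect_equal(s$identity, ident, tolerance = 1e-9)
  }
})

test_that("alignments stay inside canonical virus coordinates", {
  sm <- small_mapped()
  segs <- sm$store$segments
  vlen <- nchar(sm$refs$seq[sm$refs$role == "virus"])
  vsegs <- segs[segs$ref == "virus", ]
  expect_true(all(vsegs$start >= 1L & vsegs$end <= vlen))
  expect_true(any(vsegs$wrap_join))  # wrap alignments are split at origin
})

test_that("nearly all split-capable reads produce split alignments", {
  sm <- small_mapped()
  cfg <- sm$cfg
  t <- sm$template
  tr <- sm$lib$truth
  rl <- cfg$read_length
  arm <- pcfg$min_split_segment
  q <- t$length - (t$host_len - t$mh1)  # virus-to-host boundary
  tr <- tr[tr$src == "t1", ]
  spans <- function(st) {
    off <- (q - st) %% t$length
    off >= arm - 1L & off <= rl - arm - 1L
  }
  r1 <- ifelse(tr$strand == "+", tr$frag_start,
               canonical_pos(tr$frag_start + tr$insert - rl, t$length))
  capable <- tr$id[spans(r1)]
  split_ids <- unique(store_split_reads(sm$store)$read_id)
  found <- mean(capable %in% split_ids)
  expect_gte(found, 0.95)
})

test_that("the alignment store round-trips through TSV", {
  sm <- small_mapped()
  path <- file.path(tempdir(), "store.tsv")
  write_store_tsv(sm$store$segments, path)
  back <- read_store_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(sm$store$segments))
})

test_that("an empty read stream maps to an empty store", {
  store <- map_pairs(small_index(), small_mapped()$store$pairs[0, ], pcfg)
  expect_equal(nrow(store$segments), 0L)
})
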