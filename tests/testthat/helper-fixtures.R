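# Shared fixtures, built in code and memoised per test session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# small study: full-size virus, 2 x 50-kb host chromosomes
small_sim_config <- function(seed = 7, ...) {
  simulation_config(seed = seed, n_host_chrom = 2,
                    host_chrom_length = 50000, ...)
}

small_refs <- function() {
  memo("small_refs", {
    cfg <- small_sim_config()
    combine_refs(sim_virus_genome(cfg), sim_host_genome(cfg))
  })
}

small_cfg <- function() small_sim_config()

small_virus <- function() small_refs()[small_refs()$role == "virus", ]
small_host <- function() {
  refs <- small_refs()
  h <- refs[refs$role == "host", ]
  attr(h, "windows") <- attr(refs, "windows")
  h
}

small_index <- function() {
  memo("small_index", build_seed_index(small_refs(), pipeline_config()))
}

# one planted minicircle plus its mapped library (used by several files)
small_mapped <- function() {
  memo("small_mapped", {
    cfg <- small_cfg()
    refs <- small_refs()
    mc <- withr::with_seed(1, sim_minicircle(small_virus(), small_host(),
                                             cfg, id = "t1"))
    lib <- sim_read_library(mc, refs, cfg)
    pcfg <- pipeline_config()
    pairs <- filter_pairs(trim_pairs(lib$pairs, pcfg,
                                     adapter = cfg$adapter_seq), pcfg)
    store <- map_pairs(small_index(), pairs, pcfg)
    list(cfg = cfg, refs = refs, template = mc, lib = lib, store = store,
         junctions = call_junctions(store, refs, pcfg))
  })
}

# a small but complete pipeline run: 2 hybrids + 1 defective on 2 x 50 kb
small_run <- function() {
  memo("small_run", {
    cfg <- small_sim_config(seed = 11, n_hybrids = 2, n_defectives = 1,
                            helper_copy_number = 40,
                            copy_number_range = c(20, 80))
    run_pipeline(sim_cfg = cfg)
  })
}

random_quality_string <- function(n, lo = 2, hi = 40) {
  intToUtf8(sample(seq(lo, hi), n, replace = TRUE) + 33L)
}

# independent brute-force implementation of the two-sided window trim
oracle_trim_interval <- function(q, w = 4L, min_q = 15) {
  n <- length(q)
  from <- NA_integer_
  for (i in seq_len(n)) {
    if (mean(q[i:min(i + w - 1L, n)]) >= min_q) {
      from <- i
      break
    }
  }
  if (is.na(from)) return(c(1L, 0L))
  to <- NA_integer_
  for (j in rev(seq_len(n))) {
    if (mean(q[max(1L, j - w + 1L):j]) >= min_q) {
      to <- j
      break
    }
  }
  c(from, to)
}
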