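.datatable.aware <- TRUE

# data.table non-standard evaluation columns
utils::globalVariables(c(
  ".", ".N", ".SD", "kmer", "pos", "diag", "nhits", "off", "ridx", "ref_i",
  "rank", "n", "uid", "orient", "qpos", "cl"
))
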