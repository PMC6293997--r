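#' Simulation configuration
#'
#' Collects every numeric parameter of the synthetic sequencing design in one
#' validated list.  Defaults emulate the study conditions of a geminivirus
#' infection sequencing experiment: a circular 2845-nt virus whose replication
#' origin (nonanucleotide `TAATATTAC`) sits at position 1 by convention, an
#' AT-rich host genome, hybrid minicircles of 1241-1572 nt carrying host
#' fragments of 735-1058 nt, and 2 x 76-nt paired-end reads with ~350-nt
#' inserts.
#'
#' @param seed integer seed driving every random sub-stream.
#' @param virus_length length of the circular virus genome (nt).
#' @param origin_motif nonanucleotide marking the rolling-circle replication
#'   origin, placed at position 1 of the virus coordinate frame.
#' @param intergenic_span two integers `c(right_start, left_end)`: the viral
#'   arc `[right_start..virus_length] + [1..left_end]` through the origin that
#'   every simulated minicircle must retain (the conserved intergenic region).
#' @param n_host_chrom,host_chrom_length number and length (nt) of linear host
#'   chromosomes.
#' @param host_at_fraction target A+T fraction of the catalogued AT-rich
#'   intergenic windows minicircle host fragments are drawn from.
#' @param host_background_at A+T fraction of bulk host chromatin.
#' @param minicircle_total_bounds,host_fragment_bounds inclusive length bounds
#'   (nt) for whole minicircles and their host-derived fragments.
#' @param read_length read length (nt) of each mate.
#' @param insert_mean,insert_sd insert-size distribution (nt).
#' @param per_base_error substitution error rate per sequenced base, in
#'   `[0, 0.2]`.
#' @param adapter_seq 3' adapter that appears by read-through when a fragment
#'   is shorter than the read.
#' @param quality_q constant Phred quality written to simulated reads (the
#'   error process is independent of the printed quality).
#' @param background_depth fold-coverage of whole-genome background fragments.
#' @param template_depth per-copy depth multiplier; a template with copy
#'   number c is sequenced at `background_depth * template_depth * c` fold.
#' @param copy_number_range log-uniform sampling range for per-template copy
#'   number relative to 1x chromosomal background.
#' @param microhomology_range inclusive integer range of planted junction
#'   microhomology (nt).
#' @param n_hybrids,n_defectives template counts for [sim_study()].
#' @param helper_copy_number copy number of the intact helper virus circle in
#'   [sim_study()].
#' @param min_junction_reads guaranteed number of junction-spanning fragments
#'   per planted junction (the planted read support).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              virus_length = 2845L,
                              origin_motif = "TAATATTAC",
                              intergenic_span = c(2637L, 102L),
                              n_host_chrom = 5L,
                              host_chrom_length = 200000L,
                              host_at_fraction = 0.71,
                              host_background_at = 0.64,
                              minicircle_total_bounds = c(1241L, 1572L),
                              host_fragment_bounds = c(735L, 1058L),
                              read_length = 76L,
                              insert_mean = 350,
                              insert_sd = 35,
                              per_base_error = 0.001,
                              adapter_seq = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                              quality_q = 35L,
                              background_depth = 1,
                              template_depth = 1,
                              copy_number_range = c(10, 500),
                              microhomology_range = c(0L, 3L),
                              n_hybrids = 8L,
                              n_defectives = 2L,
                              helper_copy_number = 150,
                              min_junction_reads = 12L) {
  cfg <- list(
    seed = as.integer(seed), virus_length = as.integer(virus_length),
    origin_motif = toupper(origin_motif),
    intergenic_span = as.integer(intergenic_span),
    n_host_chrom = as.integer(n_host_chrom),
    host_chrom_length = as.integer(host_chrom_length),
    host_at_fraction = host_at_fraction,
    host_background_at = host_background_at,
    minicircle_total_bounds = as.integer(minicircle_total_bounds),
    host_fragment_bounds = as.integer(host_fragment_bounds),
    read_length = as.integer(read_length),
    insert_mean = insert_mean, insert_sd = insert_sd,
    per_base_error = per_base_error, adapter_seq = toupper(adapter_seq),
    quality_q = as.integer(quality_q),
    background_depth = background_depth, template_depth = template_depth,
    copy_number_range = copy_number_range,
    microhomology_range = as.integer(microhomology_range),
    n_hybrids = as.integer(n_hybrids),
    n_defectives = as.integer(n_defectives),
    helper_copy_number = helper_copy_number,
    min_junction_reads = as.integer(min_junction_reads)
  )
  class(cfg) <- c("simulation_config", "list")
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  stopifnot(
    cfg$virus_length >= 1L,
    cfg$n_host_chrom >= 1L, cfg$host_chrom_length >= 1L,
    cfg$host_at_fraction > 0, cfg$host_at_fraction < 1,
    cfg$read_length >= 1L, cfg$insert_mean > 0,
    cfg$per_base_error >= 0, cfg$per_base_error <= 0.2,
    diff(cfg$minicircle_total_bounds) >= 0,
    diff(cfg$host_fragment_bounds) >= 0,
    cfg$background_depth >= 0, cfg$template_depth >= 0
  )
  if (nchar(cfg$origin_motif) > cfg$virus_length) {
    stop("invalid config: origin motif longer than the virus genome",
         call. = FALSE)
  }
  if (nchar(cfg$origin_motif) +
        arc_len(cfg$intergenic_span[1], cfg$intergenic_span[2],
                cfg$virus_length) > cfg$virus_length) {
    stop("invalid config: origin motif plus intergenic span exceed the genome",
         call. = FALSE)
  }
  cfg
}

#' Pipeline configuration
#'
#' Numeric parameters of the detection pipeline.  The defaults are the
#' published analysis settings: sliding-window quality trimming over a 4-nt
#' window at mean Phred >= 15, discarding pairs with a mate shorter than
#' 16 nt, a 95% alignment identity threshold, a minimum junction support of
#' 10 reads, and a 10-kb read-recovery locus around each selected junction.
#'
#' @param trim_window sliding window width (nt) for quality trimming.
#' @param trim_min_q minimum mean Phred quality of a window.
#' @param min_mate_len pairs with a mate shorter than this are discarded (nt).
#' @param min_identity minimum alignment identity (matches / aligned columns).
#' @param min_junction_support minimum distinct-read support for a junction.
#' @param recovery_window size (nt) of the read-recovery locus around a
#'   junction side; interpreted per `recovery_mode`.
#' @param recovery_mode `"centered"`: a `recovery_window` window centred on
#'   each junction side (+/- half); `"each_side"`: `recovery_window` on each
#'   side (double width).
#' @param seed_k exact seed k-mer length of the aligner.
#' @param min_split_segment minimum read-interval length (nt) of a reported
#'   split-alignment segment.
#' @param junction_cluster_tol junctions whose both sides agree within this
#'   tolerance (nt) are merged.
#' @param min_overlap minimum suffix/prefix overlap (nt) for read merging in
#'   assembly and for end-overlap circularisation.
#' @param max_overlap_mm_per one mismatch allowed per this many overlap bases.
#' @param min_scaffold_len scaffolds shorter than this multiple of the read
#'   length are discarded.
#' @param max_group_pairs cap on read pairs entering one targeted assembly
#'   (deeper groups are deterministically subsampled).
#' @param orf_min_codons minimum ORF length in codons (stop excluded).
#' @param ecori_site restriction site used by the in-silico digestion default.
#' @param trim_both_ends if `FALSE`, use single-direction (5'-leading only)
#'   window semantics instead of trimming from both ends.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(trim_window = 4L,
                            trim_min_q = 15,
                            min_mate_len = 16L,
                            min_identity = 0.95,
                            min_junction_support = 10L,
                            recovery_window = 10000L,
                            recovery_mode = c("centered", "each_side"),
                            seed_k = 15L,
                            min_split_segment = 16L,
                            junction_cluster_tol = 5L,
                            min_overlap = 31L,
                            max_overlap_mm_per = 32L,
                            min_scaffold_len = 2,
                            max_group_pairs = 800L,
                            orf_min_codons = 100L,
                            ecori_site = "GAATTC",
                            trim_both_ends = TRUE) {
  cfg <- list(
    trim_window = as.integer(trim_window), trim_min_q = trim_min_q,
    min_mate_len = as.integer(min_mate_len), min_identity = min_identity,
    min_junction_support = as.integer(min_junction_support),
    recovery_window = as.integer(recovery_window),
    recovery_mode = match.arg(recovery_mode),
    seed_k = as.integer(seed_k),
    min_split_segment = as.integer(min_split_segment),
    junction_cluster_tol = as.integer(junction_cluster_tol),
    min_overlap = as.integer(min_overlap),
    max_overlap_mm_per = as.integer(max_overlap_mm_per),
    min_scaffold_len = min_scaffold_len,
    max_group_pairs = as.integer(max_group_pairs),
    orf_min_codons = as.integer(orf_min_codons),
    ecori_site = toupper(ecori_site),
    trim_both_ends = isTRUE(trim_both_ends)
  )
  stopifnot(
    cfg$trim_window >= 1L, cfg$min_mate_len >= 1L,
    cfg$min_identity > 0.5, cfg$min_identity <= 1,
    cfg$min_junction_support >= 1L, cfg$recovery_window >= 1L,
    cfg$seed_k >= 1L, cfg$min_split_segment >= cfg$seed_k,
    cfg$min_overlap >= 1L, cfg$orf_min_codons >= 1L
  )
  class(cfg) <- c("pipeline_config", "list")
  cfg
}
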