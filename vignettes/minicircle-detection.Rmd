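---
title: "Detecting hybrid virus/host minicircles from paired-end reads"
author: "minicircler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hybrid virus/host minicircles from paired-end reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological problem

Geminivirus-infected plants can accumulate small circular DNA molecules —
*minicircles* — that join a fragment of the circular viral genome to a
fragment of host chromosomal DNA. In BCTIV-infected sugar beet these
molecules are roughly half a viral genome in size (1241–1572 nt), always
retain the viral intergenic region with the stem-loop and the origin of
rolling-circle replication (so the helper virus can amplify them in trans),
and carry AT-rich (68–73%), ORF-free host fragments of 735–1058 nt from
apparently random intergenic loci. Virus-only deletion derivatives
("defective DNAs") co-occur and must not be confused with hybrids.

`minicircler` re-implements the discovery analysis as a reusable,
deterministic pipeline: paired-end reads are quality-trimmed, aligned with a
split-read aligner against the combined host+virus reference, virus/host
breakpoint junctions are called and filtered, reads near selected junctions
are recovered together with their mates and assembled, and assembled
scaffolds are classified and reconstructed into circular molecules with a
characterization-table row per circle (lengths, AT%, coordinate string,
host locus, ORF status, read-depth copy number). A synthetic-data generator
emulates the sequencing design of the original experiment so that the whole
pipeline can be validated against a planted truth table.

## The simulator and what it emulates

`sim_study()` generates the default study conditions:

* a circular 2845-nt virus with the nonanucleotide origin `TAATATTAC` at
  position 1 (the conventional start at the stem-loop) and exactly one EcoRI
  site, at ~60% AT;
* five 200-kb host chromosomes at 64% AT, each carrying four catalogued
  2-kb "intergenic" windows rewritten to 71% AT (the windows minicircle
  host fragments are drawn from);
* eight hybrid minicircles: a viral arc through the origin (the arc always
  contains the conserved intergenic span, arc ends sampled within the
  published junction ranges) joined to a host fragment of 735–1058 nt from a
  distinct window on either strand, with 0–3 nt of planted junction
  microhomology per junction and total length confined to 1241–1572 nt;
* two virus-only defective circles and the intact helper virus at high copy
  number as confounders;
* paired-end 2 × 76-nt reads with normally distributed ~350 ± 35-nt inserts,
  wrap-around fragments on circular templates, per-base substitution errors
  (0.1% by default, no indels), constant Q35 qualities (the error process is
  independent of the printed quality, because no instrument quality profile
  is available to emulate), 3′ adapter read-through for short fragments, and
  1× whole-genome background coverage.

Copy numbers are log-uniform on [10, 500] relative to the 1× chromosomal
background, so per-template depth equals
`background_depth * template_depth * copy_number` and the read-depth
copy-number estimator recovers the multiplier directly. Because the study
condition is *planted junctions with at least 10 supporting reads*, the
generator tops up junction-spanning fragments until every planted junction
has at least 12 potential split reads (two of margin over the downstream
filter, covering trimming and mapping losses); without the guarantee a
low-copy template could fall below the support filter by sampling noise and
the run would measure the filter, not the pipeline.

What the simulator deliberately does **not** model: indel sequencing
errors, PCR amplification bias (the emulated protocol is PCR-free),
position- or motif-dependent error rates, chimeric library artefacts, and
host repeat structure. Passing the planted-truth tests therefore shows the
pipeline's logic is correct under the stated error model — not that it is
robust to every artefact of real libraries.

## Pipeline stages and the parameters that matter

All tunables live in `pipeline_config()`; defaults are the published
analysis settings.

* **Trimming** (`trim_window = 4`, `trim_min_q = 15`): after adapter
  removal, bases are cut inward from each end until the first 4-nt window
  with mean Phred ≥ 15; windows truncated at the read end use the mean of
  the remaining bases, so 1–3 terminal bases can still be trimmed. A config
  toggle (`trim_both_ends = FALSE`) gives single-direction semantics.
  Pairs with a mate shorter than `min_mate_len = 16` nt are discarded.
* **Split alignment** (`seed_k = 15`, `min_identity = 0.95`,
  `min_split_segment = 16`): exact 15-mer seeds over the forward strand of
  every reference (the circular virus is virtually extended so origin-
  spanning k-mers are indexed), candidate diagonals evaluated by ungapped
  extension scored like an aligner (match +1, mismatch −3) under the 95%
  identity floor — the penalty stops segments at divergence boundaries
  instead of padding them with chance matches up to the identity budget.
  Identity is matches over aligned columns, applied per segment. A split is
  reported only when no single segment explains `read length −
  min_split_segment + 1` bases; the split pair maximises total matched
  bases, with the read-level overlap (microhomology) trimmed at its
  midpoint. The error model is substitution-only end to end, so the
  aligner is ungapped; divergent indel-rich reads are out of scope.
* **Junction calling** (`junction_cluster_tol = 5`): each split mate
  contributes one breakpoint event per adjacent segment pair; the
  breakpoint is re-derived against the read by sliding the split point and
  maximising matched bases, and the plateau of equally good placements *is*
  the microhomology span. Placements are canonicalised leftmost on the
  virus side; clusters within 5 nt on both sides merge, the modal placement
  representing the cluster (5 nt absorbs placement jitter without merging
  distinct loci). Selection keeps junctions with support ≥ 10 that involve
  the virus; virus–virus junctions are kept and labelled so defectives stay
  separable from hybrids.
* **Recovery and assembly** (`recovery_window = 10000`, centred;
  `min_overlap = 31`, one mismatch per 32 overlap bases): reads whose
  segments overlap a 10-kb window centred on either junction side are
  recovered with their mates ("10 kb around each junction" could also mean
  10 kb *per side*; `recovery_mode = "each_side"` is the explicit toggle).
  Assembly is greedy overlap–layout–consensus with exact k-mer seeded
  overlap detection, longest-overlap-first extension (ties to the smallest
  read id), per-column majority consensus, and a 2 × read-length floor —
  recovered read sets are tiny, so a desk-scale assembler whose contracts
  are checked by oracle properties replaces a production assembler.
* **Classification and reconstruction**: scaffolds are tiled by
  maximal-scoring chains of reference blocks; hybrid = virus and host
  blocks, defective = virus-only below full genome length. Circles close
  by scaffold end-overlap when the assembly traversed the whole molecule,
  otherwise from two terminal junctions: the circle is the annotated host
  block plus the viral arc between the two virus-side junction coordinates
  through the origin, both read off the references — the same
  coordinate-string reconstruction used in published minicircle tables.
  Reported records keep `viral + host = total` exact by construction.

### Why assembly is grouped per host locus

Every minicircle shares the near-origin viral arc with every other
replicon and with the helper virus, so pooled overlap assembly of all
recovered reads cannot separate templates: the shared arc is a repeat
longer than both the read and the insert. `run_pipeline()` therefore
clusters selected virus–host junctions by host locus (single linkage,
20 kb) and assembles each group from host-side recovery windows only —
the unique host flank anchors each assembly, and the viral arc is
restored from the junction coordinates during circularisation.
Virus–virus junction groups use the published both-side windows.
Groups deeper than `max_group_pairs = 800` pairs are deterministically
subsampled; ~75× is ample for a 76-nt greedy assembler and keeps deep
(high-copy) loci from dominating run time. Two single-junction partial
scaffolds from the same locus (broken assemblies at low copy number) are
merged when their junction-free host ends approach each other on the same
chromosome and strand, with reference gap fill.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive throughout (the R/Bioconductor
  convention, matching published coordinate strings); wrap-aware on the
  circular virus, and alignments never report coordinates beyond the virus
  length — origin-crossing alignments are split into canonical intervals.
* Ties break deterministically everywhere: lexicographically smallest
  reference id then smallest coordinate for equal alignments, smallest
  read-id pair for equal overlaps; every random stage derives independent
  sub-stream seeds from the one global seed, so reruns are byte-identical.
* `viral_percent` is stored at full precision; comparisons against printed
  tables round half-away-from-zero at the printed decimal count
  (`minicircle_arithmetic()`).
* `orf_min_codons = 100` for the ORF-freedom flag: the source analysis
  asserts absence of ORFs without stating a threshold; 100 codons is the
  classical annotation cutoff and it is configurable and reported.
* Degenerate inputs: empty read streams map to empty stores; junction
  calling on a store without splits returns an empty table; an empty
  template list with zero background warns and returns an empty library;
  candidates without closure evidence raise a "linear candidate" error and
  are retained as incomplete; a zero-depth copy-number control yields `NA`
  ("not detected").

## Known limitations

* The aligner is ungapped and substitution-only; reads with indels or
  >5% divergence from the reference are not recovered.
* Published "accuracy" thresholds are interpreted per alignment segment;
  a read-level interpretation would be slightly stricter for split reads.
* The greedy assembler resolves no repeats beyond the host-locus grouping;
  templates sharing long host-side repeats would collapse.
* Inverse PCR prediction uses exact primer matching only (no mismatch
  tolerance, no thermodynamics).
* Problem sizes used in the validation suite — a 2845-nt virus, five 200-kb
  chromosomes, ~13k read pairs — are the package's test design for a
  complete, deterministic study in minutes on one core; they emulate the
  *structure*, not the volume, of a real sequencing run.

## A worked run

```{r, eval = FALSE}
library(minicircler)

run <- run_pipeline(sim_cfg = simulation_config(seed = 1))
run
tidy(run)              # one characterization row per reconstructed circle
compare_to_truth(run)$summary
plot_composition(run)
```

The acceptance script at `scripts/acceptance.R` re-runs exactly this study
from scratch and records the recovery statistics alongside the published
feature-table arithmetic.
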