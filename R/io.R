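#' Read and write pipeline files
#'
#' Thin wrappers around Biostrings for the standard formats used by the
#' pipeline: FASTA for references, templates and scaffolds; Phred+33 FASTQ
#' (optionally gzipped) for read pairs; TSV for the tabular stores.
#'
#' @param refs reference tibble (`id`, `seq`, `role`, `is_circular`).
#' @param path output/input file path.
#' @name io
NULL

#' @rdname io
#' @export
write_ref_fasta <- function(refs, path) {
  x <- Biostrings::DNAStringSet(setNames(refs$seq, refs$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname io
#' @param virus_id id of the (circular) virus sequence; defaults to the one
#'   record whose id contains "virus".
#' @export
read_ref_fasta <- function(path, virus_id = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (is.null(virus_id)) {
    hit <- grep("virus", ids, ignore.case = TRUE)
    if (length(hit) != 1L) {
      stop("cannot infer the virus record; pass virus_id", call. = FALSE)
    }
    virus_id <- ids[hit]
  }
  tibble::tibble(
    id = ids,
    seq = as.character(x),
    role = ifelse(ids == virus_id, "virus", "host"),
    is_circular = ids == virus_id
  )
}

#' @rdname io
#' @param pairs read-pair tibble (`id`, `seq1`, `qual1`, `seq2`, `qual2`).
#' @param prefix path prefix; mates go to `<prefix>_R1.fastq.gz` and
#'   `<prefix>_R2.fastq.gz`.
#' @export
write_pairs_fastq <- function(pairs, prefix) {
  files <- paste0(prefix, c("_R1.fastq.gz", "_R2.fastq.gz"))
  for (m in 1:2) {
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(pairs[[paste0("seq", m)]], pairs$id)),
      Biostrings::PhredQuality(pairs[[paste0("qual", m)]])
    )
    Biostrings::writeQualityScaledXStringSet(x, files[m], compress = TRUE)
  }
  invisible(files)
}

#' @rdname io
#' @export
read_pairs_fastq <- function(prefix) {
  files <- paste0(prefix, c("_R1.fastq.gz", "_R2.fastq.gz"))
  if (!all(file.exists(files))) {
    files <- paste0(prefix, c("_R1.fastq", "_R2.fastq"))
  }
  r1 <- Biostrings::readQualityScaledDNAStringSet(files[1])
  r2 <- Biostrings::readQualityScaledDNAStringSet(files[2])
  stopifnot(length(r1) == length(r2))
  tibble::tibble(
    id = sub("\\s.*$", "", names(r1)),
    seq1 = as.character(r1), qual1 = as.character(Biostrings::quality(r1)),
    seq2 = as.character(r2), qual2 = as.character(Biostrings::quality(r2))
  )
}

#' @rdname io
#' @param x a data frame to serialise.
#' @export
write_store_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_store_tsv <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE))
}

#' Export scaffold annotations as GFF3
#'
#' Writes the reference blocks of each scaffold annotation (virus/host
#' tiling) as GFF3 features on the scaffold coordinate frame, for genome
#' browsers. Requires the rtracklayer package.
#'
#' @param anns list of `scaffold_annotation` objects.
#' @param path output GFF3 path.
#' @param refs reference tibble (for the block roles).
#' @export
write_annotation_gff3 <- function(anns, path, refs) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required for GFF3 export", call. = FALSE)
  }
  role <- setNames(refs$role, refs$id)
  rows <- dplyr::bind_rows(lapply(anns, function(a) {
    b <- a$blocks
    if (nrow(b) == 0L) return(NULL)
    tibble::tibble(
      seqnames = a$scaffold_id, start = b$s_start, end = b$s_end,
      strand = b$strand, type = paste0(role[b$ref], "_block"),
      ref = b$ref, ref_start = b$r_start, ref_end = b$r_end,
      identity = b$identity
    )
  }))
  if (is.null(rows) || nrow(rows) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = rows$seqnames,
    ranges = IRanges::IRanges(rows$start, rows$end),
    strand = rows$strand
  )
  gr$type <- rows$type
  gr$ref <- rows$ref
  gr$ref_start <- rows$ref_start
  gr$ref_end <- rows$ref_end
  gr$identity <- rows$identity
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
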