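#' Published feature table of BCTIV minicircles
#'
#' The characterization table of hybrid virus/host minicircles recovered
#' from BCTIV-infected sugar beet: three molecules cloned by rolling-circle
#' amplification from field samples, four cloned after experimental
#' infection, and seven assembled from NGS data of one experimentally
#' infected plant.  `viral_percent_printed` is the bracketed percentage as
#' printed (some rows are marked `partial_match` for incomplete or
#' discontinuous alignment and are not arithmetically exact).
#'
#' @return a tibble with one row per minicircle: `clone`, `section`,
#'   `total_length`, `viral_length`, `viral_percent_printed`,
#'   `host_length`, `viral_coords`, `at_viral`, `at_host`, `host_locus`,
#'   `partial_match`.
#' @examples
#' tbl <- minicircle_reference_features()
#' range(tbl$total_length[tbl$section != "field"])
#' @export
minicircle_reference_features <- function() {
  tibble::tribble(
    ~clone, ~section, ~total_length, ~viral_length, ~viral_percent_printed,
    ~host_length, ~viral_coords, ~at_viral, ~at_host, ~host_locus,
    ~partial_match,
    "MC#1", "field", 1315L, 580L, "44.1", 735L,
    "1–172 … 2435–2845", 61.4, 69.8,
    "Beta chr6:9915362-9916096", FALSE,
    "MC#2", "field", 1294L, 416L, "32.0", 878L,
    "1–166 … 2596–2845", 61.3, 71.2,
    "Beta chr7:36583873-36584676", TRUE,
    "MC#3", "field", 1502L, 444L, "29.3", 1058L,
    "1–157 … 2223–2299 … 2637–2845", 59.0, 71.2,
    "Beta chr3:un.sca001:135440-136484", FALSE,
    "MC#4", "rca_experimental", 1337L, 459L, "34.33", 878L,
    "1–135 … 1184–1234 … 2570–2845", 62.3, 73.6,
    "Beta chr6:57105781-57106674", TRUE,
    "MC#5", "rca_experimental", 1504L, 532L, "35.4", 972L,
    "1–267 … 2581–2845", 62.0, 70.6,
    "Beta chr3.sca001:1755016-1755723", TRUE,
    "MC#6", "rca_experimental", 1572L, 574L, "36.5", 998L,
    "1–188 … 2460–2845", 61.5, 68.2,
    "Beta chr5.sca008:17697504-17698497", FALSE,
    "MC#7", "rca_experimental", 1484L, 664L, "44.7", 820L,
    "1–327 … 2509–2845", 61.1, 71.2,
    "Beta chr1.sca002:10250861-10250043", FALSE,
    "scf#1", "ngs_experimental", 1407L, 396L, "28.0", 1011L,
    "1–110 … 2560–2845", 60.36, 71.97,
    "Beta chr4:23770925-23771936", TRUE,
    "scf#2", "ngs_experimental", 1315L, 332L, "25.24", 983L,
    "1–177 … 2560–2845", 60.25, 73.25,
    "Beta chr8:1269745-1270665", TRUE,
    "scf#4", "ngs_experimental", 1336L, 458L, "34.28", 878L,
    "1–135 … 1184–1234 … 2570–2845", 62.3, 73.6,
    "Beta chr6:57105781-57106674", TRUE,
    "scf#5", "ngs_experimental", 1552L, 715L, "46.1", 837L,
    "1–196 … 2327–2845", 59.31, 71.45,
    "Beta chr8:33213612-33212757", TRUE,
    "scf#7", "ngs_experimental", 1393L, 621L, "44.6", 772L,
    "1–329 … 2554–2845", 61.20, 73.06,
    "Beta chr6:470978-471718", TRUE,
    "scf#33", "ngs_experimental", 1241L, 763L, "61.48", 478L,
    "1–108 … 2188–2845", 56.49, 73.44,
    "Beta 0118.sca0038:22639-23116", FALSE,
    "scf#56/59", "ngs_experimental", 1429L, 453L, "31.7", 976L,
    "1–102 … 2495–2845", 59.83, 68.04,
    "Beta chr3:21716285-21716210", FALSE
  )
}

#' Recompute minicircle feature arithmetic from segment lengths
#'
#' From viral and host segment lengths, recomputes the derived columns of a
#' minicircle feature table: total length (additivity: `viral + host`), the
#' viral percentage at full precision, and the percentage rounded
#' half-away-from-zero at the same number of decimals as a printed value.
#'
#' @param viral_length,host_length integer vectors of segment lengths (nt).
#' @param printed_percent optional character vector of printed percentages;
#'   when given, `percent_at_printed_precision` reproduces each value's
#'   decimal count.
#' @return tibble (`viral_length`, `host_length`, `total_length`,
#'   `viral_percent`, `percent_at_printed_precision`).
#' @examples
#' minicircle_arithmetic(580, 735, "44.1")
#' @export
minicircle_arithmetic <- function(viral_length, host_length,
                                  printed_percent = NULL) {
  total <- viral_length + host_length
  pct <- 100 * viral_length / total
  at_printed <- rep(NA_real_, length(total))
  if (!is.null(printed_percent)) {
    digits <- vapply(strsplit(printed_percent, ".", fixed = TRUE),
                     function(p) {
                       if (length(p) == 2L) nchar(p[2]) else 0L
                     }, integer(1))
    at_printed <- round_half_up(pct, digits)
  }
  tibble::tibble(
    viral_length = as.integer(viral_length),
    host_length = as.integer(host_length),
    total_length = as.integer(total),
    viral_percent = pct,
    percent_at_printed_precision = at_printed
  )
}
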