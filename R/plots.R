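#' Plot the distribution of virus-side junction coordinates
#'
#' Junction positions on the circular virus genome with their read support,
#' separating proximal (arc-end, downstream of the origin) and distal
#' (arc-start) junctions of virus-host breakpoints.
#'
#' @param junctions a junction tibble, or a `minicircle_run` (its selected
#'   junctions are used).
#' @return a ggplot object.
#' @export
plot_junction_distribution <- function(junctions) {
  if (inherits(junctions, "minicircle_run")) junctions <- junctions$junctions
  j <- dplyr::filter(junctions, .data$jtype == "virus-host")
  j$side <- ifelse(j$dir_a == "L", "proximal (arc end)", "distal (arc start)")
  ggplot2::ggplot(j, ggplot2::aes(x = .data$pos_a, y = .data$support,
                                  colour = .data$side)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$pos_a, yend = 0)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "virus coordinate (nt)", y = "read support",
                  colour = NULL,
                  title = "Virus/host junction distribution") +
    ggplot2::theme_minimal()
}

#' Plot the viral/host composition of reconstructed minicircles
#'
#' Stacked segment lengths per molecule, the relative contribution of virus
#' and host DNA to each reconstructed circle.
#'
#' @param records a minicircle record tibble, or a `minicircle_run`.
#' @return a ggplot object.
#' @export
plot_composition <- function(records) {
  if (inherits(records, "minicircle_run")) records <- records$records
  long <- tidyr::pivot_longer(
    records[, c("id", "viral_length", "host_length")],
    cols = c("viral_length", "host_length"),
    names_to = "segment", values_to = "length"
  )
  long$segment <- ifelse(long$segment == "viral_length", "virus-derived",
                         "host-derived")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$id, y = .data$length,
                                     fill = .data$segment)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "length (nt)", fill = NULL,
                  title = "Minicircle composition") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot relative copy numbers of reconstructed minicircles
#'
#' Read-depth copy number of each reconstructed circle's host locus relative
#' to the single-copy control, on a log scale.
#'
#' @param records a minicircle record tibble, or a `minicircle_run`.
#' @return a ggplot object.
#' @export
plot_copy_number <- function(records) {
  if (inherits(records, "minicircle_run")) records <- records$records
  ggplot2::ggplot(records, ggplot2::aes(x = .data$id,
                                        y = .data$copy_number_rel)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "copy number (relative to control)",
                  title = "Minicircle copy number") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot method for pipeline runs
#'
#' @param object a `minicircle_run`.
#' @param type one of `"composition"`, `"junctions"`, `"copy_number"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.minicircle_run <- function(object,
                                    type = c("composition", "junctions",
                                             "copy_number"), ...) {
  switch(match.arg(type),
         composition = plot_composition(object),
         junctions = plot_junction_distribution(object),
         copy_number = plot_copy_number(object))
}
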