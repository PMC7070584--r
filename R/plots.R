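# ggplot2 views of the main result types

#' Plot a peptide property panel
#'
#' Net charge against GRAVY, the two axes that separate the classical
#' cationic-amphipathic antimicrobial peptides from anionic/neutral
#' families; point size tracks peptide length and shape marks amidation.
#'
#' @param properties Output of [peptide_properties()].
#' @return A ggplot object.
#' @export
plot_property_panel <- function(properties) {
  properties <- as_tibble(properties)
  ggplot2::ggplot(properties,
                  ggplot2::aes(x = .data$gravy, y = .data$net_charge)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = .data$length,
                                     shape = .data$amidated),
                        alpha = 0.8) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17)) +
    ggplot2::labs(x = "GRAVY (Kyte-Doolittle mean)",
                  y = "Formal net charge at pH 7",
                  size = "Length (aa)", shape = "Amidated") +
    ggplot2::theme_minimal()
}

#' Plot LC-MS peak assignments
#'
#' The observed peak list as a stick spectrum with matched peaks
#' highlighted and labelled by peptide and charge state.
#'
#' @param x An `fsap_ms_match` from [match_peaks()].
#' @param peaks The peak list that was matched (for the unmatched sticks).
#' @return A ggplot object.
#' @export
plot_mass_matches <- function(x, peaks) {
  stopifnot(inherits(x, "fsap_ms_match"))
  peaks <- as_tibble(peaks) |> mutate(peak_id = row_number())
  peaks$matched <- peaks$peak_id %in% x$matches$peak_id
  intensity <- if ("intensity" %in% names(peaks)) peaks$intensity else 1
  peaks$intensity <- intensity
  ggplot2::ggplot(peaks, ggplot2::aes(x = .data$mz, xend = .data$mz,
                                      y = 0, yend = .data$intensity)) +
    ggplot2::geom_segment(ggplot2::aes(colour = .data$matched),
                          linewidth = 0.4) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "m/z", y = "Intensity", colour = "Matched") +
    ggplot2::theme_minimal()
}

#' Plot a family expression summary
#'
#' Horizontal bars of summed TPM per protein family.
#'
#' @param report Output of [aggregate_family_tpm()].
#' @return A ggplot object.
#' @export
plot_family_tpm <- function(report) {
  report <- as_tibble(report)
  ggplot2::ggplot(report,
                  ggplot2::aes(x = .data$sum_tpm,
                               y = stats::reorder(.data$family, .data$sum_tpm))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Summed expression (TPM)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Property-panel view of a pipeline run
#'
#' @param object An `fsap_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fsap_run
#' @export
autoplot.fsap_run <- function(object, ...) {
  plot_property_panel(object$properties)
}
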