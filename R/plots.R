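# Presentation helpers. All statistics are computed elsewhere; these only
# arrange tibbles into the field's conventional displays.

type_palette <- c(
  "C>A" = "#03bcee", "C>G" = "#010101", "C>T" = "#e32926",
  "T>A" = "#cac9c9", "T>C" = "#a1ce63", "T>G" = "#ebc6c4"
)

#' The conventional 96-channel signature bar plot
#'
#' @param catalog Signature catalog tibble (one or more signatures; one
#'   facet row per signature).
#' @return A ggplot object.
#' @export
plot_signature <- function(catalog) {
  d <- catalog |>
    dplyr::mutate(
      type = substitution_type(.data$class),
      context = substr(.data$class, 1, 3),
      class = factor(.data$class, levels = mutation_classes())
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$prob,
                                  fill = .data$type)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::facet_grid(.data$signature ~ .data$type, scales = "free_x",
                        space = "free_x") +
    ggplot2::scale_fill_manual(values = type_palette, guide = "none") +
    ggplot2::scale_x_discrete(labels = function(x) substr(x, 1, 3)) +
    ggplot2::labs(x = "trinucleotide context", y = "proportion of mutations") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 5),
                   panel.spacing.x = ggplot2::unit(1, "pt"))
}

#' Bar plot of a mutation spectrum
#'
#' @param spectrum Tibble from [build_spectrum()] (aggregated over samples).
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum) {
  agg <- aggregate_spectrum(spectrum)
  plot_signature(spectrum_to_signature(agg, name = "observed spectrum"))
}

#' +AT / -AT composition of signatures
#'
#' Shows, per signature, the fraction of mutations converting C/G to A/T
#' and the converse.
#'
#' @param catalog Signature catalog tibble.
#' @return A ggplot object.
#' @export
plot_at_fractions <- function(catalog) {
  d <- at_gain_fraction(catalog) |>
    tidyr::pivot_longer(c("plus_at", "minus_at"), names_to = "direction",
                        values_to = "fraction") |>
    dplyr::mutate(direction = dplyr::recode(.data$direction,
                                            plus_at = "+AT", minus_at = "-AT"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fraction, y = .data$signature,
                                  fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c("+AT" = "#e32926", "-AT" = "#03bcee"),
                               name = NULL) +
    ggplot2::labs(x = "fraction of signature mass", y = NULL) +
    ggplot2::theme_minimal()
}
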