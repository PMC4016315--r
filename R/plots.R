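# Quick ggplot2 views of the main result types.

#' Composition box plot by temperature class
#'
#' Per-residue distribution of species-pooled proportions, split into
#' mesophiles and thermophiles.
#'
#' @param composition Pooled composition tibble
#'   ([pool_composition()] output).
#' @param traits Tibble with `species_id`, `binary_class`.
#' @return A ggplot object.
#' @export
plot_composition <- function(composition, traits) {
  d <- composition %>%
    left_join(traits %>% select("species_id", "binary_class"),
              by = "species_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$residue, y = .data$proportion,
                                  fill = .data$binary_class)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(mesophile = "#4477AA",
                                          thermophile = "#CC3311"),
                               name = NULL) +
    ggplot2::labs(x = NULL, y = "proportion of residues")
}

#' CEF box plot across species
#'
#' Per-residue distribution of species-level Contact Enrichment
#' Factors with the indifference line CEF = 1.
#'
#' @param species_cef Species-level CEF tibble
#'   ([aggregate_cef()] output); undefined cells are dropped.
#' @param traits Optional trait tibble to split by temperature class.
#' @return A ggplot object.
#' @export
plot_cef <- function(species_cef, traits = NULL) {
  d <- species_cef %>% filter(.data$defined)
  p <- if (is.null(traits)) {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$residue, y = .data$cef))
  } else {
    ggplot2::ggplot(
      d %>% left_join(traits %>% select("species_id", "binary_class"),
                      by = "species_id"),
      ggplot2::aes(x = .data$residue, y = .data$cef,
                   fill = .data$binary_class)
    ) +
      ggplot2::scale_fill_manual(values = c(mesophile = "#4477AA",
                                            thermophile = "#CC3311"),
                                 name = NULL)
  }
  p +
    ggplot2::geom_boxplot(outlier.size = 0.4, linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "Contact Enrichment Factor")
}
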