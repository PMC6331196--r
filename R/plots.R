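## ggplot2 display methods --------------------------------------------------

#' @importFrom ggplot2 autoplot ggplot aes geom_col labs facet_wrap
#'   scale_y_continuous position_fill theme_minimal
#' @export
ggplot2::autoplot

#' Plot a SNP sharing spectrum
#'
#' Bar chart of SNP counts by the number of spores sharing the alternate
#' allele; clean Mendelian data peaks at k = 4.
#'
#' @param object A `zt_spectrum` from [sharing_spectrum()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot zt_spectrum
#' @export
autoplot.zt_spectrum <- function(object, ...) {
  fm <- attr(object, "filter_mode") %||% "none"
  ggplot(tibble::as_tibble(object), aes(x = factor(.data$k), y = .data$n_snps)) +
    geom_col(fill = "grey30") +
    labs(x = "spores sharing the SNP (k of 8)", y = "SNPs",
         title = "SNP octad-sharing spectrum",
         subtitle = paste0("coverage filter: ", fm)) +
    theme_minimal()
}

#' Plot chromosome transmission conditioned on mitochondrial genotype
#'
#' Stacked relative frequencies of presence/absence of a chromosome by
#' mitochondrial haplotype, the octad analogue of the mito-conditioned
#' transmission panels.
#'
#' @param object A `zt_transmission` from [transmission_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot zt_transmission
#' @export
autoplot.zt_transmission <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("present", "absent"),
                              names_to = "state", values_to = "count")
  ggplot(long, aes(x = .data$mito_genotype, y = .data$count,
                   fill = .data$state)) +
    geom_col(position = "fill") +
    labs(x = "mitochondrial genotype", y = "relative frequency",
         fill = NULL,
         title = paste("Transmission of", object$chromosome[1])) +
    theme_minimal()
}

#' Plot a predicted carrier-count distribution
#'
#' @param object A `zt_prediction` from [predict_patterns()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot zt_prediction
#' @export
autoplot.zt_prediction <- function(object, ...) {
  ggplot(tibble::as_tibble(object),
         aes(x = factor(.data$carriers), y = .data$probability)) +
    geom_col(fill = "steelblue") +
    labs(x = "carrier spores per octad", y = "probability",
         title = paste0(attr(object, "mechanism"), ", ",
                        attr(object, "context"))) +
    theme_minimal()
}

#' Plot segregation-label counts by pairing context
#'
#' @param records Segregation records from [classify_octads()].
#' @return A ggplot object.
#' @export
plot_segregation <- function(records) {
  counts <- dplyr::count(records, .data$pairing_status, .data$label)
  ggplot(counts, aes(x = .data$label, y = .data$n)) +
    geom_col(fill = "grey30") +
    facet_wrap(~pairing_status, scales = "free_y") +
    labs(x = NULL, y = "instances (ascus x chromosome)",
         title = "Segregation patterns by pairing context") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
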