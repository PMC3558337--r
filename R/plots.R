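# ggplot2 display methods for the tabular result types.

#' @importFrom ggplot2 ggplot aes geom_col geom_segment geom_text labs
#'   facet_wrap theme_minimal scale_fill_brewer coord_flip
NULL

#' Plot a codon-usage table
#'
#' @param object A `mito_codon_usage` from [codon_usage()].
#' @param top Show only the `top` most frequent codons (default all 64).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mito_codon_usage
#' @export
autoplot.mito_codon_usage <- function(object, top = 64, ...) {
  df <- object |>
    arrange(desc(.data$count)) |>
    utils::head(top) |>
    mutate(codon = factor(.data$codon, levels = rev(.data$codon)))
  ggplot(df, aes(x = .data$codon, y = .data$percent, fill = .data$aa)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "% of codons", fill = "AA",
         title = "Codon usage (termination codons excluded)") +
    theme_minimal()
}

#' Plot a (partitioned) composition profile
#'
#' @param object A `mito_composition` from [base_composition()] or
#'   [partitioned_composition()].
#' @param ... Unused.
#' @return A ggplot of stacked base percentages per partition.
#' @method autoplot mito_composition
#' @export
autoplot.mito_composition <- function(object, ...) {
  df <- object |>
    tidyr::pivot_longer(cols = c("A", "C", "T", "G"),
                        names_to = "base", values_to = "percent") |>
    mutate(partition = factor(.data$partition, levels = unique(.data$partition)),
           base = factor(.data$base, levels = c("A", "T", "G", "C")))
  ggplot(df, aes(x = .data$partition, y = .data$percent, fill = .data$base)) +
    geom_col() +
    scale_fill_brewer(palette = "Set2") +
    labs(x = NULL, y = "% of non-N residues",
         title = "Nucleotide composition by partition") +
    theme_minimal()
}

#' Linear gene-map plot of a feature table
#'
#' @param features Feature tibble.
#' @param genome Optional [mito_genome()] for the axis limit.
#' @return A ggplot with one segment per feature, coloured by class.
#' @export
plot_gene_map <- function(features, genome = NULL) {
  features <- validate_features(features)
  L <- if (!is.null(genome)) genome$length else max(features$end)
  df <- mutate(features,
               y = as.integer(factor(.data$class,
                                     levels = c("PCG", "rRNA", "tRNA", "NCR"))))
  ggplot(df) +
    geom_segment(aes(x = .data$start, xend = .data$end,
                     y = .data$y, yend = .data$y, colour = .data$class),
                 linewidth = 4) +
    geom_text(data = filter(df, .data$class %in% c("PCG", "rRNA", "NCR")),
              aes(x = (.data$start + .data$end) / 2, y = .data$y + 0.25,
                  label = .data$gene), size = 2.6) +
    ggplot2::scale_y_continuous(breaks = 1:4,
                                labels = c("PCG", "rRNA", "tRNA", "NCR"),
                                limits = c(0.5, 4.6)) +
    ggplot2::xlim(0, L) +
    labs(x = "position (bp)", y = NULL, colour = NULL,
         title = "Mitochondrial gene map (linearised)") +
    theme_minimal()
}
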