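#' @importFrom ggplot2 ggplot aes geom_point geom_col geom_hline autoplot
#'   labs theme_minimal position_dodge geom_vline facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot log2 noise ratios per cell type
#'
#' Scatter of the cell-level against the sample-level aged/young log2
#' noise ratio, one point per cell type; points above 0 on both axes are
#' types whose transcriptional noise increases with age under both
#' definitions.
#'
#' @param object A `"noise_report"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.noise_report <- function(object, ...) {
  ggplot(object$summary,
         aes(x = .data$log2_ratio_samples, y = .data$log2_ratio_cells,
             label = .data$cell_type)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    labs(x = "log2 noise ratio (sample level)",
         y = "log2 noise ratio (cell level)",
         title = "Aged vs young transcriptional noise") +
    theme_minimal()
}

#' Volcano plot of a differential-expression table
#'
#' @param object A `"de_table"` from [find_degs()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.de_table <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$logFC, y = -log10(pmax(.data$padj, 1e-300)),
                 colour = .data$significant)) +
    geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    labs(x = "log fold change (aged - young)", y = "-log10 adjusted p",
         colour = "significant") +
    theme_minimal()
}

#' Cell-type proportion bars by age group
#'
#' @param props Output of [celltype_proportions()].
#' @return A ggplot.
#' @export
plot_proportions <- function(props) {
  ggplot(props, aes(x = .data$cell_type, y = .data$fraction,
                    fill = .data$age_group)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = "fraction of group", fill = "age group") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Dot plot of classified ligand-receptor interactions
#'
#' @param comparison An `"lr_comparison"` from [compare_groups()].
#' @param classes Classes to show (default: lost and gained interactions).
#' @return A ggplot.
#' @export
plot_lr_classes <- function(comparison,
                            classes = c("young_only", "aged_only", "shared")) {
  df <- comparison$classified |>
    filter(.data$class %in% classes) |>
    tidyr::pivot_longer(c("p_young", "p_aged"), names_to = "group",
                        names_prefix = "p_", values_to = "p")
  ggplot(df, aes(x = paste(.data$sender, .data$receiver, sep = " > "),
                 y = .data$pair_id, size = -log10(.data$p),
                 colour = .data$class)) +
    geom_point() +
    facet_wrap(~group) +
    labs(x = "sender > receiver", y = NULL, size = "-log10 p") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
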