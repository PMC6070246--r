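#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an expression partition
#'
#' Bar chart of the not-expressed / stable / differential split.
#'
#' @param object An `expr_partition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.expr_partition <- function(object, ...) {
  g <- glance(object)
  df <- tibble(
    status = factor(c("not expressed", "stable", "differential"),
                    levels = c("not expressed", "stable", "differential")),
    n = c(g$n_not_expressed, g$n_stable, g$n_differential)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$status, y = .data$n, fill = .data$status)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c("steelblue", "grey60", "darkorange")) +
    ggplot2::labs(x = NULL, y = "features",
                  title = sprintf("%d features", g$n_total)) +
    ggplot2::theme_minimal()
}

#' Plot a category distribution
#'
#' Percentage of lncRNAs per genomic category relative to the closest PCG.
#'
#' @param object A `category_distribution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.category_distribution <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$category, y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% of lncRNAs",
                  title = sprintf("n = %d annotated lncRNAs", attr(object, "n_total"))) +
    ggplot2::theme_minimal()
}

#' Plot a Venn partition as region counts
#'
#' Bar chart of the disjoint region sizes, ordered by the number of
#' comparisons in the region.
#'
#' @param object A `venn_partition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.venn_partition <- function(object, ...) {
  df <- tidy(object) %>%
    mutate(region = factor(.data$region, levels = .data$region))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$n,
                                   fill = factor(.data$n_sets))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "features", fill = "comparisons") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the per-comparison counting chain
#'
#' Grouped bars of DE lncRNAs, annotated lncRNAs and lncRNA-PCG pairs per
#' comparison.
#'
#' @param chain Tibble from [pair_counting_chain()].
#' @return A ggplot object.
#' @export
plot_counting_chain <- function(chain) {
  df <- chain %>%
    tidyr::pivot_longer(c("n_de_lncrnas", "n_annotated", "n_pairs"),
                        names_to = "stage", values_to = "n") %>%
    mutate(stage = factor(.data$stage,
                          levels = c("n_de_lncrnas", "n_annotated", "n_pairs"),
                          labels = c("DE lncRNAs", "annotated", "pairs")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$comparison, y = .data$n,
                                   fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "lncRNAs", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
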