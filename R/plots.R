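# ggplot2 views of the main result types.

#' Plot gene-class enrichment among DE genes
#'
#' Observed DE proportion per gene class with the global expectation as a
#' dashed line (the figure shape used for class enrichment panels).
#'
#' @param object `neorf_enrichment` tibble from [class_enrichment()]
#' @param ... unused
#' @return a ggplot
#' @exportS3Method ggplot2::autoplot
autoplot.neorf_enrichment <- function(object, ...) {
  d <- object %>% mutate(prop = n_de / n_analyzed)
  expected_prop <- sum(d$n_de) / sum(d$n_analyzed)
  ggplot2::ggplot(d, ggplot2::aes(x = gene_class, y = prop)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = expected_prop, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "proportion differentially expressed") +
    ggplot2::theme_minimal()
}

#' Plot |LFC| magnitude of DE genes by gene class
#'
#' @param results per-gene result tibble with `gene_id`, `lfc`, `padj`
#' @param classes tibble with `gene_id`, `gene_class`
#' @param alpha FDR threshold defining the DE set (default 0.05)
#' @return a ggplot
#' @export
plot_lfc_magnitude <- function(results, classes, alpha = 0.05) {
  d <- results %>%
    inner_join(classes, by = "gene_id") %>%
    filter(!is.na(padj), padj <= alpha)
  ggplot2::ggplot(d, ggplot2::aes(x = gene_class, y = abs(lfc))) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = "|log2 fold change|") +
    ggplot2::theme_minimal()
}

#' MA-style plot of a DE fit
#'
#' @param object a `neorf_de` fit
#' @param ... unused
#' @return a ggplot
#' @exportS3Method ggplot2::autoplot
autoplot.neorf_de <- function(object, ...) {
  d <- object$results %>%
    mutate(de = !is.na(padj) & padj <= object$alpha)
  ggplot2::ggplot(d, ggplot2::aes(x = base_mean, y = lfc, colour = de)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "mean of normalized counts",
                  y = "log2 fold change", colour = "DE") +
    ggplot2::theme_minimal()
}
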