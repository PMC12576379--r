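# Relation between neORF expression / differential expression and the
# number of original annotation lines carrying the neORF (frequency
# classes 1-7).

#' Bin neORFs by the number of annotation lines carrying them
#'
#' @param genes gene tibble; neORF rows must carry `line_presence`
#' @return tibble `gene_id`, `lines_present` (popcount of the presence
#'   vector); errors listing ids with missing presence data
#' @export
bin_by_frequency <- function(genes) {
  ne <- genes %>% filter(gene_class == "neORF")
  missing <- ne$gene_id[is.na(ne$line_presence)]
  if (length(missing) > 0L) {
    abort(sprintf("neORFs without line_presence: %s",
                  paste(head(missing, 10), collapse = ", ")))
  }
  tibble(gene_id = ne$gene_id,
         lines_present = popcount_presence(ne$line_presence))
}

#' Frequency-class enrichment of expressed or DE neORFs
#'
#' For each frequency class (1..7 lines), compares the observed number of
#' flagged (expressed or differentially expressed) neORFs to the number
#' expected at the overall flagged proportion, with a 1-df
#' goodness-of-fit chi-square (no continuity correction) and BH
#' adjustment across the classes. Classes with expected counts below 5
#' carry a low-count warning flag rather than being merged; empty classes
#' are absent from the output.
#'
#' @param partition tibble from [bin_by_frequency()]
#' @param flags tibble with `gene_id` and a logical `flag` column (the
#'   first logical column is used)
#' @return `FrequencyClassSummary` tibble: `lines_present`, `n_genes`,
#'   `n_flagged`, `prop`, `n_expected`, `chi2`, `p_value`, `p_adj`,
#'   `direction`, `low_count`
#' @export
frequency_enrichment <- function(partition, flags) {
  flag_col <- names(flags)[vapply(flags, is.logical, TRUE)][1]
  if (is.na(flag_col)) abort("flags needs a logical column")
  x <- partition %>%
    inner_join(flags %>% select(gene_id, flag = all_of(flag_col)),
               by = "gene_id")
  if (nrow(x) < nrow(partition)) {
    abort("flags must be defined for every partitioned neORF")
  }
  p_global <- mean(x$flag)
  out <- x %>%
    group_by(lines_present) %>%
    summarise(n_genes = n(), n_flagged = sum(flag), .groups = "drop") %>%
    mutate(prop = n_flagged / n_genes, n_expected = n_genes * p_global)
  gof <- gof_proportion_test(out$n_flagged, out$n_genes, out$n_expected)
  out %>%
    mutate(chi2 = gof$chi2, p_value = gof$p_value, direction = gof$direction,
           p_adj = bh_adjust(p_value),
           low_count = n_expected < 5 | (n_genes - n_expected) < 5) %>%
    arrange(lines_present)
}

#' Plot frequency-class proportions (expressed / DE neORFs by class)
#'
#' @param summary tibble from [frequency_enrichment()] (or several
#'   row-bound together with an extra `sample_type` column)
#' @return a ggplot
#' @export
plot_frequency_classes <- function(summary) {
  p <- ggplot2::ggplot(summary,
                       ggplot2::aes(x = factor(lines_present), y = prop)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "lines containing the neORF (of 7)",
                  y = "proportion flagged") +
    ggplot2::theme_minimal()
  if ("sample_type" %in% names(summary)) {
    p <- p + ggplot2::facet_wrap(~sample_type)
  }
  p
}
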