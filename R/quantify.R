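# TPM computation, pooled expressed-gene calling and per-class
# expression summaries.

#' Sum neORF member counts into orthogroup rows
#'
#' neORFs in the same orthogroup are highly similar or identical, so
#' expression analyses run per orthogroup: counts of member neORFs are
#' summed. Non-neORF rows pass through unchanged; column sums are
#' conserved exactly.
#'
#' @param counts count tibble (`gene_id` + sample columns)
#' @param mapping tibble with `gene_id`, `orthogroup_id` covering every
#'   neORF row (a gene tibble works)
#' @return count tibble with one row per orthogroup
#' @export
aggregate_orthogroups <- function(counts, mapping) {
  if ("gene_class" %in% names(mapping)) {
    ne <- mapping %>% filter(gene_class == "neORF")
    unmapped <- intersect(ne$gene_id[is.na(ne$orthogroup_id)], counts$gene_id)
    if (length(unmapped) > 0L) {
      abort(sprintf("neORF rows without orthogroup mapping: %s",
                    paste(head(unmapped, 10), collapse = ", ")))
    }
  }
  mapping <- mapping %>%
    filter(!is.na(orthogroup_id)) %>%
    select(gene_id, orthogroup_id)
  is_member <- counts$gene_id %in% mapping$gene_id
  samples <- setdiff(names(counts), "gene_id")
  agg <- counts %>%
    filter(is_member) %>%
    left_join(mapping, by = "gene_id") %>%
    group_by(gene_id = orthogroup_id) %>%
    summarise(across(all_of(samples), sum), .groups = "drop")
  dplyr::bind_rows(counts %>% filter(!is_member), agg)
}

#' Check that every neORF row of a count table has an orthogroup mapping
#' @param counts count tibble
#' @param genes gene tibble (rows with `gene_class == "neORF"` must map)
#' @return invisibly `TRUE`; errors listing unmapped ids otherwise
#' @export
check_orthogroup_mapping <- function(counts, genes) {
  ne <- genes %>% filter(gene_class == "neORF")
  missing <- ne$gene_id[is.na(ne$orthogroup_id)]
  if (length(missing) > 0L) {
    abort(sprintf("neORFs without orthogroup mapping: %s",
                  paste(head(missing, 10), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Pool biological replicates by summing counts
#'
#' Columns are summed within (population, sex, condition) groups; the
#' pooled column name is `population_sex_condition`.
#'
#' @param counts count tibble
#' @param designs design tibble with `sample_id`, `population`, `sex`,
#'   `condition`
#' @return count tibble with one column per sample type
#' @export
pool_replicates <- function(counts, designs) {
  key <- designs %>%
    mutate(sample_type = paste(population,
                               if_else(is.na(sex), "X", sex),
                               condition, sep = "_"))
  long <- counts %>%
    tidyr::pivot_longer(-gene_id, names_to = "sample_id", values_to = "count") %>%
    left_join(key %>% select(sample_id, sample_type), by = "sample_id")
  long %>%
    group_by(gene_id, sample_type) %>%
    summarise(count = sum(count), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = sample_type, values_from = count) %>%
    arrange(match(gene_id, counts$gene_id))
}

#' Compute transcripts per million
#'
#' `TPM_g = 1e6 * (c_g / L_g) / sum_j (c_j / L_j)` per column, with
#' plain annotated lengths (no effective-length correction). An all-zero
#' column yields all-zero TPM with a warning.
#'
#' @param counts count tibble
#' @param lengths tibble with `gene_id`, `cds_length` (a gene tibble
#'   works), or a named numeric vector
#' @return TPM tibble in the layout of `counts`
#' @export
compute_tpm <- function(counts, lengths) {
  if (is.numeric(lengths)) {
    len <- unname(lengths[counts$gene_id])
  } else {
    len <- lengths$cds_length[match(counts$gene_id, lengths$gene_id)]
  }
  if (anyNA(len)) {
    abort(sprintf("missing length for gene(s): %s",
                  paste(head(counts$gene_id[is.na(len)], 5), collapse = ", ")))
  }
  stopifnot(all(len > 0))
  m <- counts_to_matrix(counts)
  rate <- m / len
  tot <- colSums(rate)
  if (any(tot == 0)) {
    warn(sprintf("%d all-zero column(s): TPM set to 0", sum(tot == 0)))
    tot[tot == 0] <- 1
  }
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  matrix_to_counts(tpm)
}

#' Call genes expressed at a TPM threshold
#'
#' A gene is expressed in a sample type when its TPM is at or above the
#' threshold (inclusive; default 0.5 TPM).
#'
#' @param tpm TPM tibble from [compute_tpm()]
#' @param threshold TPM cutoff (default 0.5)
#' @return logical call tibble in the layout of `tpm`; the threshold is
#'   stored in the `threshold` attribute
#' @export
call_expressed <- function(tpm, threshold = 0.5) {
  stopifnot(threshold >= 0)
  m <- counts_to_matrix(tpm) >= threshold
  out <- dplyr::bind_cols(tibble(gene_id = tpm$gene_id), as_tibble(m))
  attr(out, "threshold") <- threshold
  out
}

#' Union expressed calls across sample types
#'
#' A gene counts as expressed for a tissue when it is expressed in at
#' least one of the grouped sample types (logical OR).
#'
#' @param calls call tibble from [call_expressed()]
#' @param grouping named list mapping tissue name -> character vector of
#'   call columns
#' @return tibble with `gene_id` and one logical column per tissue
#' @export
union_expressed <- function(calls, grouping) {
  stopifnot(length(grouping) > 0)
  out <- tibble(gene_id = calls$gene_id)
  for (tissue in names(grouping)) {
    cols <- grouping[[tissue]]
    stopifnot(all(cols %in% names(calls)))
    out[[tissue]] <- Reduce(`|`, lapply(cols, function(cc) calls[[cc]]))
  }
  out
}

#' Per-class expressed-gene summary (publication table shape)
#'
#' Counts expressed genes per gene class and sample type and reports the
#' percentage against class totals. With the full annotation the fixed
#' denominators are 13,986 PC genes, 2,557 ncRNAs and 5,687 neORFs;
#' otherwise the supplied (or observed) class totals are used.
#'
#' @param calls call tibble from [call_expressed()]
#' @param genes gene tibble giving `gene_class` per gene/orthogroup id
#' @param totals optional named vector of class totals for percentages
#' @return tibble: `sample_type`, `gene_class`, `n_expressed`, `total`,
#'   `percent`
#' @export
expression_summary <- function(calls, genes, totals = NULL) {
  cls <- genes %>%
    mutate(gene_id = if_else(gene_class == "neORF" & !is.na(orthogroup_id),
                             orthogroup_id, gene_id)) %>%
    distinct(gene_id, gene_class)
  long <- calls %>%
    tidyr::pivot_longer(-gene_id, names_to = "sample_type",
                        values_to = "expressed") %>%
    left_join(cls, by = "gene_id") %>%
    filter(!is.na(gene_class))
  denom <- if (is.null(totals)) {
    cls %>% count(gene_class, name = "total")
  } else {
    tibble(gene_class = names(totals), total = unname(totals))
  }
  long %>%
    group_by(sample_type, gene_class) %>%
    summarise(n_expressed = sum(expressed), .groups = "drop") %>%
    left_join(denom, by = "gene_class") %>%
    mutate(percent = 100 * n_expressed / total)
}
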