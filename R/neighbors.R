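# Genome placement of neORF orthogroups from tabular nucleotide-search
# hits, and the 1-kb neighboring-gene differential-expression
# association test.

#' Select the best genome placement per orthogroup
#'
#' Hits are filtered to 100% query coverage and e-value <= 0.01; among
#' survivors the maximum-bitscore hit wins, ties broken by lower e-value
#' then lexicographic (chrom, start). Orthogroups without a surviving
#' hit are absent from the result.
#'
#' @param hits tibble from [read_hits()] (`query_id` is the orthogroup)
#' @param coverage_min minimum query coverage (default 1.0)
#' @param evalue_max maximum e-value (default 0.01)
#' @return `Placement` tibble: `orthogroup_id`, `chrom`, `start`, `end`,
#'   `strand`, `bitscore`, `e_value`
#' @export
select_placement <- function(hits, coverage_min = 1.0, evalue_max = 0.01) {
  hits %>%
    filter(query_coverage >= coverage_min, e_value <= evalue_max) %>%
    group_by(orthogroup_id = query_id) %>%
    arrange(dplyr::desc(bitscore), e_value, chrom, start, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select(orthogroup_id, chrom, start, end, strand, bitscore, e_value)
}

#' Protein-coding genes overlapping or within a window of each placement
#'
#' A PC gene is a neighbor of an neORF when its interval overlaps the
#' placement extended by `window` nt on both sides (strand-ignored,
#' 0-based half-open; a gene abutting exactly at `start - window` is
#' excluded). Overlap detection uses IRanges.
#'
#' @param placements tibble from [select_placement()]
#' @param gene_intervals tibble with `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), e.g. from [read_gene_intervals()]
#' @param window flank size in nt (default 1000)
#' @return tibble `orthogroup_id`, `gene_id` (one row per neighbor pair)
#' @export
window_neighbors <- function(placements, gene_intervals, window = 1000) {
  if (nrow(placements) == 0L || nrow(gene_intervals) == 0L) {
    return(tibble(orthogroup_id = character(), gene_id = character()))
  }
  rows <- purrr::map(unique(placements$chrom), function(ch) {
    pl <- placements %>% filter(chrom == ch)
    gn <- gene_intervals %>% filter(chrom == ch)
    if (nrow(pl) == 0L || nrow(gn) == 0L) return(NULL)
    # convert half-open [start, end) to 1-based closed IRanges
    qi <- IRanges::IRanges(start = pmax(pl$start - window, 0) + 1L,
                           end = pl$end + window)
    si <- IRanges::IRanges(start = gn$start + 1L, end = gn$end)
    ov <- IRanges::findOverlaps(qi, si, minoverlap = 1L)
    tibble(orthogroup_id = pl$orthogroup_id[S4Vectors::queryHits(ov)],
           gene_id = gn$gene_id[S4Vectors::subjectHits(ov)])
  })
  dplyr::bind_rows(rows) %>% distinct()
}

#' Differential expression of PC genes neighboring DE neORFs
#'
#' Pools the unique PC neighbors of differentially expressed neORFs and
#' tests, with a 1-df goodness-of-fit chi-square (no continuity
#' correction), whether more of them are differentially expressed than
#' expected from the sample-type-wide DE proportion among PC genes. A PC
#' gene neighboring several DE neORFs counts once.
#'
#' @param neighbors tibble `orthogroup_id`, `gene_id` from
#'   [window_neighbors()], already restricted to DE neORFs (or pass
#'   `de_orthogroups` to restrict here)
#' @param pc_de_flags tibble `gene_id`, logical `de` for PC genes
#' @param pc_de_proportion expected DE proportion among PC genes in the
#'   sample type; defaults to `mean(pc_de_flags$de)`
#' @param de_orthogroups optional character vector of DE orthogroup ids
#' @return one-row `NeighborResult` tibble: `n`, `n_de`, `n_expected`,
#'   `chi2`, `p_value`, `direction`; empty neighbor sets yield a row of
#'   `NA`s
#' @export
neighbor_de_test <- function(neighbors, pc_de_flags,
                             pc_de_proportion = NULL,
                             de_orthogroups = NULL) {
  if (!is.null(de_orthogroups)) {
    neighbors <- neighbors %>% filter(orthogroup_id %in% de_orthogroups)
  }
  ids <- unique(neighbors$gene_id)
  prop <- pc_de_proportion %||% mean(pc_de_flags$de)
  stopifnot(prop > 0, prop < 1)
  n <- length(ids)
  if (n == 0L) {
    return(tibble(n = 0L, n_de = NA_integer_, n_expected = NA_real_,
                  chi2 = NA_real_, p_value = NA_real_,
                  direction = NA_character_))
  }
  de_set <- pc_de_flags$gene_id[pc_de_flags$de]
  obs <- sum(ids %in% de_set)
  gof <- gof_proportion_test(obs, n, n * prop)
  tibble(n = n, n_de = obs, n_expected = n * prop,
         chi2 = gof$chi2, p_value = gof$p_value, direction = gof$direction)
}

#' Neighbor-DE test from printed summary counts
#'
#' Recomputes the neighbor association test directly from a
#' (total, observed DE, expected DE) triplet, as printed in a summary
#' table, without needing the underlying per-gene data.
#'
#' @param n total neighboring PC genes
#' @param n_de observed DE neighbors
#' @param n_expected expected DE neighbors
#' @return tibble from [gof_proportion_test()]
#' @export
neighbor_de_test_counts <- function(n, n_de, n_expected) {
  gof_proportion_test(n_de, n, n_expected)
}
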