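# End-to-end orchestration over simulated (or supplied) inputs. Stages
# communicate only via on-disk TSV/SAM artifacts so each stage is
# independently re-runnable; a manifest records every threshold and seed
# actually used.

default_run_config <- function() {
  list(
    seed = 1L,
    tpm_threshold = 0.5,
    fdr = 0.05,
    match_evalue = 1e-10,
    placement_coverage = 1.0,
    placement_evalue = 0.01,
    window = 1000L,
    min_support = 2L,
    min_reads = 4L,
    integrity_depth = 20L,
    popgen_depth = 30L,
    n_integrity_orfs = 8L,
    n_popgen_orfs = 8L,
    stages = list(quantify = TRUE, diffexpr = TRUE, integrity = TRUE,
                  popgen = TRUE, frequency = TRUE, neighbors = TRUE),
    simulation = list()
  )
}

#' Load a run configuration (YAML or list) with defaults filled in
#' @param config path to a YAML file, a list, or `NULL` for defaults
#' @return complete configuration list
#' @export
load_run_config <- function(config = NULL) {
  user <- if (is.null(config)) list()
  else if (is.character(config)) yaml::read_yaml(config)
  else config
  cfg <- utils::modifyList(default_run_config(), user)
  stopifnot(cfg$tpm_threshold >= 0, cfg$fdr > 0, cfg$window >= 0,
            cfg$min_support >= 1, cfg$min_reads >= 1)
  cfg
}

#' Run the full analysis pipeline on simulated inputs
#'
#' Simulates annotations, pooled counts, read pairs and polymorphic
#' pools under the configured study conditions, then executes quantify
#' -> differential expression -> ORF integrity -> pN/pS -> frequency
#' analysis -> neighbor analysis, writing each stage's table-shaped TSV
#' output plus a machine-readable manifest into `outdir`. Disabled
#' stages are skipped along with their dependants, with an explicit
#' notice in the manifest.
#'
#' @param config YAML path or list (see [load_run_config()])
#' @param outdir output directory (created if needed)
#' @return invisibly, a named list of the stage output tibbles
#' @export
run_pipeline <- function(config = NULL, outdir = tempfile("neorfpop_run_")) {
  cfg <- load_run_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  notices <- character(0)
  scfg <- do.call(sim_config, c(cfg$simulation, list(seed = cfg$seed)))

  ann <- simulate_annotation(scfg)
  designs <- simulate_design(scfg)
  cnt <- simulate_counts(ann$genes, designs, scfg)
  write_gene_table(ann$genes %>% select(-sequence), file.path(outdir, "genes.tsv"))
  write_orf_fasta(ann$genes %>% filter(!is.na(sequence)),
                  file.path(outdir, "neorfs.fasta"))
  readr::write_tsv(designs, file.path(outdir, "design.tsv"))
  write_counts(cnt$counts, file.path(outdir, "counts.tsv"))

  calls <- NULL
  if (isTRUE(cfg$stages$quantify)) {
    pooled <- pool_replicates(cnt$counts, designs)
    tpm <- compute_tpm(pooled, ann$genes)
    calls <- call_expressed(tpm, cfg$tpm_threshold)
    summ <- expression_summary(calls, ann$genes)
    readr::write_tsv(tpm, file.path(outdir, "tpm.tsv"))
    readr::write_tsv(calls, file.path(outdir, "expressed_calls.tsv"))
    readr::write_tsv(summ, file.path(outdir, "expression_summary.tsv"))
    out$expression_summary <- summ
  } else {
    notices <- c(notices, "quantify disabled: expression outputs skipped")
  }

  fit <- NULL
  if (isTRUE(cfg$stages$diffexpr)) {
    fit <- nb_wald_test(cnt$counts, designs, model = "two_factor",
                        contrast = "population", fdr = cfg$fdr)
    res <- generics::tidy(fit)
    readr::write_tsv(res, file.path(outdir, "de_results.tsv"))
    analyzed <- res %>% filter(!filtered)
    enr <- class_enrichment(
      analyzed %>% mutate(de = !is.na(padj) & padj <= cfg$fdr) %>%
        select(gene_id, de),
      ann$genes %>%
        mutate(gene_id = if_else(gene_class == "neORF", orthogroup_id, gene_id)) %>%
        select(gene_id, gene_class)
    )
    mag <- lfc_magnitude_test(res, ann$genes %>%
                                select(gene_id, gene_class), alpha = cfg$fdr)
    readr::write_tsv(enr, file.path(outdir, "class_enrichment.tsv"))
    readr::write_tsv(mag, file.path(outdir, "lfc_magnitude.tsv"))
    out$de <- res; out$class_enrichment <- enr; out$lfc_magnitude <- mag
  } else {
    notices <- c(notices,
                 "diffexpr disabled: DE, enrichment, LFC-magnitude, intact-DE and neighbor-DE outputs skipped")
  }

  orfs <- orf_models(ann$genes)
  if (isTRUE(cfg$stages$integrity)) {
    cand <- ann$genes %>%
      filter(gene_class == "neORF",
             orf_detectable(cds_length, scfg$read_length, TRUE)) %>%
      head(cfg$n_integrity_orfs)
    states <- rep(c("intact", "internal_stop", "frameshift", "no_start"),
                  length.out = nrow(cand))
    sims <- purrr::map2(seq_len(nrow(cand)), states, function(i, st) {
      simulate_read_pairs(cand[i, ], st, depth = cfg$integrity_depth,
                          config = scfg, seed = scfg$seed + 100L + i)
    })
    pairs <- dplyr::bind_rows(purrr::map(sims, "pairs"))
    sam_path <- file.path(outdir, "integrity_reads.sam")
    write_alignments(pairs, cand, sam_path)
    aln <- read_alignments(sam_path, cand)
    categories <- classify_read_pairs(aln, orfs, e_threshold = cfg$match_evalue)
    intact <- call_intact(categories, orfs %>%
                            filter(target_id %in% cand$gene_id),
                          scfg$read_length, paired = TRUE)
    readr::write_tsv(categories, file.path(outdir, "pair_categories.tsv"))
    readr::write_tsv(intact, file.path(outdir, "intact_calls.tsv"))
    out$intact <- intact
    if (!is.null(fit)) {
      de_ne <- de_calls(fit) %>% filter(gene_id %in% intact$orthogroup_id)
      if (sum(de_ne$de) > 0) {
        ide <- intact_de_enrichment(intact, de_ne)
        readr::write_tsv(ide, file.path(outdir, "intact_de_enrichment.tsv"))
        out$intact_de <- ide
      }
    }
  } else {
    notices <- c(notices, "integrity disabled: pair categories and intact calls skipped")
  }

  if (isTRUE(cfg$stages$popgen)) {
    cand <- ann$genes %>%
      filter(gene_class == "neORF",
             orf_detectable(cds_length, scfg$read_length, TRUE)) %>%
      head(cfg$n_popgen_orfs)
    per <- purrr::map(seq_len(nrow(cand)), function(i) {
      pool <- simulate_polymorphic_pool(cand[i, ], n_lines = scfg$pool_lines,
                                        depth = cfg$popgen_depth, config = scfg,
                                        seed = scfg$seed + 200L + i)
      list(calls = call_polymorphisms(pool$reads, cand$sequence[i],
                                      cfg$min_support, cfg$min_reads),
           sites = ng_site_counts(cand$sequence[i]))
    })
    pooled_pnps <- pnps(dplyr::bind_rows(purrr::map(per, "calls")),
                        dplyr::bind_rows(purrr::map(per, "sites")))
    readr::write_tsv(pooled_pnps, file.path(outdir, "pnps.tsv"))
    out$pnps <- pooled_pnps
  } else {
    notices <- c(notices, "popgen disabled: pN/pS outputs skipped")
  }

  if (isTRUE(cfg$stages$frequency) && !is.null(calls)) {
    part <- bin_by_frequency(ann$genes)
    ne_calls <- calls %>% filter(gene_id %in% part$gene_id)
    expressed_any <- tibble(
      gene_id = ne_calls$gene_id,
      expressed = Reduce(`|`, lapply(setdiff(names(ne_calls), "gene_id"),
                                     function(cc) ne_calls[[cc]]))
    )
    freq <- frequency_enrichment(part, expressed_any)
    readr::write_tsv(freq, file.path(outdir, "frequency_classes.tsv"))
    out$frequency <- freq
  } else if (isTRUE(cfg$stages$frequency)) {
    notices <- c(notices, "frequency skipped: requires quantify stage")
  }

  if (isTRUE(cfg$stages$neighbors) && !is.null(fit)) {
    placed <- ann$genes %>%
      filter(gene_class == "neORF", !is.na(start)) %>%
      mutate(orthogroup_id = orthogroup_id, bitscore = 2 * cds_length,
             e_value = 1e-30) %>%
      select(orthogroup_id, chrom, start, end, strand, bitscore, e_value)
    pc_ivl <- ann$genes %>%
      filter(gene_class == "PC", !is.na(start)) %>%
      select(gene_id, chrom, start, end)
    nb <- window_neighbors(placed, pc_ivl, window = cfg$window)
    dcalls <- de_calls(fit)
    de_og <- dcalls$gene_id[dcalls$de & dcalls$gene_id %in% placed$orthogroup_id]
    pc_de <- dcalls %>% filter(gene_id %in% pc_ivl$gene_id)
    nres <- neighbor_de_test(nb, pc_de, de_orthogroups = de_og)
    write_placements_bed(placed, file.path(outdir, "placements.bed"))
    readr::write_tsv(nres, file.path(outdir, "neighbor_de.tsv"))
    out$neighbors <- nres
  } else if (isTRUE(cfg$stages$neighbors)) {
    notices <- c(notices, "neighbors skipped: requires diffexpr stage")
  }

  manifest <- list(
    package = "neorfpop",
    version = as.character(utils::packageVersion("neorfpop")),
    seed = cfg$seed,
    thresholds = cfg[c("tpm_threshold", "fdr", "match_evalue",
                       "placement_coverage", "placement_evalue", "window",
                       "min_support", "min_reads")],
    stages = cfg$stages,
    notices = as.list(notices)
  )
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(out)
}
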