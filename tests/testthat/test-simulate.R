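test_that("annotation generator satisfies its invariants deterministically", {
  cfg <- sim_config(n_pc = 10, n_nc = 5, n_neorf = 70, seed = 31)
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_equal(a1, a2)  # full determinism under fixed seed

  ne <- a1$genes[a1$genes$gene_class == "neORF", ]
  expect_true(all(substr(ne$sequence, 1, 3) == "ATG"))
  aa <- vapply(ne$sequence, translate_cds, "", USE.NAMES = FALSE)
  expect_true(all(substr(aa, nchar(aa), nchar(aa)) == "*"))
  expect_false(any(grepl("\\*", substr(aa, 1, nchar(aa) - 1))))
  expect_true(all(ne$cds_length >= 90 & ne$cds_length %% 3 == 0))
  # all frequency classes populated at n_neorf >= 70
  expect_setequal(unique(popcount_presence(ne$line_presence)), 1:7)
  # truth covers every neORF exactly once
  expect_equal(sort(a1$truth$gene_id), sort(ne$gene_id))

  # n_neorf = 7 -> exactly one neORF per frequency class
  a7 <- simulate_annotation(sim_config(n_pc = 2, n_nc = 1, n_neorf = 7, seed = 3))
  expect_equal(sort(a7$truth$lines_present), 1:7)
})

test_that("count generator inverts the NB model with exhaustive truth", {
  cfg0 <- sim_config(n_pc = 50, n_nc = 10, n_neorf = 20,
                     de_fraction = c(PC = 0, ncRNA = 0, neORF = 0), seed = 8)
  ann <- simulate_annotation(cfg0)
  designs <- simulate_design(cfg0)
  cnt <- simulate_counts(ann$genes, designs, cfg0)
  expect_true(all(cnt$truth$true_lfc == 0))  # de_fraction 0 -> all null
  # exactly one truth row per emitted count row
  expect_equal(sort(cnt$truth$gene_id), sort(cnt$counts$gene_id))

  # Poisson limit: dispersion -> 0 gives variance/mean ~ 1 over many draws
  cfgp <- sim_config(n_pc = 2000, n_nc = 0, n_neorf = 0, dispersion = 0,
                     baseline_sdlog = 0, de_fraction = c(PC = 0), seed = 9)
  annp <- simulate_annotation(cfgp)
  dp <- simulate_design(cfgp, sexes = NA)
  cp <- simulate_counts(annp$genes, dp, cfgp)
  m <- as.matrix(cp$counts[-1])
  sf <- cp$sample_truth$size_factor
  norm <- sweep(m, 2, sf, "/")
  ratio <- mean(apply(norm, 1, var) / rowMeans(norm))
  expect_lt(abs(ratio - 1), 0.1)
})

test_that("read-pair generator records category truth consistent with geometry", {
  cfg <- sim_config(n_pc = 1, n_nc = 0, n_neorf = 5, seed = 13)
  ann <- simulate_annotation(cfg)
  ne <- ann$genes[ann$genes$gene_class == "neORF" &
                    ann$genes$cds_length <= 300, ][1, ]
  sim <- simulate_read_pairs(ne, "intact", depth = 30, config = cfg, seed = 14)
  # truth covers every fragment exactly once
  expect_equal(sort(unique(sim$pairs$fragment_id)), sort(sim$truth$fragment_id))
  # spanning fragments are cat1 truths; with 150-nt pairs and ~250-nt
  # fragments over a short ORF most fragments span
  expect_true(all(sim$truth$true_category[sim$truth$covers_full] == "cat1"))

  # reads/fragments too short to span the ORF -> no cat1 truths
  cfg_short <- sim_config(n_pc = 1, n_nc = 0, n_neorf = 5, read_length = 40,
                          fragment_mean = 60, fragment_sd = 5, seed = 15)
  ne300 <- ann$genes[ann$genes$gene_class == "neORF" &
                       ann$genes$cds_length >= 150, ][1, ]
  sshort <- simulate_read_pairs(ne300, "intact", depth = 40,
                                config = cfg_short, seed = 16)
  expect_false(any(sshort$truth$true_category == "cat1"))
  expect_error(simulate_read_pairs(ne, "intact", depth = 0), "positive")
})

test_that("polymorphic pool generator controls site classes", {
  cfg <- sim_config(seed = 17)
  ann <- simulate_annotation(sim_config(n_pc = 1, n_nc = 0, n_neorf = 3,
                                        neorf_length_range = c(300, 600),
                                        seed = 18))
  ne <- ann$genes[ann$genes$gene_class == "neORF", ][1, ]
  syn_only <- simulate_polymorphic_pool(ne, n_lines = 12, pn_rate = 0,
                                        ps_rate = 0.05, depth = 20,
                                        config = cfg, seed = 19)
  expect_true(all(syn_only$truth$site_class == "synonymous"))
  non_only <- simulate_polymorphic_pool(ne, n_lines = 12, pn_rate = 0.03,
                                        ps_rate = 0, depth = 20,
                                        config = cfg, seed = 20)
  expect_true(all(non_only$truth$site_class == "nonsynonymous"))
  # downstream ratio undefined when pS = 0
  calls <- call_polymorphisms(non_only$reads, ne$sequence)
  res <- pnps(calls, ng_site_counts(ne$sequence))
  expect_false(res$ratio_defined)
  expect_warning(
    simulate_polymorphic_pool(ne, pn_rate = 0.2, ps_rate = 0.2, depth = 4,
                              config = cfg, seed = 21),
    "double hits"
  )
})
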