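test_that("full-length collection keeps only ORF-spanning fragments", {
  set.seed(71)
  genes <- tibble::tibble(gene_id = "ne1", gene_class = "neORF",
                          orthogroup_id = "og1", cds_length = 300L,
                          sequence = random_orf(300), line_presence = "1111111")
  orf <- as.list(orf_models(genes)[1, ])
  s <- orf$sequence
  row <- function(fid, start, seq, mate = 1L) {
    tibble::tibble(fragment_id = fid, target_id = "ne1", mate = mate,
                   start = start, end = start + nchar(seq),
                   cigar = paste0(nchar(seq), "M"), seq = seq,
                   mate_count = NA_integer_)
  }
  aln <- dplyr::bind_rows(
    row("span", 0, substr(s, 1, 160)),
    row("span", 150, substr(s, 151, 300), 2L),
    row("short", 0, substr(s, 1, 299)),          # [0,299) -> dropped
    row("gapped", 0, substr(s, 1, 100)),
    row("gapped", 200, substr(s, 201, 300), 2L)  # inner gap -> dropped
  )
  reads <- collect_full_length(aln, orf)
  expect_length(reads, 1)
  expect_equal(nchar(reads), 300)
  expect_identical(reads, s)
})

test_that("polymorphism calling enforces support and depth thresholds", {
  set.seed(72)
  ref <- random_orf(90)
  alt <- ref
  substr(alt, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                 substr(ref, 10, 10))[1]
  # 3 reads total -> no calls regardless of variation
  expect_equal(nrow(call_polymorphisms(c(ref, alt, alt), ref)), 0L)
  # 4 reads but singleton alternate -> putative error, no call
  expect_equal(nrow(call_polymorphisms(c(ref, ref, ref, alt), ref)), 0L)
  # 4 reads, alternate in 2 -> called once at the right site
  calls <- call_polymorphisms(c(ref, ref, alt, alt), ref)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos, 9L)
  expect_equal(calls$n_support, 2L)
  expect_equal(calls$n_reads, 4L)
  # invariant to read order and duplicated reads beyond threshold effects
  calls2 <- call_polymorphisms(c(alt, ref, alt, ref, alt), ref)
  expect_equal(calls2$pos, calls$pos)
  expect_equal(calls2$site_class, calls$site_class)
})

test_that("Nei-Gojobori site counts equal the mutation-translate oracle", {
  # exhaustive over all 61 sense codons
  for (cod in sense_codons) {
    got <- ng_site_counts(cod)
    ref <- oracle_ng_sites(cod)
    expect_equal(got$n_sites, unname(ref["n_sites"]), tolerance = 1e-12)
    expect_equal(got$s_sites, unname(ref["s_sites"]), tolerance = 1e-12)
    expect_equal(got$n_sites + got$s_sites, 3)
  }
  expect_equal(ng_site_counts("TTT")$n_sites, 8 / 3)
  expect_equal(ng_site_counts("TTT")$s_sites, 1 / 3)

  set.seed(73)
  for (i in 1:100) {
    s <- paste(sample(sense_codons, 30, replace = TRUE), collapse = "")
    got <- ng_site_counts(s)
    ref <- oracle_ng_sites(s)
    expect_equal(got$n_sites, unname(ref["n_sites"]), tolerance = 1e-9)
    expect_equal(got$s_sites, unname(ref["s_sites"]), tolerance = 1e-9)
    expect_equal(got$n_sites + got$s_sites, 3 * 30)
  }
  expect_error(ng_site_counts("ATGTAAATG"), "internal stop")
})

test_that("pN/pS and its goodness-of-fit behave at the null and edges", {
  sites <- tibble::tibble(n_sites = 150, s_sites = 50, n_codons = 66)
  calls <- tibble::tibble(site_class = rep(c("nonsynonymous", "synonymous"),
                                           c(30, 10)))
  out <- pnps(calls, sites)
  expect_equal(out$ratio, 1)   # counts proportional to sites
  expect_equal(out$gof_chi2, 0)
  expect_equal(out$gof_p, 1)

  syn_only <- pnps(tibble::tibble(site_class = rep("synonymous", 8)), sites)
  expect_equal(syn_only$pN, 0)
  non_only <- pnps(tibble::tibble(site_class = rep("nonsynonymous", 8)), sites)
  expect_false(non_only$ratio_defined)
  expect_true(is.finite(non_only$gof_chi2))
})

test_that("group comparison of pN/pS is a 2x2 contingency chi-square", {
  a <- tibble::tibble(site_class = rep(c("nonsynonymous", "synonymous"),
                                       c(20, 20)))
  expect_equal(compare_pnps(a, a)$chi2, 0)

  set.seed(74)
  hits <- replicate(20, {
    na <- 200; nb <- 200
    ca <- tibble::tibble(site_class = ifelse(runif(na) < 0.2 / 1.2,
                                             "nonsynonymous", "synonymous"))
    cb <- tibble::tibble(site_class = ifelse(runif(nb) < 0.5,
                                             "nonsynonymous", "synonymous"))
    out <- compare_pnps(ca, cb)
    ref <- suppressWarnings(chisq.test(rbind(
      table(factor(ca$site_class, c("nonsynonymous", "synonymous"))),
      table(factor(cb$site_class, c("nonsynonymous", "synonymous")))),
      correct = FALSE))
    expect_equal(out$chi2, unname(ref$statistic))
    out$p_value < 0.01
  })
  expect_gte(mean(hits), 0.95)
})
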