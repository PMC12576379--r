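# hand-built alignment rows: exact match of `seq` at [start, start+len)
mate_row <- function(fragment_id, target_id, start, seq, mate = 1L) {
  tibble::tibble(fragment_id = fragment_id, target_id = target_id,
                 mate = mate, start = start, end = start + nchar(seq),
                 cigar = paste0(nchar(seq), "M"), seq = seq,
                 mate_count = NA_integer_)
}

toy_orf <- function(length_nt = 90, seed = 1) {
  set.seed(seed)
  genes <- tibble::tibble(
    gene_id = "ne1", gene_class = "neORF", orthogroup_id = "og1",
    cds_length = length_nt, sequence = random_orf(length_nt),
    line_presence = "1000000"
  )
  orf_models(genes)
}

test_that("detectable-length rule follows read geometry", {
  expect_true(orf_detectable(300, 150, paired = TRUE))
  expect_false(orf_detectable(90, 50, paired = FALSE))
  expect_false(orf_detectable(201, 100, paired = TRUE))
  expect_true(orf_detectable(200, 100, paired = TRUE))
})

test_that("step-1 categories follow geometry, stop scan and precedence", {
  orfs <- toy_orf(300, seed = 2)
  orf <- as.list(orfs[1, ])
  s <- orf$sequence

  # mates on different targets -> cat5 before anything else
  p5 <- dplyr::bind_rows(mate_row("f", "ne1", 0, substr(s, 1, 100)),
                         mate_row("f", "neX", 0, substr(s, 1, 100), mate = 2L))
  expect_equal(classify_step1(p5, orf)$step1, "cat5")

  # overlapping mates covering [0,150) and [140,300), no stop -> cat1
  p1 <- dplyr::bind_rows(mate_row("f", "ne1", 0, substr(s, 1, 150)),
                         mate_row("f", "ne1", 140, substr(s, 141, 300), 2L))
  expect_true(oracle_union_covers(list(c(0, 150), c(140, 300)), 300))
  expect_equal(classify_step1(p1, orf)$step1, "cat1")

  # an unsequenced inner gap disqualifies cat1
  pg <- dplyr::bind_rows(mate_row("f", "ne1", 0, substr(s, 1, 100)),
                         mate_row("f", "ne1", 200, substr(s, 201, 300), 2L))
  expect_false(oracle_union_covers(list(c(0, 100), c(200, 300)), 300))
  expect_equal(classify_step1(pg, orf)$step1, "cat2")

  # in-frame internal stop -> cat3, also when the start is mutated (precedence)
  s3 <- s; substr(s3, 31, 33) <- "TAA"
  p3 <- mate_row("f", "ne1", 0, substr(s3, 1, 120))
  expect_equal(classify_step1(p3, orf)$step1, "cat3")
  s34 <- s3; substr(s34, 1, 3) <- "ATA"
  p34 <- mate_row("f", "ne1", 0, substr(s34, 1, 120))
  expect_equal(classify_step1(p34, orf)$step1, "cat3")

  # start spanned but not ATG (and no stop) -> cat4
  s4 <- s; substr(s4, 1, 3) <- "ATA"
  p4 <- mate_row("f", "ne1", 0, substr(s4, 1, 120))
  expect_equal(classify_step1(p4, orf)$step1, "cat4")

  # the annotated terminal stop codon does not count as internal
  pfull <- mate_row("f", "ne1", 0, s)
  expect_equal(classify_step1(pfull, orf)$step1, "cat1")

  # out-of-frame TAA in the read must not trigger cat3
  expect_equal(classify_step1(mate_row("f", "ne1", 1, substr(s, 2, 150)),
                              orf)$step1, "cat2")

  # alignment entirely outside the ORF interval -> caller must prefilter
  expect_error(classify_step1(mate_row("f", "ne1", 400, "ACGTACGTACGT"),
                              orf), "overlap")
})

test_that("step-1 partitions all ORF-overlapping pairs on random input", {
  cfg <- sim_config(n_pc = 1, n_nc = 0, n_neorf = 6, seed = 33)
  ann <- simulate_annotation(cfg)
  orfs <- orf_models(ann$genes)
  ne <- ann$genes[ann$genes$gene_class == "neORF", ]
  for (i in 1:3) {
    st <- c("intact", "internal_stop", "frameshift")[i]
    sim <- simulate_read_pairs(ne[i, ], st, depth = 12, config = cfg,
                               seed = 40 + i)
    orf <- as.list(orfs[orfs$target_id == ne$gene_id[i], ])
    cats <- vapply(split(sim$pairs, sim$pairs$fragment_id),
                   function(p) classify_step1(p, orf)$step1, "")
    expect_true(all(cats %in% paste0("cat", 1:5)))
    expect_equal(length(cats), length(unique(sim$pairs$fragment_id)))
  }
})

test_that("aligned translation anchors frames correctly", {
  orfs <- toy_orf(90, seed = 4)
  orf <- as.list(orfs[1, ])
  # read containing the full 90-nt ORF -> single 29-aa peptide
  pfull <- mate_row("f", "ne1", 0, orf$sequence)
  peps <- translate_aligned(pfull, orf)
  expect_length(peps, 1)
  expect_equal(nchar(peps), 29)
  expect_identical(peps, orf$protein)  # equals codon-table oracle

  # internal 30-nt segment without the start -> 3 candidate frames
  pin <- mate_row("f", "ne1", 30, substr(orf$sequence, 31, 60))
  pin_peps <- translate_aligned(pin, orf)
  expect_lte(length(pin_peps), 3)
  expect_gte(length(pin_peps), 2)
  expect_true(substr(orf$protein, 11, 20) %in% pin_peps)
  # segment < 1 codon -> empty list
  tiny <- mate_row("f", "ne1", 31, substr(orf$sequence, 32, 33))
  expect_length(translate_aligned(tiny, orf), 0)
})

test_that("protein matcher scores identity hits and rejects random peptides", {
  orfs <- toy_orf(93, seed = 5)
  prot <- orfs$protein[1]  # 30 aa
  expect_lte(protein_match(prot, prot), 1e-10)
  expect_identical(protein_match(character(0), prot), Inf)

  set.seed(55)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  null_e <- replicate(1000, {
    pep <- paste(sample(aas, 10, replace = TRUE), collapse = "")
    protein_match(pep, prot)
  })
  expect_gte(mean(null_e > 1e-10), 0.99)
})

test_that("step-2 truth table is exhaustive and boundary-inclusive", {
  cases <- expand.grid(step1 = c("cat1", "cat2"),
                       match = c(TRUE, FALSE),
                       start = c(TRUE, FALSE),
                       stringsAsFactors = FALSE)
  expected <- with(cases, ifelse(
    step1 == "cat1", ifelse(match, "catA", "catE"),
    ifelse(match, ifelse(start, "catB", "catC"), "catD")))
  for (i in seq_len(nrow(cases))) {
    e <- if (cases$match[i]) 1e-10 else 1e-9  # threshold is inclusive <=
    expect_identical(
      classify_step2(cases$step1[i], e, cases$start[i]),
      expected[i]
    )
  }
  expect_identical(classify_step2("cat1", 1e-20, TRUE), "catA")
  expect_identical(classify_step2("cat1", 0.5, TRUE), "catE")
  expect_error(classify_step2("cat3", 1e-20, TRUE), "cat1/cat2")
})

test_that("intactness calls require at least one catA on a detectable ORF", {
  orfs <- toy_orf(120, seed = 6)
  categories <- tibble::tibble(
    fragment_id = paste0("f", 1:5), target_id = "ne1",
    step1 = c("cat1", "cat3", "cat3", "cat3", "cat3"),
    step2 = c("catA", NA, NA, NA, NA),
    best_evalue = c(1e-20, NA, NA, NA, NA), start_covered = TRUE)
  call <- call_intact(categories, orfs, read_length = 150)
  expect_true(call$intact)
  expect_equal(call$catA, 1L)
  expect_equal(call$cat3, 4L)

  catb <- categories %>%
    dplyr::mutate(step2 = dplyr::if_else(step2 == "catA", "catB", step2),
                  step1 = dplyr::if_else(step1 == "cat1", "cat2", step1))
  expect_false(call_intact(catb, orfs, read_length = 150)$intact)
  # undetectable ORF can never be intact
  expect_false(call_intact(categories, orfs, read_length = 50)$intact)
})

test_that("intact-DE enrichment equals the dichotomy oracle", {
  flat <- tibble::tibble(gene_id = sprintf("og%02d", 1:40),
                         intact = rep(c(TRUE, FALSE), 20))
  de <- tibble::tibble(gene_id = flat$gene_id,
                       de = rep(c(TRUE, TRUE, FALSE, FALSE), 10))
  out <- intact_de_enrichment(flat, de)
  expect_equal(out$chi2, 0)
  expect_equal(out$p_value, 1)

  set.seed(66)
  hits <- replicate(20, {
    n <- 500
    de2 <- runif(n) < 0.4
    intact2 <- runif(n) < ifelse(de2, 0.8, 0.4)
    x <- intact_de_enrichment(
      tibble::tibble(gene_id = as.character(1:n), intact = intact2),
      tibble::tibble(gene_id = as.character(1:n), de = de2))
    o <- sum(intact2 & de2); nn <- sum(de2); e <- nn * mean(intact2)
    brute <- (o - e)^2 / e + ((nn - o) - (nn - e))^2 / (nn - e)
    expect_equal(x$chi2, brute)
    x$p_value < 1e-6
  })
  expect_gte(mean(hits), 0.95)
})
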