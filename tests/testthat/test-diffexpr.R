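test_that("median-of-ratios size factors behave under scaling and permutation", {
  set.seed(23)
  base <- matrix(rpois(600, 100) + 1, 100, 6)
  counts <- tibble::as_tibble(base, .name_repair = "minimal")
  names(counts) <- paste0("s", 1:6)
  counts <- dplyr::bind_cols(tibble::tibble(gene_id = sprintf("g%03d", 1:100)),
                             counts)
  sf <- size_factors(counts)
  expect_equal(unname(sf), rep(1, 6), tolerance = 0.05)  # similar columns

  doubled <- counts; doubled$s3 <- doubled$s3 * 2
  sfd <- size_factors(doubled)
  expect_equal(unname(sfd["s3"] / sfd["s1"]), 2, tolerance = 0.05)
  expect_equal(exp(mean(log(sfd))), 1)

  perm <- counts[sample(100), ]
  expect_equal(size_factors(perm), sf)  # gene-order invariance

  zeros <- counts; zeros[2:101] <- 0; zeros$s1 <- 1
  expect_warning(size_factors(zeros), "column-sum")
})

test_that("NB Wald test recovers large effects and nulls flat genes", {
  set.seed(24)
  g <- 400
  mu <- exp(rnorm(g, log(500), 1))
  lfc_true <- c(rep(2, 40), rep(0, g - 40))
  m <- cbind(
    matrix(rnbinom(g * 3, mu = mu, size = 20), g, 3),
    matrix(rnbinom(g * 3, mu = mu * 2^lfc_true, size = 20), g, 3)
  )
  m[5, ] <- 77  # identical counts across all samples
  counts <- dplyr::bind_cols(
    tibble::tibble(gene_id = sprintf("g%03d", 1:g)),
    tibble::as_tibble(`colnames<-`(m, paste0("s", 1:6)))
  )
  designs <- tibble::tibble(sample_id = paste0("s", 1:6),
                            population = rep(c("Eur", "Afr"), each = 3),
                            sex = "F", condition = "x", replicate = rep(1:3, 2))
  fit <- nb_wald_test(counts, designs, model = "population")
  res <- tidy(fit)
  # LFC recovery within +-0.2 at high depth for the true-effect genes
  est <- mean(res$lfc[1:40])
  expect_lt(abs(est - 2), 0.2)
  # flat gene: LFC ~ 0, large p (size factors of the other genes are
  # near but not exactly 1, so the estimate is only approximately 0)
  flat <- res[res$gene_id == "g005", ]
  expect_lt(abs(flat$lfc), 0.15)
  expect_gt(flat$pvalue, 0.5)

  # with exactly identical columns everywhere the estimate is exactly 0
  const <- counts
  for (s in paste0("s", 1:6)) const[[s]] <- const$s1
  fitc <- nb_wald_test(const, designs, model = "population")
  flatc <- tidy(fitc)[tidy(fitc)$gene_id == "g005", ]
  expect_equal(flatc$lfc, 0, tolerance = 1e-6)
  expect_equal(flatc$pvalue, 1, tolerance = 1e-6)
  # adjusted p >= raw p; filtered genes carry no adjusted p
  ok <- !is.na(res$padj)
  expect_true(all(res$padj[ok] >= res$pvalue[ok]))
  expect_true(all(is.na(res$padj[res$filtered])))
  gl <- glance(fit)
  expect_gt(gl$n_de, 20)
})

test_that("six-level one-factor design contrasts populations within stage", {
  set.seed(25)
  designs <- tidyr::expand_grid(population = c("Eur", "Afr"),
                                condition = c("early", "late", "prepup"),
                                replicate = 1:3) %>%
    dplyr::mutate(sample_id = paste(population, condition, replicate, sep = "_"),
                  sex = NA_character_)
  g <- 120
  mu <- exp(rnorm(g, log(300), 0.8))
  m <- sapply(seq_len(nrow(designs)), function(i) {
    eff <- ifelse(designs$population[i] == "Afr" &
                    designs$condition[i] == "early", 2^1.5, 1)
    rnbinom(g, mu = mu * c(rep(eff, 30), rep(1, g - 30)), size = 20)
  })
  counts <- dplyr::bind_cols(
    tibble::tibble(gene_id = sprintf("g%03d", 1:g)),
    tibble::as_tibble(`colnames<-`(m, designs$sample_id))
  )
  fit <- nb_wald_test(counts, designs, model = "six_level",
                      contrast = c("Afr.early", "Eur.early"))
  res <- tidy(fit)
  expect_lt(abs(mean(res$lfc[1:30]) - 1.5), 0.25)
  # null genes: mean |LFC| stays near its 3v3 sampling noise (~0.2)
  expect_lt(mean(abs(res$lfc[31:120])), 0.35)
  expect_error(nb_wald_test(counts, designs, model = "six_level",
                            contrast = "Afr.early"),
               "two of the groups")
})

test_that("independent filtering never loses discoveries and is deterministic", {
  set.seed(26)
  res <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:300),
    base_mean = exp(rnorm(300, 3, 1.5)),
    pvalue = runif(300)
  )
  res$pvalue[res$base_mean > 40][1:20] <- 1e-8
  f1 <- independent_filter(res)
  f0 <- neorfpop:::apply_independent_filter(res, enabled = FALSE)
  expect_gte(sum(f1$padj <= 0.05, na.rm = TRUE),
             sum(f0$padj <= 0.05, na.rm = TRUE))
  expect_identical(independent_filter(res), f1)  # deterministic grid search

  high <- res; high$base_mean <- 1000 + runif(300)  # all high counts
  fh <- independent_filter(high)
  expect_equal(sum(fh$filtered), 0L)
})

test_that("class enrichment matches the dichotomy chi-square", {
  # equal class and global proportions -> chi2 0, p 1
  de <- tibble::tibble(gene_id = sprintf("g%02d", 1:40),
                       de = rep(c(TRUE, FALSE, FALSE, FALSE), 10))
  cls <- tibble::tibble(gene_id = de$gene_id,
                        gene_class = rep(c("PC", "neORF"), each = 20))
  enr <- class_enrichment(de, cls)
  expect_equal(enr$chi2, c(0, 0))
  expect_equal(enr$p_value, c(1, 1))

  set.seed(27)
  de2 <- tibble::tibble(gene_id = sprintf("g%03d", 1:600),
                        de = runif(600) < rep(c(0.1, 0.3, 0.2), each = 200))
  cls2 <- tibble::tibble(gene_id = de2$gene_id,
                         gene_class = rep(c("PC", "neORF", "ncRNA"), each = 200))
  enr2 <- class_enrichment(de2, cls2)
  p_glob <- mean(de2$de)
  for (i in seq_len(nrow(enr2))) {
    o <- enr2$n_de[i]; n <- enr2$n_analyzed[i]; e <- n * p_glob
    brute <- (o - e)^2 / e + ((n - o) - (n - e))^2 / (n - e)
    expect_equal(enr2$chi2[i], brute)
  }
  expect_equal(enr2$p_adj, bh_adjust(enr2$p_value))
})

test_that("|LFC| magnitude comparisons are Welch tests with symmetry", {
  same <- tibble::tibble(gene_id = sprintf("g%02d", 1:20),
                         lfc = rep(c(1, -1), 10), padj = 0.01)
  cls <- tibble::tibble(gene_id = same$gene_id,
                        gene_class = rep(c("PC", "neORF"), each = 10))
  out <- lfc_magnitude_test(same, cls)
  expect_equal(out$t, 0)
  expect_equal(out$p_value, 1)

  set.seed(28)
  detect <- replicate(20, {
    res <- tibble::tibble(
      gene_id = sprintf("g%03d", 1:400),
      lfc = c(rnorm(200, 1, 1), rnorm(200, 2, 1)), padj = 0.01)
    cc <- tibble::tibble(gene_id = res$gene_id,
                         gene_class = rep(c("PC", "neORF"), each = 200))
    lfc_magnitude_test(res, cc)$p_value < 1e-3
  })
  expect_gte(mean(detect), 0.9)  # shifted normals, delta 1, n 200

  # swapping class order negates t, p unchanged
  res <- tibble::tibble(gene_id = sprintf("g%02d", 1:40),
                        lfc = c(rnorm(20, 1), rnorm(20, 3)), padj = 0.01)
  cA <- tibble::tibble(gene_id = res$gene_id,
                       gene_class = rep(c("A", "B"), each = 20))
  cB <- tibble::tibble(gene_id = res$gene_id,
                       gene_class = rep(c("B", "A"), each = 20))
  oA <- lfc_magnitude_test(res, cA)
  oB <- lfc_magnitude_test(res, cB)
  expect_equal(oA$t, -oB$t)
  expect_equal(oA$p_value, oB$p_value)

  few <- lfc_magnitude_test(res[1:21, ], cA[1:21, ])
  expect_true(is.na(few$t))
  expect_match(few$reason, "fewer than 2")
})
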