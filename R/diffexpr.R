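# Negative-binomial differential expression. The machinery is a
# documented simplification of the DESeq2 scheme: median-of-ratios size
# factors, per-gene NB GLMs with log link fit by IRLS, gene-wise
# dispersion by grid-maximized Cox-Reid adjusted profile likelihood,
# a parametric mean-dispersion trend, MAP shrinkage of the gene-wise
# estimates toward the trend, and a Wald test of the contrast
# coefficient against the standard normal. Bit-level agreement with
# DESeq2 is not a goal; the statistical design is.

#' Median-of-ratios size factors
#'
#' Per-gene ratios of counts to the geometric-mean reference are taken
#' over genes with all-positive counts; each sample's factor is the
#' median ratio, rescaled so the factors have geometric mean 1. When no
#' gene is positive in every sample, column-sum ratios are used with a
#' warning.
#'
#' @param counts count tibble (`gene_id` + sample columns)
#' @return named numeric vector of positive size factors
#' @export
size_factors <- function(counts) {
  m <- counts_to_matrix(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    warn("no gene with all-positive counts; falling back to column-sum ratios")
    sf <- colSums(m)
    sf <- sf / exp(mean(log(sf)))
    return(sf)
  }
  lm_ <- log(m[pos, , drop = FALSE])
  ref <- rowMeans(lm_)
  sf <- exp(apply(lm_ - ref, 2, median))
  sf / exp(mean(log(sf)))
}

# closed-form / generic log-determinant of per-gene p x p information
# matrices; E is G x (p*p) with columns vec(XtWX_g)
logdet_rows <- function(E, p) {
  if (p == 1L) return(log(E[, 1]))
  if (p == 2L) {
    return(log(pmax(E[, 1] * E[, 4] - E[, 2] * E[, 3], 1e-300)))
  }
  if (p == 3L) {
    a <- E[, 1]; b <- E[, 4]; c <- E[, 7]
    d <- E[, 2]; e <- E[, 5]; f <- E[, 8]
    g <- E[, 3]; h <- E[, 6]; i <- E[, 9]
    det3 <- a * (e * i - f * h) - d * (b * i - c * h) + g * (b * f - c * e)
    return(log(pmax(det3, 1e-300)))
  }
  apply(E, 1, function(v) {
    d <- det(matrix(v, p, p))
    log(max(d, 1e-300))
  })
}

# Cox-Reid adjusted profile log-likelihood for all genes at one
# dispersion value, with fitted means held fixed
apl_at <- function(m, mu, phi, X) {
  p <- ncol(X)
  W <- mu / (1 + phi * mu)
  xx <- matrix(NA_real_, nrow(m), p * p)
  k <- 0L
  for (j in seq_len(p)) for (l in seq_len(p)) {
    k <- k + 1L
    xx[, k] <- W %*% (X[, j] * X[, l])
  }
  ll <- rowSums(dnbinom(m, size = 1 / phi, mu = mu, log = TRUE))
  ll - 0.5 * logdet_rows(xx, p)
}

# parabolic refinement of a grid argmax
refine_argmax <- function(logphi_grid, apl_mat) {
  idx <- max.col(apl_mat, ties.method = "first")
  n <- length(logphi_grid)
  out <- logphi_grid[idx]
  interior <- idx > 1L & idx < n
  i <- idx[interior]
  rows <- which(interior)
  y1 <- apl_mat[cbind(rows, i - 1L)]
  y2 <- apl_mat[cbind(rows, i)]
  y3 <- apl_mat[cbind(rows, i + 1L)]
  h <- logphi_grid[2] - logphi_grid[1]
  denom <- y1 - 2 * y2 + y3
  shift <- ifelse(abs(denom) > 1e-12, 0.5 * h * (y1 - y3) / denom, 0)
  out[interior] <- logphi_grid[i] + pmax(pmin(shift, h), -h)
  out
}

# IRLS fit of per-gene NB GLMs with log link and log(sf) offset.
# Returns list(beta = G x p, mu = G x n, converged, cov_list?)
fit_nb_glms <- function(m, X, sf, phi, contrast_vec = NULL, max_iter = 30L) {
  G <- nrow(m); n <- ncol(m); p <- ncol(X)
  off <- log(sf)
  beta <- matrix(0, G, p)
  mu <- matrix(0, G, n)
  se_contrast <- rep(NA_real_, G)
  converged <- rep(FALSE, G)
  phi <- rep_len(phi, G)
  for (g in seq_len(G)) {
    y <- m[g, ]
    b <- tryCatch(
      stats::lm.fit(X, log((y + 0.5) / sf))$coefficients,
      error = function(e) rep(0, p)
    )
    b[is.na(b)] <- 0
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      eta <- pmin(pmax(drop(X %*% b) + off, -30), 30)
      mug <- exp(eta)
      w <- mug / (1 + phi[g] * mug)
      z <- (eta - off) + (y - mug) / mug
      fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
      if (is.null(fit)) break
      bnew <- fit$coefficients
      bnew[is.na(bnew)] <- 0
      delta <- max(abs(bnew - b))
      b <- bnew
      if (delta < 1e-6) { ok <- TRUE; break }
    }
    eta <- pmin(pmax(drop(X %*% b) + off, -30), 30)
    mu[g, ] <- exp(eta)
    beta[g, ] <- b
    converged[g] <- ok
    if (!is.null(contrast_vec)) {
      w <- mu[g, ] / (1 + phi[g] * mu[g, ])
      info <- crossprod(X, X * w)
      cv <- tryCatch(drop(t(contrast_vec) %*% solve(info, contrast_vec)),
                     error = function(e) NA_real_)
      se_contrast[g] <- if (is.finite(cv) && cv > 0) sqrt(cv) else NA_real_
    }
  }
  list(beta = beta, mu = mu, converged = converged, se = se_contrast)
}

# parametric dispersion trend disp = a0 + a1/mean via Gamma GLM with
# identity link, iterating outlier exclusion; falls back to the median
fit_disp_trend <- function(base_mean, disp_gw) {
  use <- is.finite(disp_gw) & disp_gw > 1e-7 & base_mean > 0
  d <- disp_gw[use]; mu <- base_mean[use]
  coefs <- c(a0 = median(d), a1 = 0)
  for (it in 1:10) {
    fit <- tryCatch(
      stats::glm(d ~ I(1 / mu), family = stats::Gamma(link = "identity"),
                 start = pmax(coefs, 1e-6)),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(fit)) break
    newco <- pmax(stats::coef(fit), 0)
    pred <- newco[1] + newco[2] / mu
    ratio <- d / pmax(pred, 1e-10)
    keep <- ratio < 1e4 & ratio > 1e-4
    if (all(keep) || sum(keep) < 10) { coefs <- newco; break }
    d <- d[keep]; mu <- mu[keep]
    coefs <- newco
  }
  function(bm) pmax(coefs[1] + coefs[2] / pmax(bm, 1e-8), 1e-8)
}

build_design <- function(designs, model, contrast) {
  model <- match.arg(model, c("two_factor", "six_level", "population"))
  if (model == "two_factor") {
    pop <- factor(designs$population, levels = unique(designs$population))
    sex <- factor(designs$sex, levels = unique(designs$sex))
    X <- model.matrix(~ pop + sex)
    contrast <- contrast %||% "population"
    cn <- if (contrast == "population") 2L
          else if (contrast == "sex") 3L
          else abort("contrast must be 'population' or 'sex' for two_factor")
    cvec <- as.numeric(seq_len(ncol(X)) == cn)
    label <- sprintf("%s: %s vs %s", contrast,
                     if (contrast == "population") levels(pop)[2] else levels(sex)[2],
                     if (contrast == "population") levels(pop)[1] else levels(sex)[1])
  } else if (model == "six_level") {
    grp <- factor(paste(designs$population, designs$condition, sep = "."))
    X <- model.matrix(~ 0 + grp)
    colnames(X) <- levels(grp)
    if (is.null(contrast) || length(contrast) != 2L ||
        !all(contrast %in% levels(grp))) {
      abort(sprintf("contrast must name two of the groups: %s",
                    paste(levels(grp), collapse = ", ")))
    }
    cvec <- as.numeric(levels(grp) == contrast[1]) -
      as.numeric(levels(grp) == contrast[2])
    label <- sprintf("group: %s vs %s", contrast[1], contrast[2])
  } else {
    pop <- factor(designs$population, levels = unique(designs$population))
    X <- model.matrix(~ pop)
    cvec <- as.numeric(seq_len(ncol(X)) == 2L)
    label <- sprintf("population: %s vs %s", levels(pop)[2], levels(pop)[1])
  }
  if (qr(X)$rank < ncol(X)) abort("design matrix is not full rank")
  list(X = X, cvec = cvec, label = label)
}

#' Negative-binomial Wald test for differential expression
#'
#' Fits a per-gene NB GLM (log link, size-factor offsets) under either a
#' two-factor population + sex design, a one-factor six-level
#' population-by-stage design, or a plain population design, estimates
#' dispersions by Cox-Reid adjusted profile likelihood with MAP shrinkage
#' toward a parametric mean-dispersion trend, and tests the contrast
#' coefficient with a Wald z statistic. Benjamini-Hochberg adjustment is
#' applied after optional independent filtering of low-count genes.
#'
#' @param counts count tibble (`gene_id` + sample columns, replicates
#'   unpooled)
#' @param designs design tibble matching the count columns
#' @param model `"two_factor"` (population + sex), `"six_level"`
#'   (population x stage grouping) or `"population"`
#' @param contrast for `two_factor`: `"population"` (default) or
#'   `"sex"`; for `six_level`: a length-2 character vector of group
#'   levels (`"population.condition"`), first minus second
#' @param fdr target false discovery rate (default 0.05)
#' @param independent_filtering drop low-count genes before BH using the
#'   rejection-maximizing mean-count threshold (default TRUE)
#' @return object of class `neorf_de`; see [tidy.neorf_de()]
#' @export
nb_wald_test <- function(counts, designs, model = "two_factor",
                         contrast = NULL, fdr = 0.05,
                         independent_filtering = TRUE) {
  m_all <- counts_to_matrix(counts)
  m_all <- m_all[, designs$sample_id, drop = FALSE]
  des <- build_design(designs, model, contrast)
  X <- des$X
  if (any(colSums(abs(X)) > 0 & apply(X != 0, 2, sum) < 2)) {
    abort("each tested level needs at least 2 samples")
  }
  sf <- size_factors(counts)[designs$sample_id]
  keep <- rowSums(m_all) > 0
  m <- m_all[keep, , drop = FALSE]
  G <- nrow(m)
  base_mean_all <- rowMeans(sweep(m_all, 2, sf, "/"))
  base_mean <- base_mean_all[keep]

  # moment-based starting dispersion, then CR-APL on a log grid
  norm <- sweep(m, 2, sf, "/")
  mom <- pmax((apply(norm, 1, var) - rowMeans(norm)) / rowMeans(norm)^2, 1e-4)
  phi0 <- median(mom, na.rm = TRUE)
  fit0 <- fit_nb_glms(m, X, sf, phi0)
  grid <- seq(log(1e-4), log(3), length.out = 50L)
  apl <- vapply(grid, function(lp) apl_at(m, fit0$mu, exp(lp), X),
                numeric(G))
  disp_gw <- exp(refine_argmax(grid, apl))

  trend_fun <- fit_disp_trend(base_mean, disp_gw)
  disp_tr <- trend_fun(base_mean)
  lr <- log(disp_gw) - log(disp_tr)
  samp_var <- trigamma(max((ncol(m) - ncol(X)) / 2, 0.5))
  # prior width from the excess spread of gene-wise log dispersions over
  # their sampling variance; a small floor keeps the MAP step proper
  sigma2 <- max(stats::mad(lr, na.rm = TRUE)^2 - samp_var, 0.05)
  pen <- outer(log(disp_tr), grid, function(a, b) (b - a)^2) / (2 * sigma2)
  disp_map <- exp(refine_argmax(grid, apl - pen))

  fit <- fit_nb_glms(m, X, sf, disp_map, contrast_vec = des$cvec)
  lfc_ln <- drop(fit$beta %*% des$cvec)
  lfc <- lfc_ln / log(2)
  se <- fit$se / log(2)
  stat <- lfc / se
  pvalue <- 2 * pnorm(-abs(stat))
  pvalue[!fit$converged | !is.finite(pvalue)] <- NA_real_

  res <- tibble(
    gene_id = rownames(m), contrast = des$label,
    base_mean = base_mean, lfc = lfc, se = se, stat = stat,
    pvalue = pvalue
  )
  # all-zero genes are reported but untestable
  if (any(!keep)) {
    res <- dplyr::bind_rows(res, tibble(
      gene_id = rownames(m_all)[!keep], contrast = des$label,
      base_mean = 0, lfc = NA_real_, se = NA_real_, stat = NA_real_,
      pvalue = NA_real_
    ))
  }
  res <- res %>% arrange(match(gene_id, rownames(m_all)))
  res <- apply_independent_filter(res, alpha = fdr,
                                  enabled = independent_filtering)
  structure(list(
    results = res, model = model, contrast = des$label, alpha = fdr,
    dispersion = tibble(gene_id = rownames(m), gene_wise = disp_gw,
                        trend = disp_tr, map = disp_map),
    size_factors = sf,
    lfc_test = "Wald z on log2 fold change (Welch t for magnitude tests)"
  ), class = "neorf_de")
}

apply_independent_filter <- function(res, alpha = 0.05, enabled = TRUE) {
  testable <- !is.na(res$pvalue)
  if (!enabled) {
    res$filtered <- !testable
    res$padj <- NA_real_
    res$padj[testable] <- bh_adjust(res$pvalue[testable])
    return(res)
  }
  thetas <- seq(0, 0.95, by = 0.05)
  cuts <- quantile(res$base_mean[testable], thetas, names = FALSE)
  n_rej <- vapply(cuts, function(ct) {
    use <- testable & res$base_mean >= ct
    sum(bh_adjust(res$pvalue[use]) <= alpha, na.rm = TRUE)
  }, 0L)
  ct <- cuts[which.max(n_rej)]
  use <- testable & res$base_mean >= ct
  res$filtered <- !use
  res$padj <- NA_real_
  res$padj[use] <- bh_adjust(res$pvalue[use])
  attr(res, "filter_threshold") <- ct
  res
}

#' Independent filtering of a finished result table
#'
#' Re-applies the rejection-maximizing low-count filter and BH adjustment
#' to a per-gene result tibble (columns `base_mean`, `pvalue`).
#'
#' @param results tibble with `base_mean` and `pvalue`
#' @param alpha FDR target used in the threshold search (default 0.05)
#' @return the tibble with `filtered` and `padj` recomputed
#' @export
independent_filter <- function(results, alpha = 0.05) {
  apply_independent_filter(results, alpha = alpha, enabled = TRUE)
}

#' @exportS3Method generics::tidy
tidy.neorf_de <- function(x, ...) x$results

#' @exportS3Method generics::glance
glance.neorf_de <- function(x, ...) {
  tibble(
    model = x$model, contrast = x$contrast, alpha = x$alpha,
    n_genes = nrow(x$results),
    n_tested = sum(!x$results$filtered),
    n_de = sum(x$results$padj <= x$alpha, na.rm = TRUE)
  )
}

#' @export
print.neorf_de <- function(x, ...) {
  cat(sprintf("<neorf_de> %s model, contrast %s\n", x$model, x$contrast))
  cat(sprintf("  %d genes (%d tested after filtering), %d DE at FDR %.2g\n",
              nrow(x$results), sum(!x$results$filtered),
              sum(x$results$padj <= x$alpha, na.rm = TRUE), x$alpha))
  invisible(x)
}

#' Per-gene DE calls from a fitted test
#' @param fit `neorf_de` object
#' @param alpha FDR threshold (defaults to the fit's)
#' @return tibble `gene_id`, `de` (logical; `FALSE` for filtered genes)
#' @export
de_calls <- function(fit, alpha = fit$alpha) {
  fit$results %>%
    mutate(de = !is.na(padj) & padj <= alpha) %>%
    select(gene_id, de)
}

#' Gene-class enrichment among differentially expressed genes
#'
#' For each gene class, compares the observed number of DE genes to the
#' number expected at the global DE proportion among all analyzed genes,
#' with a 1-df goodness-of-fit chi-square (no continuity correction) and
#' BH adjustment across classes.
#'
#' @param de_flags tibble with `gene_id` and logical `de` (analyzed genes
#'   only, e.g. from [de_calls()] with filtered genes removed)
#' @param classes tibble with `gene_id`, `gene_class`
#' @return `neorf_enrichment` tibble: per class `n_analyzed`, `n_de`,
#'   `n_expected`, `chi2`, `p_value`, `p_adj`, `direction`, `low_expected`
#' @export
class_enrichment <- function(de_flags, classes) {
  x <- de_flags %>% inner_join(classes, by = "gene_id")
  if (sum(x$de) < 1) abort("no DE genes overall")
  p_global <- mean(x$de)
  out <- x %>%
    group_by(gene_class) %>%
    summarise(n_analyzed = n(), n_de = sum(de), .groups = "drop") %>%
    mutate(n_expected = n_analyzed * p_global)
  gof <- gof_proportion_test(out$n_de, out$n_analyzed, out$n_expected)
  out <- out %>%
    mutate(chi2 = gof$chi2, p_value = gof$p_value, direction = gof$direction,
           p_adj = bh_adjust(p_value),
           low_expected = n_expected < 1 | (n_analyzed - n_expected) < 1) %>%
    select(gene_class, n_analyzed, n_de, n_expected, chi2, p_value, p_adj,
           direction, low_expected)
  class(out) <- c("neorf_enrichment", class(out))
  out
}

#' Compare |LFC| magnitude between gene classes
#'
#' Welch two-sample t-tests on the absolute log2 fold changes of DE genes
#' for every pair of classes, BH-adjusted across the pairs.
#'
#' @param results per-gene result tibble (e.g. `tidy()` of a fit) with
#'   `gene_id`, `lfc`, `padj`
#' @param classes tibble with `gene_id`, `gene_class`
#' @param alpha FDR threshold defining the DE set (default 0.05)
#' @return tibble: `class_a`, `class_b`, `n_a`, `n_b`, `t`, `df`,
#'   `p_value`, `p_adj`, `reason` (NA unless the test was not possible)
#' @export
lfc_magnitude_test <- function(results, classes, alpha = 0.05) {
  x <- results %>%
    inner_join(classes, by = "gene_id") %>%
    filter(!is.na(padj), padj <= alpha) %>%
    mutate(abs_lfc = abs(lfc))
  cls <- sort(unique(classes$gene_class))
  pairs <- utils::combn(cls, 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(pr) {
    a <- x$abs_lfc[x$gene_class == pr[1]]
    b <- x$abs_lfc[x$gene_class == pr[2]]
    if (length(a) < 2 || length(b) < 2) {
      return(tibble(class_a = pr[1], class_b = pr[2],
                    n_a = length(a), n_b = length(b),
                    t = NA_real_, df = NA_real_, p_value = NA_real_,
                    reason = "fewer than 2 DE genes in a class"))
    }
    if (sd(a) == 0 && sd(b) == 0 && isTRUE(all.equal(mean(a), mean(b)))) {
      return(tibble(class_a = pr[1], class_b = pr[2],
                    n_a = length(a), n_b = length(b),
                    t = 0, df = length(a) + length(b) - 2, p_value = 1,
                    reason = NA_character_))
    }
    tt <- stats::t.test(a, b)  # Welch
    tibble(class_a = pr[1], class_b = pr[2],
           n_a = length(a), n_b = length(b),
           t = unname(tt$statistic), df = unname(tt$parameter),
           p_value = tt$p.value, reason = NA_character_)
  })
  dplyr::bind_rows(rows) %>% mutate(p_adj = bh_adjust(p_value))
}
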