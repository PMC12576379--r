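# Small shared statistics used across the enrichment, pN/pS and
# neighbor-gene analyses. All chi-square tests here are 1-df
# goodness-of-fit tests on a success/failure dichotomy, without
# continuity correction.

#' Goodness-of-fit test of an observed count against an expected count
#'
#' Tests whether `observed` successes out of `n` trials depart from an
#' expectation of `expected` successes, using a 1-df chi-square
#' goodness-of-fit statistic over the success/failure dichotomy,
#' \eqn{\chi^2 = \sum (O-E)^2/E}, with no continuity correction. This is
#' the test used for gene-class enrichment among differentially expressed
#' genes, intact-ORF enrichment, frequency-class enrichment, and
#' differential expression of neORF-neighboring genes.
#'
#' @param observed observed number of successes (vectorized)
#' @param n total number of trials
#' @param expected expected number of successes under the null
#' @return tibble with columns `observed`, `n`, `expected`, `chi2`,
#'   `p_value`, `direction` ("excess" or "paucity")
#' @export
#' @examples
#' gof_proportion_test(581, 2352, 459.02)
gof_proportion_test <- function(observed, n, expected) {
  stopifnot(all(n > 0), all(expected >= 0), all(expected <= n))
  o2 <- n - observed
  e2 <- n - expected
  chi2 <- (observed - expected)^2 / expected + (o2 - e2)^2 / e2
  chi2[expected == 0 | e2 == 0] <- NA_real_
  tibble(
    observed = observed, n = n, expected = expected,
    chi2 = chi2,
    p_value = pchisq(chi2, df = 1, lower.tail = FALSE),
    direction = if_else(observed >= expected, "excess", "paucity")
  )
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' No continuity correction (the form used to compare pN/pS between neORF
#' subsets).
#'
#' @param tab 2x2 numeric matrix of counts
#' @return tibble with `chi2`, `df`, `p_value`; `p_value` is `NA` with a
#'   warning when a marginal total is zero
#' @export
contingency_chi2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    warn("contingency table has a zero row or column; p-value undefined")
    return(tibble(chi2 = NA_real_, df = 1L, p_value = NA_real_))
  }
  exp_tab <- outer(rs, cs) / sum(tab)
  chi2 <- sum((tab - exp_tab)^2 / exp_tab)
  tibble(chi2 = chi2, df = 1L,
         p_value = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Standard step-up procedure: order the m raw p-values, multiply the i-th
#' smallest by m/i, enforce monotonicity from the largest down, cap at 1.
#' `NA` entries are ignored (they receive `NA` and do not count toward m).
#'
#' @param p numeric vector of raw p-values in \[0, 1\]
#' @return numeric vector of adjusted p-values, same length and order
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(out)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  out[ok] <- adj
  out
}
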