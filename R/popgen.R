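# Pooled-read polymorphism calling and Nei-Gojobori pN/pS. Polymorphisms
# require support from two independent fragments (mates of one fragment
# count once) out of at least four full-length reads; sites are
# classified by mutating the reference codon one substitution at a time
# under the standard code, with mutations to stop codons counted as
# nonsynonymous.

#' Collect full-length read sequences over an ORF
#'
#' Retains only fragments whose mate-union contiguously covers the entire
#' ORF (cat1 geometry); each fragment contributes one nucleotide sequence
#' across the ORF (read bases in reference order, deletions marked `-`).
#'
#' @param aln alignment tibble from [read_alignments()]
#' @param orf one row of [orf_models()] (or a list with `target_id`,
#'   `orf_start`, `orf_end`)
#' @return character vector of one sequence per spanning fragment
#' @export
collect_full_length <- function(aln, orf) {
  orf <- as.list(orf)
  sub <- aln %>% filter(target_id == orf$target_id)
  frags <- split(sub, sub$fragment_id)
  out <- purrr::map_chr(frags, function(pair) {
    fb <- fragment_blocks(pair, orf)
    if (!covers_interval(fb$cover, orf$orf_start, orf$orf_end)) {
      return(NA_character_)
    }
    b <- fb$blocks[[1]]
    paste(if_else(is.na(b$base), "-", b$base), collapse = "")
  })
  unname(out[!is.na(out)])
}

#' Call polymorphic sites from full-length pooled reads
#'
#' A site is called when at least `min_support` reads carry the same
#' alternate base and at least `min_reads` full-length reads are
#' available (with fewer reads, no site can be distinguished from a
#' sequencing or reverse-transcription error). Each called alternate is
#' classified synonymous/nonsynonymous by substituting it into the
#' reference codon (standard code).
#'
#' @param reads character vector of full-length ORF sequences (equal
#'   length; gap characters ignored per site)
#' @param ref_seq reference ORF nucleotide sequence
#' @param min_support minimum reads carrying the alternate (default 2)
#' @param min_reads minimum full-length reads (default 4)
#' @return `SiteCall` tibble: `pos` (0-based), `codon_index`,
#'   `codon_pos`, `ref_base`, `alt_base`, `n_support`, `n_reads`,
#'   `site_class`
#' @export
call_polymorphisms <- function(reads, ref_seq, min_support = 2,
                               min_reads = 4) {
  empty <- tibble(pos = integer(), codon_index = integer(),
                  codon_pos = integer(), ref_base = character(),
                  alt_base = character(), n_support = integer(),
                  n_reads = integer(), site_class = character())
  n_reads <- length(reads)
  if (n_reads < min_reads) return(empty)
  ref_seq <- toupper(ref_seq)
  L <- nchar(ref_seq)
  stopifnot(all(nchar(reads) == L))
  codons <- split_codons(ref_seq)
  mat <- do.call(rbind, strsplit(toupper(reads), ""))
  out <- vector("list", L)
  for (p0 in seq_len(L) - 1L) {
    col <- mat[, p0 + 1L]
    ref_base <- substr(ref_seq, p0 + 1L, p0 + 1L)
    alt_tab <- table(col[col %in% DNA_BASES & col != ref_base])
    alt_tab <- alt_tab[alt_tab >= min_support]
    if (length(alt_tab) == 0L) next
    ci <- p0 %/% 3L + 1L
    cp <- p0 %% 3L + 1L
    rows <- purrr::map(names(alt_tab), function(a) {
      mut <- codons[ci]
      substr(mut, cp, cp) <- a
      tibble(pos = p0, codon_index = ci, codon_pos = cp,
             ref_base = ref_base, alt_base = a,
             n_support = as.integer(alt_tab[[a]]), n_reads = n_reads,
             site_class = if (identical(codon_table[[mut]],
                                        codon_table[[codons[ci]]]))
               "synonymous" else "nonsynonymous")
    })
    out[[p0 + 1L]] <- dplyr::bind_rows(rows)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) empty else res
}

#' Nei-Gojobori synonymous and nonsynonymous site counts
#'
#' Each codon position contributes the fraction of its three possible
#' single-base substitutions that are synonymous to the synonymous site
#' count and the remainder to the nonsynonymous count; mutations creating
#' stop codons count as nonsynonymous. Totals satisfy
#' `n_sites + s_sites = 3 * codon count` exactly.
#'
#' @param sequence in-frame CDS (no internal stop; a terminal stop codon
#'   is allowed and excluded from the counts)
#' @return tibble with `n_sites`, `s_sites`, `n_codons`
#' @export
ng_site_counts <- function(sequence) {
  sequence <- toupper(sequence)
  codons <- split_codons(sequence)
  if (length(codons) > 0 && is_stop_codon(codons[length(codons)])) {
    codons <- codons[-length(codons)]
  }
  if (any(vapply(codons, is_stop_codon, TRUE))) {
    abort("internal stop codon in sequence")
  }
  s <- 0
  for (cod in codons) {
    aa <- codon_table[[cod]]
    for (cp in 1:3) {
      for (a in setdiff(DNA_BASES, substr(cod, cp, cp))) {
        mut <- cod
        substr(mut, cp, cp) <- a
        if (identical(codon_table[[mut]], aa)) s <- s + 1 / 3
      }
    }
  }
  n_codons <- length(codons)
  tibble(n_sites = 3 * n_codons - s, s_sites = s, n_codons = n_codons)
}

#' pN/pS from site calls and Nei-Gojobori site counts
#'
#' `pN = n_poly / n_sites`, `pS = s_poly / s_sites`. Departure from the
#' neutral expectation pN/pS = 1 is tested with a 1-df chi-square
#' goodness-of-fit of the observed (nonsynonymous, synonymous)
#' polymorphism counts against expectations proportional to
#' (n_sites, s_sites), without continuity correction. With `pS = 0` the
#' ratio is undefined (`NA`, flagged) but the test is still computed.
#'
#' @param calls `SiteCall` tibble from [call_polymorphisms()] (possibly
#'   pooled over neORFs)
#' @param sites site-count tibble from [ng_site_counts()] (possibly
#'   summed over neORFs)
#' @return one-row `PnPsResult` tibble
#' @export
pnps <- function(calls, sites) {
  n_sites <- sum(sites$n_sites)
  s_sites <- sum(sites$s_sites)
  n_poly <- sum(calls$site_class == "nonsynonymous")
  s_poly <- sum(calls$site_class == "synonymous")
  pN <- n_poly / n_sites
  pS <- s_poly / s_sites
  ratio_defined <- s_poly > 0
  tot <- n_poly + s_poly
  if (tot > 0) {
    e_n <- tot * n_sites / (n_sites + s_sites)
    e_s <- tot - e_n
    chi2 <- (n_poly - e_n)^2 / e_n + (s_poly - e_s)^2 / e_s
    p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  } else {
    chi2 <- NA_real_; p <- NA_real_
  }
  tibble(
    n_sites = n_sites, s_sites = s_sites,
    n_poly = n_poly, s_poly = s_poly,
    pN = pN, pS = pS,
    ratio = if (ratio_defined) pN / pS else NA_real_,
    ratio_defined = ratio_defined,
    gof_chi2 = chi2, gof_p = p
  )
}

#' Compare pN/pS between two neORF subsets
#'
#' 2x2 contingency chi-square (no continuity correction) on the
#' (nonsynonymous, synonymous) polymorphism counts of the two groups.
#'
#' @param calls_a,calls_b `SiteCall` tibbles of the two groups
#' @return tibble from [contingency_chi2()]
#' @export
compare_pnps <- function(calls_a, calls_b) {
  stopifnot(nrow(calls_a) >= 1, nrow(calls_b) >= 1)
  tab <- rbind(
    a = c(nonsyn = sum(calls_a$site_class == "nonsynonymous"),
          syn = sum(calls_a$site_class == "synonymous")),
    b = c(sum(calls_b$site_class == "nonsynonymous"),
          sum(calls_b$site_class == "synonymous"))
  )
  contingency_chi2(tab)
}
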