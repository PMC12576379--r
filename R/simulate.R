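# Forward simulator: annotations, pooled NB count matrices, read-pair
# alignments over short ORFs with controllable intactness states, and
# polymorphic read pools with known per-site truth. Every emitted record
# carries exactly one ground-truth entry, so each analysis stage can be
# tested against what was actually generated.

#' Simulation configuration
#'
#' Default values define the simulated study conditions: two populations
#' (derived European, ancestral African), pooled libraries of 8-12 inbred
#' lines, 3 biological replicates, seven original annotation lines, 150-nt
#' paired reads with ~250-nt fragments, neORFs of 90-600 nt. Count
#' parameters invert the negative-binomial model used for testing
#' (per-gene baseline around `baseline_mean`, gene-wise dispersion
#' `dispersion`, log2 population effects drawn from
#' `lfc_distribution`).
#'
#' @param n_pc,n_nc,n_neorf numbers of protein-coding genes, ncRNAs and
#'   neORF orthogroups
#' @param neorf_length_range neORF length range in nt (each length is
#'   rounded to a multiple of 3)
#' @param n_lines number of original annotation lines (presence vector
#'   length)
#' @param replicates biological replicates per (population, sex/condition)
#' @param pool_lines inbred lines pooled per library (8-12)
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2)
#' @param baseline_mean median per-gene baseline expected count
#' @param baseline_sdlog log-sd of the per-gene baseline spread
#' @param de_fraction named vector: per-class probability a gene carries a
#'   true population effect
#' @param lfc_mean,lfc_sd mean and sd of the absolute true log2 fold
#'   change for DE genes (sign is random)
#' @param expression_turnover_prob per-line probability that a line
#'   carrying an neORF does not express it
#' @param read_length read length in nt
#' @param fragment_mean,fragment_sd fragment (insert) length distribution
#'   in nt (truncated so both mates fit the transcript)
#' @param pn_rate,ps_rate per-substitution probabilities that a
#'   nonsynonymous / synonymous alternate allele segregates in the pool
#' @param seed integer seed used by the generators (kept below 2^31)
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_pc = 200, n_nc = 50, n_neorf = 100,
                       neorf_length_range = c(90, 600),
                       n_lines = 7, replicates = 3, pool_lines = 12,
                       dispersion = 0.05, baseline_mean = 500,
                       baseline_sdlog = 1,
                       de_fraction = c(PC = 0.10, ncRNA = 0.05, neORF = 0.20),
                       lfc_mean = 1, lfc_sd = 0.5,
                       expression_turnover_prob = 0.3,
                       read_length = 150,
                       fragment_mean = 250, fragment_sd = 40,
                       pn_rate = 0.01, ps_rate = 0.01,
                       seed = 1L) {
  cfg <- list(
    n_pc = n_pc, n_nc = n_nc, n_neorf = n_neorf,
    neorf_length_range = neorf_length_range,
    n_lines = n_lines, replicates = replicates, pool_lines = pool_lines,
    dispersion = dispersion, baseline_mean = baseline_mean,
    baseline_sdlog = baseline_sdlog,
    de_fraction = de_fraction, lfc_mean = lfc_mean, lfc_sd = lfc_sd,
    expression_turnover_prob = expression_turnover_prob,
    read_length = read_length,
    fragment_mean = fragment_mean, fragment_sd = fragment_sd,
    pn_rate = pn_rate, ps_rate = ps_rate, seed = as.integer(seed)
  )
  stopifnot(
    cfg$read_length >= 30,
    cfg$pool_lines >= 8, cfg$pool_lines <= 12,
    all(cfg$de_fraction >= 0 & cfg$de_fraction <= 1),
    cfg$expression_turnover_prob >= 0, cfg$expression_turnover_prob <= 1,
    cfg$pn_rate >= 0, cfg$pn_rate <= 1, cfg$ps_rate >= 0, cfg$ps_rate <= 1,
    cfg$neorf_length_range[1] >= 90
  )
  if (any(cfg$neorf_length_range %% 3 != 0)) {
    abort("neorf_length_range bounds must be divisible by 3")
  }
  structure(cfg, class = "sim_config")
}

with_sim_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Simulate the sample design table
#'
#' @param config a [sim_config()]
#' @param populations,sexes,conditions factor levels to cross; set
#'   `sexes = NA` for single-sex designs (larval/prepupal fat body style,
#'   where `conditions` carries the developmental stage)
#' @return `SampleDesign` tibble: `sample_id`, `population`, `sex`,
#'   `condition`, `replicate`, `pool_lines`
#' @export
simulate_design <- function(config = sim_config(),
                            populations = c("Eur", "Afr"),
                            sexes = c("M", "F"),
                            conditions = "15C") {
  grid <- tidyr::expand_grid(
    population = populations, sex = sexes, condition = conditions,
    replicate = seq_len(config$replicates)
  )
  grid %>%
    mutate(
      pool_lines = config$pool_lines,
      sample_id = paste(population,
                        if_else(is.na(sex), "X", sex),
                        condition, paste0("r", replicate), sep = "_")
    ) %>%
    select(sample_id, population, sex, condition, replicate, pool_lines)
}

#' Simulate gene annotations with ground truth
#'
#' Emits protein-coding genes, ncRNAs and neORF orthogroups. neORF
#' sequences start with ATG, end with a stop codon and are stop-free in
#' frame 0. Line presence over the `n_lines` annotation lines is drawn so
#' that the first seven neORFs take presence counts 1..7 (all frequency
#' classes populated), the rest uniformly. Per-line expression states
#' apply the expression-turnover probability. PC genes and neORFs receive
#' non-overlapping genome placements; each neORF is placed near a PC gene
#' so that the 1-kb neighbor analysis has signal.
#'
#' @param config a [sim_config()]
#' @param seed seed (defaults to `config$seed`)
#' @return list with `genes` (gene tibble) and `truth` (per-neORF presence
#'   and expression-state strings)
#' @export
simulate_annotation <- function(config = sim_config(), seed = config$seed) {
  with_sim_seed(seed, {
    pc_len <- pmax(300L, as.integer(round(exp(rnorm(config$n_pc, log(1500), 0.5)) / 3) * 3))
    nc_len <- pmax(200L, as.integer(round(exp(rnorm(config$n_nc, log(800), 0.5)))))
    lo <- config$neorf_length_range[1] / 3
    hi <- config$neorf_length_range[2] / 3
    ne_len <- 3L * as.integer(sample(lo:hi, config$n_neorf, replace = TRUE))
    ne_seq <- vapply(ne_len, random_orf, "")

    # line presence: first 7 neORFs cover popcounts 1..7, rest uniform
    popcounts <- c(seq_len(min(7L, config$n_neorf)),
                   if (config$n_neorf > 7L)
                     sample(config$n_lines, config$n_neorf - 7L, replace = TRUE))
    presence <- vapply(popcounts, function(k) {
      v <- rep("0", config$n_lines)
      v[sample(config$n_lines, k)] <- "1"
      paste(v, collapse = "")
    }, "")
    # per-line expression state: a carrying line is silent with
    # probability expression_turnover_prob
    expr_state <- vapply(presence, function(p) {
      bits <- strsplit(p, "")[[1]] == "1"
      on <- bits & (runif(length(bits)) > config$expression_turnover_prob)
      paste(as.integer(on), collapse = "")
    }, "", USE.NAMES = FALSE)

    # placements: PC genes tiled along a chromosome with random gaps;
    # each neORF dropped near (or overlapping the flank of) a PC gene
    gap <- sample(200:5000, config$n_pc, replace = TRUE)
    pc_start <- cumsum(gap + dplyr::lag(pc_len, default = 0L))
    pc_ivl <- tibble(chrom = "2L", start = pc_start, end = pc_start + pc_len,
                     strand = sample(c("+", "-"), config$n_pc, replace = TRUE))
    anchor <- sample(config$n_pc, config$n_neorf, replace = TRUE)
    offset <- sample(c(-1, 1), config$n_neorf, replace = TRUE) *
      sample(0:3000, config$n_neorf, replace = TRUE)
    ne_start <- pmax(0L, as.integer(pc_ivl$end[anchor] + offset))
    genes <- dplyr::bind_rows(
      tibble(gene_id = sprintf("pc%04d", seq_len(config$n_pc)),
             gene_class = "PC", orthogroup_id = NA_character_,
             cds_length = pc_len, sequence = NA_character_,
             chrom = pc_ivl$chrom, start = pc_ivl$start, end = pc_ivl$end,
             strand = pc_ivl$strand, line_presence = NA_character_),
      tibble(gene_id = sprintf("nc%04d", seq_len(config$n_nc)),
             gene_class = "ncRNA", orthogroup_id = NA_character_,
             cds_length = nc_len, sequence = NA_character_,
             chrom = NA_character_, start = NA_integer_, end = NA_integer_,
             strand = NA_character_, line_presence = NA_character_),
      tibble(gene_id = sprintf("og%04d", seq_len(config$n_neorf)),
             gene_class = "neORF",
             orthogroup_id = sprintf("og%04d", seq_len(config$n_neorf)),
             cds_length = ne_len, sequence = ne_seq,
             chrom = "2L", start = ne_start, end = ne_start + ne_len,
             strand = "+", line_presence = presence)
    )
    truth <- tibble(
      gene_id = sprintf("og%04d", seq_len(config$n_neorf)),
      line_presence = presence,
      expression_state = expr_state,
      lines_present = popcounts,
      lines_expressing = popcount_presence(expr_state)
    )
    list(genes = validate_genes(genes), truth = truth)
  })
}

#' Simulate pooled NB count matrices with ground truth
#'
#' Counts are drawn NB with mean
#' `baseline * 2^(LFC * I(population == Afr)) * size_factor * pool_fraction`
#' and the configured dispersion. True-null genes have LFC exactly 0. For
#' neORFs the pool mean scales linearly with the fraction of pool lines
#' expressing the orthogroup (drawn once per gene from the per-line
#' expression probability, shared across samples so that the only
#' between-population signal is the true LFC).
#'
#' @param genes gene tibble from [simulate_annotation()]
#' @param designs design tibble from [simulate_design()]
#' @param config a [sim_config()]
#' @param seed seed (defaults to `config$seed + 1`)
#' @return list with `counts` (tibble) and `truth` (per-gene `true_de`,
#'   `true_lfc`, `pool_fraction`, `baseline`, plus per-sample size factors
#'   as attribute columns in `sample_truth`)
#' @export
simulate_counts <- function(genes, designs, config = sim_config(),
                            seed = config$seed + 1L) {
  stopifnot(length(unique(designs$population)) >= 2)
  with_sim_seed(seed, {
    g <- nrow(genes)
    de_frac <- config$de_fraction[genes$gene_class]
    de_frac[is.na(de_frac)] <- 0
    true_de <- runif(g) < de_frac
    lfc_abs <- abs(rnorm(g, config$lfc_mean, config$lfc_sd))
    true_lfc <- if_else(true_de,
                        sample(c(-1, 1), g, replace = TRUE) * lfc_abs, 0)
    baseline <- exp(rnorm(g, log(config$baseline_mean), config$baseline_sdlog))

    # pooled-expression fraction for neORFs: each pooled line expresses
    # the orthogroup with probability (lines_expressing / n_lines); the
    # realized fraction is shared across samples
    p_expr <- if_else(
      genes$gene_class == "neORF",
      popcount_presence(if_else(is.na(genes$line_presence), "0000000",
                                genes$line_presence)) / config$n_lines *
        (1 - config$expression_turnover_prob),
      1
    )
    pool_fraction <- if_else(
      genes$gene_class == "neORF",
      rbinom(g, designs$pool_lines[1], p_expr) / designs$pool_lines[1],
      1
    )

    sf <- exp(rnorm(nrow(designs), 0, 0.15))
    sf <- sf / exp(mean(log(sf)))
    afr <- as.numeric(designs$population == "Afr")
    mu <- outer(baseline * pool_fraction, sf) *
      2^(outer(true_lfc, afr))
    counts <- matrix(
      rnbinom(length(mu), mu = mu,
              size = if (config$dispersion > 0) 1 / config$dispersion else Inf),
      nrow = g
    )
    # dispersion == 0 is the Poisson limit
    if (config$dispersion == 0) {
      counts <- matrix(stats::rpois(length(mu), mu), nrow = g)
    }
    colnames(counts) <- designs$sample_id
    rownames(counts) <- genes$gene_id
    list(
      counts = matrix_to_counts(counts),
      truth = tibble(gene_id = genes$gene_id, gene_class = genes$gene_class,
                     true_de = true_de, true_lfc = true_lfc,
                     baseline = baseline, pool_fraction = pool_fraction),
      sample_truth = tibble(sample_id = designs$sample_id, size_factor = sf)
    )
  })
}

# map molecule coordinates to reference coordinates for the one-base
# deletion edit (frameshift state)
mol_to_ref <- function(pos0, del_ref) {
  if (is.na(del_ref)) pos0 else if_else(pos0 >= del_ref, pos0 + 1L, pos0)
}

apply_state_edit <- function(sequence, state) {
  n <- nchar(sequence)
  n_codons <- n / 3L
  switch(state,
    intact = list(mol = sequence, del_ref = NA_integer_, edit_codon = NA_integer_),
    internal_stop = {
      # replace one internal codon (not first, not last) with TAA
      k <- sample(2:(n_codons - 1L), 1L)
      mol <- paste0(substr(sequence, 1L, (k - 1L) * 3L), "TAA",
                    substr(sequence, k * 3L + 1L, n))
      list(mol = mol, del_ref = NA_integer_, edit_codon = k)
    },
    frameshift = {
      # delete one base in the interior
      d <- sample(4:(n - 4L), 1L)  # 1-based position to delete
      mol <- paste0(substr(sequence, 1L, d - 1L), substr(sequence, d + 1L, n))
      list(mol = mol, del_ref = d - 1L, edit_codon = NA_integer_)
    },
    no_start = {
      # mutate the start codon so it is no longer ATG
      mol <- paste0("ATA", substr(sequence, 4L, n))
      list(mol = mol, del_ref = NA_integer_, edit_codon = 1L)
    },
    abort(sprintf("unknown state '%s'", state))
  )
}

#' Simulate read pairs over an neORF with a known intactness state
#'
#' A state-specific edit is applied to a copy of the annotated sequence
#' (one in-frame TAA introduced; one base deleted; the ATG mutated) and
#' paired reads are drawn from the edited molecule with uniform fragment
#' positions. Fragment lengths follow a truncated normal, resampled until
#' both mates fit the transcript. Each pair's true step-1 category is
#' recorded from the generative state and fragment geometry.
#'
#' @param neorf one-row gene tibble (neORF with `sequence`)
#' @param state one of `"intact"`, `"internal_stop"`, `"frameshift"`,
#'   `"no_start"`
#' @param depth number of read pairs
#' @param config a [sim_config()]
#' @param seed seed (defaults to `config$seed + 2`)
#' @return list with `pairs` (alignment tibble in [read_alignments()]
#'   layout) and `truth` (per-fragment state, geometry and true category)
#' @export
simulate_read_pairs <- function(neorf, state = "intact", depth = 20,
                                config = sim_config(),
                                seed = config$seed + 2L) {
  stopifnot(nrow(neorf) == 1L, !is.na(neorf$sequence))
  if (depth <= 0) abort("depth must be positive")
  state <- match.arg(state, c("intact", "internal_stop", "frameshift", "no_start"))
  with_sim_seed(seed, {
    edit <- apply_state_edit(neorf$sequence, state)
    mol <- edit$mol
    mol_len <- nchar(mol)
    rl <- config$read_length
    orf_len <- neorf$cds_length

    pairs <- vector("list", depth)
    truths <- vector("list", depth)
    for (i in seq_len(depth)) {
      # truncated-normal fragment, resampled until positive, then capped
      # so both mates fit the transcript (short ORFs are spanned whole)
      repeat {
        fl <- round(rnorm(1, config$fragment_mean, config$fragment_sd))
        if (fl >= 30) break
      }
      fl <- min(fl, mol_len)
      fs <- sample.int(mol_len - fl + 1L, 1L) - 1L  # 0-based molecule coord
      fe <- fs + fl
      m1 <- c(fs, min(fs + rl, fe))
      m2 <- c(max(fe - rl, fs), fe)
      gap_free <- m2[1] <= m1[2]
      fid <- sprintf("%s_%s_frag%04d", neorf$gene_id, state, i)
      mk_mate <- function(lo, hi, mate_i) {
        seq_i <- substr(mol, lo + 1L, hi)
        rs <- mol_to_ref(lo, edit$del_ref)
        if (!is.na(edit$del_ref) && lo < edit$del_ref && hi > edit$del_ref) {
          left <- edit$del_ref - lo
          cig <- sprintf("%dM1D%dM", left, (hi - lo) - left)
          re <- rs + (hi - lo) + 1L
        } else {
          cig <- sprintf("%dM", hi - lo)
          re <- rs + (hi - lo)
        }
        tibble(fragment_id = fid, target_id = neorf$gene_id,
               mate = mate_i, start = rs, end = re, cigar = cig, seq = seq_i)
      }
      two_mates <- m2[1] > m1[1]  # distinct second mate only if it adds bases
      p <- if (two_mates) {
        dplyr::bind_rows(mk_mate(m1[1], m1[2], 1L), mk_mate(m2[1], m2[2], 2L))
      } else {
        mk_mate(m1[1], m1[2], 1L)
      }
      p$mate_count <- nrow(p)

      # true category from generative state and geometry (reference
      # coords). A region counts as observed when it lies within a single
      # mate, or within the union when the mates abut or overlap.
      ref_lo <- mol_to_ref(fs, edit$del_ref)
      ref_hi <- mol_to_ref(fe - 1L, edit$del_ref) + 1L
      covers_full <- gap_free && ref_lo == 0L && ref_hi == orf_len
      r1 <- c(mol_to_ref(m1[1], edit$del_ref),
              mol_to_ref(m1[2] - 1L, edit$del_ref) + 1L)
      r2 <- c(mol_to_ref(m2[1], edit$del_ref),
              mol_to_ref(m2[2] - 1L, edit$del_ref) + 1L)
      covered <- function(lo, hi) {
        (r1[1] <= lo && r1[2] >= hi) || (r2[1] <= lo && r2[2] >= hi) ||
          (gap_free && ref_lo <= lo && ref_hi >= hi)
      }
      true_cat <- if (state == "internal_stop" &&
                      covered((edit$edit_codon - 1L) * 3L, edit$edit_codon * 3L)) {
        "cat3"
      } else if (state == "no_start" && covered(0L, 3L)) {
        "cat4"
      } else if (state == "frameshift" && gap_free && ref_lo <= edit$del_ref &&
                 ref_hi > edit$del_ref &&
                 frameshift_hits_stop(mol, fs, fe, orf_len)) {
        "cat3"
      } else if (covers_full) {
        "cat1"
      } else {
        "cat2"
      }
      truths[[i]] <- tibble(
        fragment_id = fid, state = state,
        frag_start = ref_lo, frag_end = ref_hi,
        gap_free = gap_free, covers_full = covers_full,
        true_category = true_cat
      )
      pairs[[i]] <- p
    }
    list(pairs = dplyr::bind_rows(pairs), truth = dplyr::bind_rows(truths))
  })
}

# does scanning the edited molecule from the ORF-start anchor reveal a
# stop codon wholly inside the fragment before the annotated end?
frameshift_hits_stop <- function(mol, fs, fe, orf_len) {
  # codons anchored at molecule position 0 (ORF start); consider codons
  # fully inside [fs, fe)
  first <- ceiling(fs / 3)
  last <- floor(fe / 3) - 1L
  if (last < first) return(FALSE)
  for (k in first:last) {
    cod <- substr(mol, k * 3L + 1L, k * 3L + 3L)
    if (nchar(cod) == 3L && is_stop_codon(cod)) return(TRUE)
  }
  FALSE
}

#' Simulate a polymorphic pooled read set over an neORF
#'
#' Segregating sites are placed by per-substitution Bernoulli draws: each
#' of the three alternate bases at each position segregates with
#' probability `pn_rate` or `ps_rate` according to whether the mutated
#' codon changes the encoded amino acid (standard code; at most one
#' alternate is kept per site). Each segregating allele is assigned to a
#' random subset of 1..(n_lines-1) pool lines; full-length reads are then
#' sampled from line haplotypes with replacement.
#'
#' @param neorf one-row gene tibble (neORF with `sequence`)
#' @param n_lines lines in the pool
#' @param pn_rate,ps_rate per-substitution segregation probabilities
#' @param depth number of full-length reads
#' @param config a [sim_config()] (unused rates in the config are
#'   overridden by the explicit arguments)
#' @param seed seed (defaults to `config$seed + 3`)
#' @return list with `reads` (character vector of full-length sequences)
#'   and `truth` (per-site tibble: position, ref/alt base, class,
#'   pool frequency)
#' @export
simulate_polymorphic_pool <- function(neorf, n_lines = 12,
                                      pn_rate = NULL, ps_rate = NULL,
                                      depth = 30, config = sim_config(),
                                      seed = config$seed + 3L) {
  stopifnot(nrow(neorf) == 1L, !is.na(neorf$sequence))
  pn_rate <- pn_rate %||% config$pn_rate
  ps_rate <- ps_rate %||% config$ps_rate
  if (max(pn_rate, ps_rate) > 0.05) {
    warn("per-site rates > 0.05: double hits per codon will not be rare")
  }
  with_sim_seed(seed, {
    ref <- toupper(neorf$sequence)
    L <- nchar(ref)
    codons <- split_codons(ref)
    sites <- vector("list", L)
    for (p0 in seq_len(L) - 1L) {
      ci <- p0 %/% 3L + 1L
      cp <- p0 %% 3L + 1L
      ref_base <- substr(ref, p0 + 1L, p0 + 1L)
      alts <- setdiff(DNA_BASES, ref_base)
      hit <- character(0)
      for (a in alts) {
        mut <- codons[ci]
        substr(mut, cp, cp) <- a
        syn <- identical(codon_table[[mut]], codon_table[[codons[ci]]])
        rate <- if (syn) ps_rate else pn_rate
        if (runif(1) < rate) hit <- c(hit, a)
      }
      if (length(hit) > 0L) {
        a <- if (length(hit) == 1L) hit else sample(hit, 1L)
        mut <- codons[ci]
        substr(mut, cp, cp) <- a
        k <- sample.int(n_lines - 1L, 1L)
        sites[[p0 + 1L]] <- tibble(
          pos = p0, codon_index = ci, codon_pos = cp,
          ref_base = ref_base, alt_base = a,
          site_class = if (identical(codon_table[[mut]],
                                     codon_table[[codons[ci]]]))
            "synonymous" else "nonsynonymous",
          n_alt_lines = k, pool_freq = k / n_lines
        )
      }
    }
    truth <- dplyr::bind_rows(sites)
    haplotypes <- rep(ref, n_lines)
    if (nrow(truth) > 0L) {
      for (i in seq_len(nrow(truth))) {
        carriers <- sample.int(n_lines, truth$n_alt_lines[i])
        for (ln in carriers) {
          substr(haplotypes[ln], truth$pos[i] + 1L, truth$pos[i] + 1L) <-
            truth$alt_base[i]
        }
      }
    }
    reads <- haplotypes[sample.int(n_lines, depth, replace = TRUE)]
    list(reads = reads, truth = truth)
  })
}
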