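# Two-step read-pair classification of neORF coding potential.
# Step 1 places each ORF-overlapping pair into cat1-cat5 from alignment
# geometry and an in-frame stop-codon scan; step 2 refines cat1/cat2
# into catA-catE using a local protein alignment of the translated
# read against the orthogroup proteins.
#
# Precedence: cat5 (mates on different targets) over everything, then
# cat3 (stop-codon evidence is the strongest disqualifier), then cat4,
# then cat1/cat2 by coverage. Indels in the alignment shift the reading
# frame for downstream codons during the stop scan.

#' Build ORF models from a gene table
#'
#' @param genes gene tibble; rows with a `sequence` become ORF models
#' @return tibble: `target_id`, `orf_start` (0), `orf_end`, `sequence`,
#'   `protein` (translation without the terminal stop), `orthogroup_id`
#' @export
orf_models <- function(genes) {
  g <- genes %>% filter(!is.na(sequence))
  tibble(
    target_id = g$gene_id,
    orf_start = 0L,
    orf_end = g$cds_length,
    sequence = toupper(g$sequence),
    protein = sub("\\*$", "", vapply(g$sequence, translate_cds, "",
                                     USE.NAMES = FALSE)),
    orthogroup_id = if ("orthogroup_id" %in% names(g)) g$orthogroup_id
                    else g$gene_id
  )
}

#' Is an ORF detectable as full-length by a single fragment?
#'
#' A complete coding sequence can only be confirmed from a single
#' molecule, i.e. when the ORF fits within one read pair: length at most
#' twice the read length for paired data, at most the read length for
#' single-end data.
#'
#' @param orf_length ORF length(s) in nt
#' @param read_length read length in nt
#' @param paired paired-end data? (default TRUE)
#' @return logical vector
#' @export
orf_detectable <- function(orf_length, read_length, paired = TRUE) {
  stopifnot(read_length > 0)
  orf_length <= (if (paired) 2 else 1) * read_length
}

# expand one mate's alignment into per-base events in reference order:
# op M (read base consumed, ref consumed), I (read base at an insertion
# point), D (ref consumed, no base). Soft clips excluded.
aligned_events <- function(start, cigar, seq) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  ref <- start
  q <- 1L
  out <- vector("list", length(ops))
  for (i in seq_along(ops)) {
    len <- lens[i]
    op <- ops[i]
    if (op %in% c("M", "=", "X")) {
      out[[i]] <- tibble(op = "M", ref_pos = ref + seq_len(len) - 1L,
                         ins_idx = 0L,
                         base = strsplit(substr(seq, q, q + len - 1L), "")[[1]])
      ref <- ref + len; q <- q + len
    } else if (op == "I") {
      out[[i]] <- tibble(op = "I", ref_pos = ref, ins_idx = seq_len(len),
                         base = strsplit(substr(seq, q, q + len - 1L), "")[[1]])
      q <- q + len
    } else if (op %in% c("D", "N")) {
      out[[i]] <- tibble(op = "D", ref_pos = ref + seq_len(len) - 1L,
                         ins_idx = 0L, base = NA_character_)
      ref <- ref + len
    } else if (op == "S") {
      q <- q + len
    }
  }
  dplyr::bind_rows(out)
}

# merge both mates' events over the ORF window into contiguous blocks.
# Returns list(cover = integer ref positions covered (M or D),
# blocks = list of tibbles of molecule bases with their anchor ref pos)
fragment_blocks <- function(pair, orf) {
  ev <- purrr::pmap(list(pair$start, pair$cigar, pair$seq), aligned_events) %>%
    dplyr::bind_rows() %>%
    distinct(op, ref_pos, ins_idx, .keep_all = TRUE) %>%
    arrange(ref_pos, op != "I", ins_idx)  # insertions before the M at their point
  ev <- ev %>% filter(ref_pos >= orf$orf_start, ref_pos < orf$orf_end)
  cover <- sort(unique(ev$ref_pos[ev$op %in% c("M", "D")]))
  if (length(cover) == 0L) {
    return(list(cover = integer(0), blocks = list()))
  }
  # split covered positions into contiguous runs; attach molecule bases
  run_id <- cumsum(c(1L, diff(cover) != 1L))
  runs <- split(cover, run_id)
  blocks <- purrr::map(runs, function(r) {
    ev %>%
      filter(ref_pos >= r[1], ref_pos <= r[length(r)], op %in% c("M", "I", "D"))
  })
  list(cover = cover, blocks = blocks)
}

# molecule string of a block (read bases in order; deletions omitted)
block_molecule <- function(block) {
  paste(block$base[block$op != "D"], collapse = "")
}

# in-frame stop scan over one contiguous block. Frame is anchored at the
# ORF start on the reference; an indel inside the block shifts the frame
# for all downstream codons. Returns TRUE if a stop codon appears wholly
# inside the block before the annotated terminal codon.
block_has_internal_stop <- function(block, orf) {
  bases <- block$base[block$op != "D"]
  refp <- block$ref_pos[block$op != "D"]
  if (length(bases) < 3L) return(FALSE)
  first_ref <- block$ref_pos[1]
  frame <- (first_ref - orf$orf_start) %% 3L
  skip <- (3L - frame) %% 3L
  i <- skip + 1L
  while (i + 2L <= length(bases)) {
    cod <- paste(bases[i:(i + 2L)], collapse = "")
    if (is_stop_codon(cod) && refp[i] < orf$orf_end - 3L) return(TRUE)
    i <- i + 3L
  }
  FALSE
}

# does the fragment contiguously cover reference interval [lo, hi)?
covers_interval <- function(cover, lo, hi) {
  if (hi <= lo) return(TRUE)
  all((lo:(hi - 1L)) %in% cover)
}

#' Step-1 category of one read pair against its ORF model
#'
#' Exactly one of: mates on different targets (`cat5`); in-frame stop
#' codon inside the aligned ORF region before the annotated stop
#' (`cat3`); alignment spans the ORF start codon but the read lacks ATG
#' there (`cat4`); union of mate alignments covers the full ORF with no
#' internal gap (`cat1`); otherwise partial coverage with no stop
#' (`cat2`). Pairs with no ORF overlap are an error (prefilter callers).
#'
#' @param pair alignment tibble rows of one fragment (see
#'   [read_alignments()])
#' @param orf one row of [orf_models()]
#' @return list: `step1`, `start_covered` (ORF start codon contiguously
#'   covered with ATG present), `blocks`/`cover` (internal reuse)
#' @export
classify_step1 <- function(pair, orf) {
  if (length(unique(pair$target_id)) > 1L) {
    return(list(step1 = "cat5", start_covered = FALSE,
                cover = integer(0), blocks = list()))
  }
  fb <- fragment_blocks(pair, orf)
  if (length(fb$cover) == 0L) {
    abort(sprintf("fragment %s does not overlap the ORF of %s",
                  pair$fragment_id[1], orf$target_id))
  }
  # start codon: contiguously covered first three bases
  start_seen <- covers_interval(fb$cover, orf$orf_start, orf$orf_start + 3L)
  start_is_atg <- FALSE
  if (start_seen) {
    b1 <- fb$blocks[[1]]
    lead <- b1$base[b1$op != "D"]
    leadref <- b1$ref_pos[b1$op != "D"]
    sel <- which(leadref >= orf$orf_start)[1:3]
    if (!anyNA(sel)) {
      start_is_atg <- identical(paste(lead[sel], collapse = ""), "ATG")
    }
  }
  has_stop <- any(vapply(fb$blocks, block_has_internal_stop, TRUE, orf = orf))
  step1 <- if (has_stop) {
    "cat3"
  } else if (start_seen && !start_is_atg) {
    "cat4"
  } else if (covers_interval(fb$cover, orf$orf_start, orf$orf_end)) {
    "cat1"
  } else {
    "cat2"
  }
  list(step1 = step1, start_covered = start_seen && start_is_atg,
       cover = fb$cover, blocks = fb$blocks)
}

#' Translate the aligned ORF segment of a read pair
#'
#' When the alignment includes the ORF start, the anchored frame alone is
#' translated; otherwise the longest contiguously covered ORF segment is
#' translated in all three frames of the ORF strand and every candidate
#' peptide is returned. Segments shorter than one codon yield an empty
#' list.
#'
#' @param pair alignment tibble rows of one fragment
#' @param orf one row of [orf_models()]
#' @param step1 optional precomputed result of [classify_step1()]
#' @return character vector of candidate peptides (terminal stop trimmed)
#' @export
translate_aligned <- function(pair, orf, step1 = NULL) {
  s1 <- step1 %||% classify_step1(pair, orf)
  if (!s1$step1 %in% c("cat1", "cat2")) {
    abort("translate_aligned applies to cat1/cat2 pairs only")
  }
  if (length(s1$blocks) == 0L) return(character(0))
  if (s1$start_covered) {
    mol <- block_molecule(s1$blocks[[1]])
    pep <- sub("\\*+$", "", translate_cds(mol))
    return(if (nchar(pep) > 0) pep else character(0))
  }
  sizes <- vapply(s1$blocks, function(b) sum(b$op != "D"), 0L)
  mol <- block_molecule(s1$blocks[[which.max(sizes)]])
  if (nchar(mol) < 3L) return(character(0))
  peps <- vapply(0:2, function(f) {
    sub("\\*+$", "", translate_cds(substr(mol, f + 1L, nchar(mol))))
  }, "")
  peps[nchar(peps) > 0]
}

# Karlin-Altschul parameters for gapped BLOSUM62 with gap open 11 /
# extend 1 (standard blastp defaults)
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Best protein-match e-value of candidate peptides
#'
#' Local alignment (BLOSUM62, gap open 11 / extend 1) of every peptide
#' against every orthogroup member protein; the e-value of a score S is
#' the Karlin-Altschul expectation `K * m * n * exp(-lambda * S)` with
#' database size n = summed orthogroup protein length. The minimum over
#' all combinations is returned; an empty peptide set yields `Inf`.
#'
#' @param peptides character vector of candidate peptides
#' @param proteins character vector of orthogroup member proteins
#' @return smallest e-value (numeric scalar)
#' @export
protein_match <- function(peptides, proteins) {
  stopifnot(length(proteins) > 0, all(nchar(proteins) > 0))
  peptides <- peptides[nchar(peptides) > 0]
  if (length(peptides) == 0L) return(Inf)
  db_size <- sum(nchar(proteins))
  data("BLOSUM62", package = "Biostrings", envir = environment())
  blosum <- get("BLOSUM62", envir = environment())
  best <- Inf
  for (pep in peptides) {
    pep_clean <- gsub("[^A-Z*]", "X", pep)
    for (prot in proteins) {
      sc <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::AAString(pep_clean),
        subject = Biostrings::AAString(prot),
        type = "local", substitutionMatrix = blosum,
        gapOpening = 11, gapExtension = 1, scoreOnly = TRUE
      )
      ev <- KA_K * nchar(pep_clean) * db_size * exp(-KA_LAMBDA * sc)
      best <- min(best, ev)
    }
  }
  best
}

#' Step-2 category from step-1 category, e-value and start coverage
#'
#' Mapping (e-value threshold inclusive at 1e-10): cat1 with a protein
#' match is catA (full ORF and protein); cat2 with a match and the start
#' codon present is catB (partial, in frame); cat2 with a match but no
#' start is catC (frame unknown); cat2 without a match is catD; cat1
#' without a match is catE (likely frameshift).
#'
#' @param step1 `"cat1"` or `"cat2"` (others error)
#' @param best_evalue best protein-match e-value
#' @param start_covered is the ORF start codon contained in the alignment?
#' @param e_threshold match threshold (default 1e-10, inclusive)
#' @return one of `"catA"`..`"catE"`
#' @export
classify_step2 <- function(step1, best_evalue, start_covered,
                           e_threshold = 1e-10) {
  if (!step1 %in% c("cat1", "cat2")) {
    abort("step-2 classification applies to cat1/cat2 pairs only")
  }
  match <- best_evalue <= e_threshold
  if (step1 == "cat1") {
    if (match) "catA" else "catE"
  } else {
    if (match && start_covered) "catB"
    else if (match) "catC"
    else "catD"
  }
}

#' Classify all read pairs against their ORF models
#'
#' Runs step 1 on every fragment, translates cat1/cat2 alignments, scores
#' them against the orthogroup proteins (or takes precomputed tabular
#' e-values) and assigns step-2 categories.
#'
#' @param aln alignment tibble from [read_alignments()]
#' @param orfs [orf_models()] tibble
#' @param hits optional precomputed tibble `fragment_id`, `e_value`
#'   (best blastp e-value per fragment) used instead of the built-in
#'   protein matcher
#' @param e_threshold step-2 match threshold (default 1e-10)
#' @return tibble: `fragment_id`, `target_id`, `step1`, `step2`,
#'   `best_evalue`, `start_covered`
#' @export
classify_read_pairs <- function(aln, orfs, hits = NULL, e_threshold = 1e-10) {
  frags <- split(aln, aln$fragment_id)
  rows <- purrr::map(frags, function(pair) {
    tid <- pair$target_id[1]
    orf <- orfs %>% filter(target_id == tid)
    if (nrow(orf) == 0L) return(NULL)
    orf <- as.list(orf[1, ])
    s1 <- classify_step1(pair, orf)
    if (!s1$step1 %in% c("cat1", "cat2")) {
      return(tibble(fragment_id = pair$fragment_id[1], target_id = tid,
                    step1 = s1$step1, step2 = NA_character_,
                    best_evalue = NA_real_, start_covered = s1$start_covered))
    }
    ev <- if (!is.null(hits)) {
      h <- hits$e_value[hits$fragment_id == pair$fragment_id[1]]
      if (length(h) == 0L) Inf else min(h)
    } else {
      group <- orfs %>% filter(orthogroup_id == orf$orthogroup_id)
      protein_match(translate_aligned(pair, orf, s1), group$protein)
    }
    tibble(fragment_id = pair$fragment_id[1], target_id = tid,
           step1 = s1$step1,
           step2 = classify_step2(s1$step1, ev, s1$start_covered, e_threshold),
           best_evalue = ev, start_covered = s1$start_covered)
  })
  dplyr::bind_rows(rows)
}

#' Per-neORF intactness calls from pair categories
#'
#' An neORF is called intact when at least one of its read pairs is catA
#' (full ORF covered by a single fragment, in frame, stop-free, protein
#' match to the orthogroup). Only detectable ORFs (see
#' [orf_detectable()]) can be called intact; category tallies are kept
#' for all.
#'
#' @param categories tibble from [classify_read_pairs()]
#' @param orfs [orf_models()] tibble
#' @param read_length read length of the data set (nt)
#' @param paired paired-end data? (default TRUE)
#' @return tibble per target: `target_id`, `orthogroup_id`, `detectable`,
#'   `intact`, `n_pairs` and one column per category tally
#' @export
call_intact <- function(categories, orfs, read_length, paired = TRUE) {
  lv1 <- paste0("cat", 1:5)
  lv2 <- paste0("cat", c("A", "B", "C", "D", "E"))
  tal <- categories %>%
    group_by(target_id) %>%
    summarise(
      n_pairs = n(),
      !!!setNames(
        purrr::map(lv1, function(l) rlang::quo(sum(step1 == !!l, na.rm = TRUE))),
        lv1),
      !!!setNames(
        purrr::map(lv2, function(l) rlang::quo(sum(step2 == !!l, na.rm = TRUE))),
        lv2),
      .groups = "drop"
    )
  orfs %>%
    select(target_id, orthogroup_id, orf_end) %>%
    left_join(tal, by = "target_id") %>%
    mutate(
      across(c(all_of(c("n_pairs", lv1, lv2))), ~ dplyr::coalesce(., 0L)),
      detectable = orf_detectable(orf_end, read_length, paired),
      intact = detectable & catA >= 1L
    ) %>%
    select(target_id, orthogroup_id, detectable, intact, n_pairs,
           all_of(c(lv1, lv2)))
}

#' Enrichment of intact neORFs among differentially expressed neORFs
#'
#' 1-df goodness-of-fit chi-square (no continuity correction) of the
#' intact count among DE neORFs against the expectation from the overall
#' intact proportion in the analyzable set.
#'
#' @param intact_calls tibble with `orthogroup_id` (or `gene_id`) and
#'   logical `intact`
#' @param de_flags tibble with `gene_id`, logical `de` over the same
#'   analyzable neORF set
#' @return one-row tibble from [gof_proportion_test()]
#' @export
intact_de_enrichment <- function(intact_calls, de_flags) {
  ic <- intact_calls
  if (!"gene_id" %in% names(ic) && "orthogroup_id" %in% names(ic)) {
    ic <- ic %>% rename(gene_id = orthogroup_id)
  }
  x <- ic %>% inner_join(de_flags, by = "gene_id")
  p_intact <- mean(x$intact)
  n_de <- sum(x$de)
  gof_proportion_test(sum(x$intact & x$de), n_de, n_de * p_intact)
}
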