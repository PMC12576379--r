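# Readers and writers for every external format the pipeline touches.
# Internal coordinates are 0-based half-open everywhere; 1-based inclusive
# coordinates appear only at format boundaries (SAM/GFF/BLAST in, BED out).

#' Read a gene-level count matrix from TSV
#'
#' First column holds gene ids, remaining columns one sample each. Values
#' must be non-negative integers.
#'
#' @param path TSV file path
#' @return tibble with `gene_id` and one numeric column per sample
#' @export
read_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  names(x)[1] <- "gene_id"
  x$gene_id <- as.character(x$gene_id)
  if (anyDuplicated(x$gene_id)) {
    dup <- unique(x$gene_id[duplicated(x$gene_id)])
    abort(sprintf("duplicate gene ids: %s", paste(head(dup, 5), collapse = ", ")))
  }
  validate_counts(x)
  as_tibble(x)
}

validate_counts <- function(counts) {
  samples <- setdiff(names(counts), "gene_id")
  if (length(samples) == 0L) abort("count table has no sample columns")
  for (s in samples) {
    v <- counts[[s]]
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad) > 0L) {
      abort(sprintf(
        "invalid count %s at gene '%s', sample '%s': counts must be non-negative integers",
        format(v[bad[1]]), counts$gene_id[bad[1]], s
      ))
    }
  }
  invisible(counts)
}

#' Write a count matrix to TSV
#' @param counts tibble from [read_counts()] or the simulator
#' @param path output path
#' @return `path`, invisibly
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

counts_to_matrix <- function(counts) {
  m <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  rownames(m) <- counts$gene_id
  storage.mode(m) <- "double"
  m
}

matrix_to_counts <- function(m) {
  bind_cols_safe <- as_tibble(m)
  dplyr::bind_cols(tibble(gene_id = rownames(m)), bind_cols_safe)
}

#' Read read-pair alignments from a SAM file
#'
#' Parses a SAM file (via Rsamtools) against a set of known transcript
#' targets, pairing records by query name. Soft-clipped bases are excluded
#' from the aligned reference interval. Records whose reference is absent
#' from `targets` are skipped with a warning giving the skip count.
#'
#' @param path SAM file path
#' @param targets tibble with at least `gene_id` (and optionally
#'   `cds_length`), or a character vector of target ids
#' @return tibble with one row per aligned mate: `fragment_id`,
#'   `target_id`, `mate` (1 or 2), `start`, `end` (0-based half-open
#'   reference interval excluding soft clips), `cigar`, `seq` (full read
#'   sequence as stored in the SAM record), and `mate_count` (number of
#'   mates observed for the fragment)
#' @export
read_alignments <- function(path, targets) {
  target_ids <- if (is.character(targets)) targets else targets$gene_id
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  rec <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "cigar", "seq")
    )
  )[[1]]
  aln <- tibble(
    fragment_id = rec$qname,
    flag = rec$flag,
    target_id = as.character(rec$rname),
    pos = rec$pos,
    cigar = rec$cigar,
    seq = as.character(rec$seq)
  ) %>%
    filter(!is.na(pos), !is.na(cigar))
  unknown <- !(aln$target_id %in% target_ids)
  if (any(unknown)) {
    warn(sprintf("skipped %d alignment(s) to unknown targets", sum(unknown)))
    aln <- aln[!unknown, ]
  }
  if (nrow(aln) == 0L) {
    return(tibble(fragment_id = character(), target_id = character(),
                  mate = integer(), start = integer(), end = integer(),
                  cigar = character(), seq = character(),
                  mate_count = integer()))
  }
  ref_width <- GenomicAlignments::cigarWidthAlongReferenceSpace(aln$cigar)
  aln %>%
    mutate(
      start = pos - 1L,
      end = pos - 1L + ref_width,
      mate = if_else(bitwAnd(flag, 128L) > 0L, 2L, 1L)
    ) %>%
    group_by(fragment_id) %>%
    mutate(
      mate_count = n(),
      mate = if_else(mate_count == 1L, 1L, mate)
    ) %>%
    ungroup() %>%
    select(fragment_id, target_id, mate, start, end, cigar, seq, mate_count)
}

#' Write read-pair alignments as a SAM file
#'
#' Emits a minimal, valid SAM file (used by the simulator so that the SAM
#' reader can be exercised round-trip). Mates are flagged paired when a
#' fragment has two rows.
#'
#' @param aln alignment tibble as returned by [read_alignments()] (the
#'   `mate_count` column may be omitted)
#' @param targets tibble with `gene_id` and `cds_length` giving reference
#'   names and lengths for the header
#' @param path output SAM path
#' @return `path`, invisibly
#' @export
write_alignments <- function(aln, targets, path) {
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", targets$gene_id, targets$cds_length)
  )
  mate_n <- aln %>% count(fragment_id, name = "mc")
  aln <- aln %>% left_join(mate_n, by = "fragment_id")
  flag <- ifelse(aln$mc == 2L,
                 ifelse(aln$mate == 2L, 129L, 65L),
                 0L)
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                  aln$fragment_id, flag, aln$target_id, aln$start + 1L,
                  aln$cigar, aln$seq)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read tabular placement hits (BLAST outfmt-6 dialect)
#'
#' Expects the standard 12 columns (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore) with an optional 13th
#' column holding the query-coverage fraction. When the coverage column is
#' absent it is computed as `alignment_length / query length` from
#' `query_lengths`. Subject coordinates are normalized to 0-based
#' half-open with strand inferred from start > end.
#'
#' @param path tabular hit file
#' @param query_lengths optional named vector of query lengths (nt)
#' @return tibble with `query_id`, `subject_id`, `percent_identity`,
#'   `alignment_length`, `e_value`, `bitscore`, `query_coverage`, `chrom`,
#'   `start`, `end`, `strand`, in file order
#' @export
read_hits <- function(path, query_lengths = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(query_id = character(), subject_id = character(),
                  percent_identity = double(), alignment_length = integer(),
                  e_value = double(), bitscore = double(),
                  query_coverage = double(), chrom = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 12L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed hit line %d: expected >= 12 tab-separated fields, got %d",
                  bad[1], nf[bad[1]]))
  }
  f <- function(i) vapply(fields, `[[`, "", i)
  num <- function(i) {
    v <- suppressWarnings(as.numeric(f(i)))
    if (anyNA(v)) abort(sprintf("malformed hit line %d: non-numeric field %d",
                                which(is.na(v))[1], i))
    v
  }
  qid <- f(1)
  sstart1 <- num(9); send1 <- num(10)
  minus <- sstart1 > send1
  lo1 <- ifelse(minus, send1, sstart1)
  hi1 <- ifelse(minus, sstart1, send1)
  alen <- as.integer(num(4))
  cov <- if (any(nf >= 13L)) {
    suppressWarnings(as.numeric(vapply(fields, function(x)
      if (length(x) >= 13L) x[[13]] else NA_character_, "")))
  } else if (!is.null(query_lengths)) {
    alen / unname(query_lengths[qid])
  } else {
    rep(NA_real_, length(qid))
  }
  tibble(
    query_id = qid,
    subject_id = f(2),
    percent_identity = num(3),
    alignment_length = alen,
    e_value = num(11),
    bitscore = num(12),
    query_coverage = cov,
    chrom = f(2),
    start = as.integer(lo1 - 1),
    end = as.integer(hi1),
    strand = ifelse(minus, "-", "+")
  )
}

#' Read neORF (or any) nucleotide sequences from FASTA
#' @param path FASTA path
#' @return tibble with `gene_id`, `sequence`
#' @export
read_orf_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(gene_id = sub("\\s.*$", "", names(x)), sequence = as.character(x))
}

#' Write sequences to FASTA
#' @param genes tibble with `gene_id` and `sequence`
#' @param path output FASTA path
#' @return `path`, invisibly
#' @export
write_orf_fasta <- function(genes, path) {
  x <- Biostrings::DNAStringSet(setNames(genes$sequence, genes$gene_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read an annotation gene table from TSV
#'
#' Columns: `gene_id`, `gene_class` (PC/ncRNA/neORF), `orthogroup_id`,
#' `cds_length`, optional `sequence`, optional placement
#' (`chrom`,`start`,`end`,`strand`, 0-based half-open), optional
#' `line_presence` (string of seven 0/1 characters, neORFs only).
#'
#' @param path TSV path
#' @return validated gene tibble
#' @export
read_gene_table <- function(path) {
  # chromosome names like "2L" must not be parsed as integer literals
  g <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         line_presence = readr::col_character(),
                         chrom = readr::col_character(),
                         strand = readr::col_character(),
                         sequence = readr::col_character(),
                         orthogroup_id = readr::col_character(),
                         .default = readr::col_guess()
                       ))
  validate_genes(as_tibble(g))
}

#' Write an annotation gene table to TSV
#' @param genes gene tibble
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gene_table <- function(genes, path) {
  readr::write_tsv(genes, path)
  invisible(path)
}

validate_genes <- function(genes) {
  stopifnot(all(c("gene_id", "gene_class", "cds_length") %in% names(genes)))
  bad_class <- setdiff(unique(genes$gene_class), c("PC", "ncRNA", "neORF"))
  if (length(bad_class) > 0L) {
    abort(sprintf("unknown gene_class: %s", paste(bad_class, collapse = ", ")))
  }
  ne <- genes$gene_class == "neORF"
  if (any(genes$cds_length[ne] < 90)) {
    abort("neORF cds_length must be >= 90 nt")
  }
  if ("sequence" %in% names(genes)) {
    has_seq <- !is.na(genes$sequence)
    if (any(nchar(genes$sequence[has_seq]) %% 3 != 0)) {
      abort("sequences must have length divisible by 3")
    }
  }
  if ("line_presence" %in% names(genes)) {
    lp <- genes$line_presence[ne & !is.na(genes$line_presence)]
    if (length(lp) > 0L) {
      pc <- popcount_presence(lp)
      if (any(nchar(lp) != 7L) || any(pc < 1L | pc > 7L)) {
        abort("line_presence must be 7 characters of 0/1 with 1-7 ones")
      }
    }
  }
  genes
}

popcount_presence <- function(presence) {
  vapply(strsplit(presence, ""), function(x) sum(x == "1"), 0L)
}

#' Write genomic placements as BED
#'
#' BED is 0-based half-open, matching the internal convention directly.
#'
#' @param placements tibble with `chrom`, `start`, `end`, `orthogroup_id`
#'   (used as the BED name), and optionally `bitscore` (score) and `strand`
#' @param path output BED path
#' @return `path`, invisibly
#' @export
write_placements_bed <- function(placements, path) {
  score <- if ("bitscore" %in% names(placements)) placements$bitscore else 0
  strand <- if ("strand" %in% names(placements)) placements$strand else "."
  writeLines(sprintf("%s\t%d\t%d\t%s\t%g\t%s",
                     placements$chrom, placements$start, placements$end,
                     placements$orthogroup_id, score, strand), path)
  invisible(path)
}

#' Read gene intervals from GFF3 or BED
#'
#' GFF3 rows of type `gene` (or all rows if none are typed `gene`) are
#' converted from 1-based inclusive to 0-based half-open; BED is read
#' as-is. The gene id is taken from the `ID=` attribute (GFF3) or the
#' name column (BED).
#'
#' @param path GFF3 (`.gff`/`.gff3`) or BED path
#' @return tibble with `gene_id`, `chrom`, `start`, `end`, `strand`
#' @export
read_gene_intervals <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
    return(tibble(
      gene_id = if (ncol(x) >= 4) as.character(x[[4]]) else paste0("iv", seq_len(nrow(x))),
      chrom = as.character(x[[1]]),
      start = as.integer(x[[2]]), end = as.integer(x[[3]]),
      strand = if (ncol(x) >= 6) as.character(x[[6]]) else "."
    ))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(x) length(x) >= 9L, TRUE)
  fields <- fields[keep]
  types <- vapply(fields, `[[`, "", 3)
  if (any(types == "gene")) fields <- fields[types == "gene"]
  ids <- vapply(fields, function(x) {
    m <- regmatches(x[[9]], regexec("ID=([^;]+)", x[[9]]))[[1]]
    if (length(m) == 2L) m[[2]] else x[[9]]
  }, "")
  tibble(
    gene_id = ids,
    chrom = vapply(fields, `[[`, "", 1),
    start = as.integer(vapply(fields, `[[`, "", 4)) - 1L,
    end = as.integer(vapply(fields, `[[`, "", 5)),
    strand = vapply(fields, `[[`, "", 7)
  )
}
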