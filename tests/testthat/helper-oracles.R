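# Independent oracles used across the suite. These deliberately take a
# different computational route from the package implementation.

# Nei-Gojobori site counts by whole-sequence mutation and Biostrings
# translation: for every position and alternate base, mutate the full
# CDS, translate both versions, and compare proteins.
oracle_ng_sites <- function(sequence) {
  sequence <- toupper(sequence)
  codons <- substring(sequence, seq(1, nchar(sequence), 3),
                      seq(3, nchar(sequence), 3))
  if (codons[length(codons)] %in% c("TAA", "TAG", "TGA")) {
    sequence <- substr(sequence, 1, nchar(sequence) - 3)
  }
  tr <- function(s) as.character(Biostrings::translate(
    Biostrings::DNAString(s), no.init.codon = TRUE))
  ref_prot <- tr(sequence)
  syn <- 0
  for (i in seq_len(nchar(sequence))) {
    for (a in setdiff(c("A", "C", "G", "T"), substr(sequence, i, i))) {
      mut <- sequence
      substr(mut, i, i) <- a
      mut_prot <- suppressWarnings(tr(mut))
      if (identical(mut_prot, ref_prot)) syn <- syn + 1
    }
  }
  c(n_sites = nchar(sequence) - syn / 3, s_sites = syn / 3)
}

# textbook step-up BH: rank-k adjusted value is the running minimum of
# m * p_(j) / j for j >= k
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  pmin(adj_sorted, 1)[order(o)]
}

# brute-force O(n^2) neighbor scan over half-open intervals
oracle_window_neighbors <- function(placements, genes, window) {
  out <- list()
  for (i in seq_len(nrow(placements))) {
    lo <- placements$start[i] - window
    hi <- placements$end[i] + window
    for (j in seq_len(nrow(genes))) {
      if (placements$chrom[i] == genes$chrom[j] &&
          genes$start[j] < hi && genes$end[j] > lo) {
        out[[length(out) + 1]] <- data.frame(
          orthogroup_id = placements$orthogroup_id[i],
          gene_id = genes$gene_id[j]
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(orthogroup_id = character(), gene_id = character()))
  }
  unique(do.call(rbind, out))
}

# union-coverage step-1 oracle over base positions (geometry only; no
# stop/start logic) for gap/coverage checks
oracle_union_covers <- function(intervals, orf_len) {
  cov <- rep(FALSE, orf_len)
  for (iv in intervals) {
    sel <- seq.int(iv[1] + 1, iv[2])
    sel <- sel[sel >= 1 & sel <= orf_len]
    cov[sel] <- TRUE
  }
  all(cov)
}

# tiny SAM writer for hand-built fixtures
write_test_sam <- function(lines, targets, path) {
  header <- c("@HD\tVN:1.6",
              sprintf("@SQ\tSN:%s\tLN:%d", targets$gene_id, targets$cds_length))
  writeLines(c(header, lines), path)
  path
}

sense_codons <- setdiff(
  as.vector(outer(as.vector(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                  paste0)), c("T", "C", "A", "G"), paste0)),
  c("TAA", "TAG", "TGA")
)
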