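# Genetic-code primitives shared by the simulator, the ORF-integrity
# classifier and the pN/pS machinery. Standard nuclear code; stops are
# TAA/TAG/TGA (Drosophila nuclear genes).

STOP_CODONS <- c("TAA", "TAG", "TGA")
DNA_BASES <- c("A", "C", "G", "T")

# named chr vector: codon -> amino acid ("*" = stop), standard code
codon_table <- local({
  bases <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"
  ), "")[[1]]
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0
  )))
  setNames(aa, codons)
})

#' Split an in-frame coding sequence into codons
#' @param seq single nucleotide string, length divisible by 3
#' @return character vector of codons
#' @keywords internal
#' @noRd
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    abort(sprintf("sequence length %d is not divisible by 3", n))
  }
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate a nucleotide sequence in frame 0
#'
#' Incomplete trailing codons are dropped; codons containing characters
#' outside ACGT (alignment gaps, ambiguity codes) translate to "X".
#'
#' @param seq nucleotide string
#' @return single amino-acid string, stop as `*`
#' @export
#' @examples
#' translate_cds("ATGAAATAA")
translate_cds <- function(seq) {
  seq <- toupper(seq)
  n_cod <- nchar(seq) %/% 3L
  if (n_cod == 0L) return("")
  codons <- substring(seq, seq(1L, by = 3L, length.out = n_cod),
                      seq(3L, by = 3L, length.out = n_cod))
  aa <- unname(codon_table[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

is_stop_codon <- function(codon) codon %in% STOP_CODONS

#' Generate a random stop-free ORF sequence
#'
#' ATG start, a final stop codon, and no in-frame internal stop.
#' Internal codons are drawn uniformly from the 60 non-stop, non-ATG-start
#' unconstrained sense codons (ATG allowed internally).
#'
#' @param length_nt total length including start and stop codon,
#'   divisible by 3, at least 9
#' @return nucleotide string
#' @export
random_orf <- function(length_nt) {
  stopifnot(length_nt >= 9, length_nt %% 3 == 0)
  n_internal <- length_nt / 3 - 2L
  sense <- setdiff(names(codon_table), STOP_CODONS)
  internal <- sample(sense, n_internal, replace = TRUE)
  paste0("ATG", paste(internal, collapse = ""),
         sample(STOP_CODONS, 1L))
}

# coordinate convention helpers: internal coordinates are 0-based
# half-open; SAM/GFF are 1-based inclusive at the boundary.
to_zero_based <- function(start1, end1) list(start = start1 - 1L, end = end1)
to_one_based <- function(start0, end0) list(start = start0 + 1L, end = end0)
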