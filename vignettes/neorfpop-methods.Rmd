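---
title: "Models and methods behind neorfpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neorfpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neorfpop)
library(dplyr)
```

## The scientific problem

Newly evolved open reading frames (neORFs) are de novo gene candidates:
genomic segments that have recently gained both transcription and a
complete ORF. In *Drosophila melanogaster* they were annotated per
orthogroup across seven inbred lines (six European, one sub-Saharan
African), and their fate in natural populations can be followed with
pooled population RNA-seq: libraries prepared from 8–12 inbred lines
mixed together, sequenced for two populations across tissues, sexes and
developmental stages.

`neorfpop` implements the full analysis chain for such data: expressed-
gene calling at a TPM threshold with orthogroup aggregation;
negative-binomial differential expression between populations or sexes
with gene-class enrichment statistics; a two-step read-pair classifier
that decides, from single sequenced fragments, whether an neORF's coding
sequence is intact in at least one pooled line; Nei–Gojobori pN/pS
estimation from pooled reads; enrichment analysis over the 1–7-line
frequency classes of the original annotation; and the association
between differentially expressed neORFs and differential expression of
protein-coding genes within 1 kb of their genome placement. A forward
simulator generates every input type with known ground truth, so all
stages are testable without any sequencing download.

## Expression calling

Counts are summed over the transcripts of a gene, and neORF members of
one orthogroup are summed into a single row (members are highly similar
or identical, so the orthogroup is the analysis unit). Biological
replicates of a sample type are pooled by summing counts — not by
averaging TPMs — before normalization; this is exposed as an explicit
two-step (`pool_replicates()`, then `compute_tpm()`) so the choice is
visible. TPM uses plain annotated lengths,

$$\mathrm{TPM}_g = 10^6 \,\frac{c_g / L_g}{\sum_j c_j / L_j},$$

with no effective-length (fragment-length) correction: the length
convention the reference analyses used is not recorded anywhere we can
consult, and plain maximum annotated CDS/exonic length per gene is
deterministic and simple to reason about. A gene is expressed in a
sample type when TPM ≥ 0.5 — the threshold is inclusive — and expressed
in a tissue when it passes that bound in at least one of the tissue's
sample types (`union_expressed()`).

## The negative-binomial DE stage

Differential expression uses a per-gene NB GLM with log link and
size-factor offsets. The machinery is deliberately a documented
simplification of the DESeq2 scheme; bit-level agreement with DESeq2 is
not a goal, the statistical design is:

* **Size factors** are median-of-ratios: per-gene ratios to the
  geometric-mean reference over genes with all-positive counts, median
  per sample, rescaled to geometric mean 1. Columns of all-zero overlap
  fall back to column-sum ratios with a warning.
* **Designs.** Whole-body, Malpighian-tubule and brain-style data use a
  two-factor population + sex model; fat-body-style developmental data
  use a one-factor grouping with six levels (population × stage), so a
  population contrast within any stage comes from one fit.
* **Dispersion** is estimated per gene by maximizing the Cox–Reid
  adjusted profile likelihood on a fixed logarithmic grid
  ($10^{-4}$–$3$, 50 points, parabolic refinement), with fitted means
  held at their values from an initial moment-based fit. A parametric
  trend $\alpha(\mu) = a_0 + a_1/\mu$ is fitted by Gamma regression with
  outlier exclusion, and gene-wise estimates are shrunk to a maximum a
  posteriori value under a log-normal prior centred on the trend. The
  prior variance is the excess of the squared MAD of log-dispersion
  residuals over the theoretical sampling variance
  $\psi'((n-p)/2)$, floored at 0.05. The floor is smaller than the one
  DESeq2 uses (0.25): with only three replicates per group, residual
  gene-level dispersion noise at the larger floor inflates tail Wald
  statistics and pushes the realized FDR above its nominal target,
  while the adaptive term still widens the prior whenever genuine
  dispersion scatter is present.
* **Testing.** The contrast coefficient is tested with a Wald z
  statistic (LFC/SE against the standard normal). **Independent
  filtering** removes low-count genes before Benjamini–Hochberg
  adjustment: the mean-normalized-count quantile threshold is chosen on
  a fixed grid (0–0.95 by 0.05) to maximize rejections at the FDR
  target, so filtering can never lose discoveries relative to no
  filtering. Filtered genes carry no adjusted p-value. The default FDR
  is 5%.
* **Gene-class statistics.** Over/under-representation of each gene
  class among DE genes is a one-degree-of-freedom goodness-of-fit
  chi-square of the observed DE count against the global DE proportion,
  without continuity correction — the form that exactly reproduces the
  published neighbor-gene association p-values from their printed count
  triplets — BH-adjusted across classes. |LFC| magnitude differences
  between classes use Welch two-sample t-tests (the pooled-variance
  form was a live alternative; Welch is recorded in the fit metadata)
  BH-adjusted across the three class pairs.

## The read-pair ORF-integrity classifier

Pooled samples confound expression level with the number of expressing
lines, and a full-length coding sequence can only be confirmed when one
sequenced molecule spans it. An ORF is therefore *detectable* only if
its length is at most twice the read length (paired) or the read length
(single-end); 50-nt single-end tissues can detect nothing, since the
shortest neORF is 90 nt.

Step 1 places each ORF-overlapping fragment into one of five
categories: full ORF covered by the mate-union (cat1), partial coverage
with no internal stop (cat2), in-frame internal stop codon (cat3),
start position spanned but no ATG there (cat4), or mates on different
targets (cat5). Three conventions are fixed here because the category
definitions alone do not order them:

* *Coverage* means the union of mate alignments covers every ORF base,
  with overlapping or abutting mates; an unsequenced inner gap
  disqualifies cat1, because unobserved bases cannot confirm the
  absence of stops. A single read that alone contains the whole ORF
  also qualifies (a stricter sub-case of one fragment).
* *Precedence*: cat5 beats everything (mates on two targets cannot be
  frame-assessed); cat3 beats cat1/cat2/cat4, since direct stop-codon
  evidence is the strongest disqualifier. When both the cat3 and cat4
  conditions hold, cat3 wins — a tie-break we fix, not one inherent in
  the category definitions.
* *Frame*: codons are anchored at the ORF start on the reference;
  insertions and deletions inside the alignment shift the frame for all
  downstream codons during the stop scan, which is exactly what makes
  frameshifted molecules surface as catE below.

Step 2 translates cat1/cat2 alignments (anchored frame when the start
is covered, otherwise all three frames of the longest covered segment)
and scores them against the orthogroup member proteins by local
alignment (BLOSUM62, gap open 11 / extend 1), converting scores to
Karlin–Altschul e-values with database size equal to the summed
orthogroup protein length. With the inclusive threshold
$e \le 10^{-10}$: cat1 with a match is catA (full ORF and protein);
cat2 splits into catB (match, start present), catC (match, frame
unknown) and catD (no match); cat1 without a match is catE — a likely
frameshift. An neORF is *intact* in a sample type when at least one of
its pairs is catA. Precomputed tabular e-values are accepted in place
of the built-in matcher.

## Pooled pN/pS

Polymorphism is read off fragments whose mate-union spans the whole ORF
(cat1 geometry), each contributing one sequence. To suppress
sequencing and reverse-transcription errors a polymorphism must be
present in two independent fragments — mates of one fragment count
once — so at least four full-length reads are required before any site
can be called. Sites are classified synonymous/nonsynonymous by
substituting the alternate base into the reference codon (one
substitution at a time, standard nuclear code; mutations creating stops
count as nonsynonymous, the standard Nei–Gojobori treatment). Site
*opportunities* follow Nei–Gojobori: each codon position contributes
the fraction of its three substitutions that are synonymous, so
$N + S = 3 \times$ codons exactly. Then $p_N = n_{\mathrm{poly}}/N$,
$p_S = s_{\mathrm{poly}}/S$, and departure from the neutral expectation
$p_N/p_S = 1$ is a 1-df goodness-of-fit chi-square of the two
polymorphism counts against expectations proportional to $(N, S)$.
Polymorphisms are pooled across neORFs before the test (per-neORF
counts are too sparse for individual tests, and the combined ratio is
the quantity of interest); per-neORF tallies are also emitted. Subset
comparisons use a 2×2 contingency chi-square without continuity
correction. $p_S = 0$ leaves the ratio flagged undefined but the test
still computed.

## Frequency classes and neighbor genes

neORFs are binned by the number of original annotation lines carrying
them (popcount of the 7-bit presence vector). Per class, the observed
number of expressed (or DE) neORFs is compared to the overall
proportion with the same 1-df GOF chi-square, BH-adjusted across the
seven classes; classes with expected counts below 5 carry a low-count
flag rather than being merged, so all seven classes stay reportable.

Genome placements come from tabular nucleotide-search hits filtered to
100% query coverage and e ≤ 0.01, best hit by bitscore (ties: lower
e-value, then lexicographic coordinates). Neighbors are protein-coding
genes overlapping the placement extended by 1 kb on both sides,
strand-ignored (the symmetric-window convention of the standard
interval tool); internally all coordinates are 0-based half-open, so a
gene abutting exactly at `start - 1000` is excluded. The unique PC
neighbors of DE neORFs are pooled per sample type — a gene neighboring
several DE neORFs counts once — and their DE count is tested against
the sample-type-wide PC DE proportion with the same GOF chi-square.

## The simulator: what it emulates, and what it does not

The generator's defaults are the study conditions: two populations,
8–12 lines per pool, 3 replicates, seven annotation lines, 150-nt
paired reads with ~250 ± 40 nt fragments, neORFs of 90–600 nt starting
with ATG and free of internal stops. Counts invert the NB model
(per-gene log-normal baselines around 500, dispersion 0.05, true-null
genes with LFC exactly 0, signed log2 effects of |N(1, 0.5)| for the DE
fraction). Two modeling choices deserve emphasis:

* **Pool expression fraction.** A pooled library's mean for an neORF
  scales linearly with the fraction of pool lines expressing it, each
  line expressing with probability (lines expressing / 7), where a
  carrying line is silent with the turnover probability 0.3. The
  realized fraction is drawn once per gene and shared across samples,
  so the only between-population signal is the true LFC; real pools
  would also differ in composition, which is exactly the
  level-versus-pervasiveness confound pooled designs cannot resolve.
  The simulator makes that confound explicit and controllable rather
  than pretending to break it.
* **Polymorphic pools.** Each of the three alternate bases at each site
  segregates independently with a per-substitution probability set by
  its synonymous/nonsynonymous status, at most one kept per site; the
  alternate is assigned to 1..(n−1) random lines and reads are sampled
  from line haplotypes with replacement. Realized pN/pS then equals the
  rate ratio in expectation, which is what the recovery experiments
  exploit.

The simulator deliberately omits sequencing error, quality scores, GC
and positional bias, multi-mapping and annotation error. Passing tests
therefore demonstrate the correctness and calibration of the
*statistical machinery* under the stated model — not robustness to
artifacts real libraries contain.

## Numerical choices and degenerate inputs

Dispersion grids, the filtering quantile grid and the BH step-up are
fully deterministic; ties in placement selection break by fixed
lexicographic rules; IRLS caps the linear predictor at ±30 and flags
non-convergent genes (their p-values are set missing) rather than
reporting unstable estimates. All-zero count columns produce all-zero
TPM with a warning; an all-zero gene is reported but untestable.
Chromosome names such as `2L` are forced to character on input (an
integer-literal parser would read them as 2).

## Problem sizes

The bundled experiments run at desk scale, chosen to give tight Monte
Carlo error while staying interactive: 3000 genes for the null
calibration (binomial SE of the false-positive rate ≈ 0.004), 20
seeds × 800 genes for empirical FDR, 40 neORFs × 5 seeds per true
pN/pS ratio (≥300 called polymorphisms each), 50 simulated neORFs for
intactness recall, and 50 × 1000 neORFs for the frequency-class power
surface. Population-scale gene counts (≈14k PC genes, ≈5.7k neORF
orthogroups) and the published tables' absolute numbers require the
original sequencing data and are out of scope; the neighbor-gene
association p-values are the exception, since their printed count
triplets fully determine the statistic.

## Known limitations

The NB stage does not implement LFC shrinkage, likelihood-ratio tests
or batch correction. The protein matcher's Karlin–Altschul parameters
are the standard gapped BLOSUM62/11/1 constants, adequate for the
sharp decision at $e \le 10^{-10}$ but not for edge-calibrated
e-values on very short peptides. pN/pS carries no multiple-hit
correction (polymorphism, not divergence). Window neighbor detection is
strand-ignored by construction. The classifier assumes alignments are
trustworthy over their aligned span; it cannot rescue misalignments.
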