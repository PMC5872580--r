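---
title: "Methods: HLA typing, locus-level quantification and body-map aggregation"
author: "hlamap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HLA typing, locus-level quantification and body-map aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlamap)
```

## The problem

The HLA genes are the most polymorphic loci in the human genome. Standard
RNA-Seq pipelines map reads against a single reference haplotype, so reads
from a donor's actual alleles are lost or misplaced, which corrupts both
genotype inference and expression estimates. `hlamap` instead aligns
paired-end reads directly against a database of known allele sequences for
twelve loci — classical class I (HLA-A, -B, -C), non-classical class I
(HLA-E, -F, -G) and the class II alpha/beta chains (DPA1, DPB1, DQA1, DQB1,
DRA, DRB1) — calls a 4-digit genotype per locus, converts read-to-locus
assignments into RPKM/TPM, and aggregates cohorts of samples into
tissue-level "body-map" statistics.

## Allele reference

The reference is any allele FASTA whose headers carry a nomenclature token
(`A*02:01:01:01`, `HLA-A*02:01`, or accession-style
`HLA:HLA00005 A*01:01:01:01 3503 bp`). Names are truncated to 4-digit
resolution (`locus*group:protein`); records identical at that resolution
but differing in later fields are retained as synonymous sequence
representatives of one callable name, and calls always report the 4-digit
name. Loci outside the supported twelve are skipped by default (DRB3/4/5
paralogs and pseudogenes are deliberately not typed); `strict = TRUE`
turns every such tolerance into an error. Sequences are uppercased and
IUPAC ambiguity codes other than N become N (rejected in strict mode).
Each record's sequence is treated as the mappable transcript; no
intron/CDS distinction is made, so the FASTA supplied is authoritative.

Coordinates are 0-based and half-open throughout. Only the forward strand
is k-mer indexed; read orientation is handled at alignment time.

## Read alignment and genotype calling

Alignment is ungapped and end-to-end, seeded by exact k-mer matches at
non-overlapping offsets of each mate (plus the final window). A pair hits
an allele when both mates place on it in a mate-consistent orientation
(FR or RF; insert size is unconstrained because allele references are
short) with total mismatches at most `maxMismatch` (default 4). Only the
pair's best (minimum-mismatch) stratum is kept. By the pigeonhole
principle the seeded search is exhaustive — provably identical to brute
force over all alleles, offsets and orientations — whenever a mate carries
fewer than `floor(mateLength / k)` mismatches; the test suite exploits
this to assert exact equality with an independent brute-force oracle.
Ungapped alignment keeps that oracle exact and is adequate here because
same-locus allele differences in transcript sequence are overwhelmingly
substitutions at read scale. Positions where either sequence is N never
count as mismatches. Base qualities are ignored for mismatch counting.

`k = 16` by default: long enough to be specific on kilobase-scale
alleles, short enough that a 50 bp read still carries three seeds and
thus tolerates the mismatch loads seen at sub-percent error rates.

Genotypes are called per locus by a two-pass vote:

1. **Group pass.** Each pair assigned to the locus contributes one vote,
   split equally over the distinct 2-digit groups in its best stratum.
   The top group is always called. A second group is called iff its vote
   share *among pairs incompatible with the top group*, relative to all
   locus-informative pairs, exceeds the heterozygosity threshold
   `thetaHet` (default 0.15 — the second allele must own at least 15% of
   the locus reads). A single stray read therefore never creates a
   heterozygous call.
2. **Allele pass.** Within each called group the 4-digit allele with the
   most compatible pairs wins; ties break by fewer total mismatches, then
   lexicographic name, so calls are fully deterministic (all iteration is
   sorted by name).

Zygosity is heterozygous iff two groups were called, or two alleles of
one group each hold more than `thetaHet` of the locus pairs after
exclusive assignment (counting only pairs compatible with one allele and
not the other — necessary because synonymous and near-identical alleles
share almost all their reads). Heterozygote confidence is the support
balance `min(1, 2*support2/(support1+support2))`, which is 1 for a
perfectly balanced 1:1 heterozygote; homozygote confidence is one minus
the exclusive read share of the best non-called allele. Pairs whose best
stratum spans two loci are cross-locus-ambiguous: they are excluded from
all locus counts but tallied, so assigned + ambiguous + unmapped always
equals the number of input pairs.

## Expression quantification

RPKM follows the standard definition,
`count / ((length/1000) * (total/1e6))`. The denominator counts each
*pair* once (configurable via the `totalMapped` override) and includes
ambiguous and unmapped pairs, since they were sequenced from the same
library. The effective length of a locus is the mean sequence length of
its called allele(s) — the reference here is the allele FASTA itself, not
an exon model. TPM is the renormalisation `rpkm / sum(rpkm) * 1e6` over
the union of HLA loci and any externally counted genes, and always sums
to one million when anything is expressed.

Two composite metrics summarise the locus-level values:

* **Classical class I** = RPKM(A) + RPKM(B) + RPKM(C). A sum is used
  because the three heavy chains are reported separately and a tissue's
  total classical presentation capacity is their aggregate; per-locus
  expression is balanced within tissues, so the sum is also directly
  comparable across loci-resolved views.
* **Class II composite** = `min(DPA1,DPB1) + min(DQA1,DQB1) +
  min(DRA,DRB1)`. Each class II molecule needs one alpha and one beta
  chain, so the scarcer chain of each isotype bounds the number of
  assemblable heterodimers.

Non-HLA genes (proteasome subunits PSMB5–PSMB10, TAP1/2, marker genes)
enter through a per-sample count table (`gene`, `count`, `length_bp`);
the constitutive proteasome is summarised as the median of PSMB5/6/7 and
the immunoproteasome as the median of PSMB8/9/10.

## Body-map aggregation

A cohort of sample profiles is aggregated per tissue into medians of
every metric, positivity fractions (share of samples *strictly* above a
threshold, default 1 RPKM — a value exactly at the threshold does not
count), and outlier flags (samples strictly above a configured threshold
on a configured metric, e.g. classical class I above 900 RPKM).
Positivity percents are rounded half-up to the nearest integer;
half-up rather than R's round-half-even keeps printed integer
percentages deterministic and reproducible by hand.

Correlations use Spearman's rank coefficient (Pearson on average ranks,
ties averaged). By default they are computed across *tissue medians*
(n = number of tissues), which answers how metrics co-vary across the
body map; `correlationLevel = "sample"` correlates per-sample values
instead, the right mode for within-individual questions such as
PSMB9 versus TAP1. With fewer than three tissues the correlation is
reported as not computable (`NA`), never silently dropped. No
multiple-testing correction is applied; raw rho values are reported.

## The read simulator and what it does (not) emulate

The simulator exists so that every stage is testable with known ground
truth and no external downloads.

* `simulateAlleleDb()` builds a reference with realistic structure: one
  ancestral sequence per locus mutated from a global root at the
  between-locus rate (default 0.20 substitutions/base), alleles mutated
  from their locus ancestor at the within-locus rate (default 0.02).
  Defaults give loci that are unambiguous at read scale and same-locus
  alleles separated by a handful of diagnostic sites — the regime that
  makes HLA typing hard. Names are assigned sequentially with groups
  advancing every two alleles, so both between-group and within-group
  resolution are exercised.
* `simulateSample()` draws pairs multinomially over the genotype's
  alleles with probability proportional to expression level times allele
  length; length-proportional sampling makes expected RPKM exactly
  proportional to the level, so recovery tests have a clean oracle
  (`expectedRpkm()`). Fragment starts are uniform, mate 2 is the
  reverse-complemented fragment end, and errors are i.i.d. substitutions.
  Defaults: 50 bp reads, 150 bp fragments, heterozygous loci split 1:1.
* `simulateCohort()` draws per-sample metric values log-normally around
  supplied tissue medians (the log-normal median equals the generating
  median, so medians are recovered without bias) and can plant outliers
  at fixed values. `simulateCorrelatedMedians()` constructs two metric
  vectors whose Spearman correlation equals a target *by construction*:
  the second metric's rank permutation is reached by seeded swaps until
  the rank statistic matches the target within the lattice resolution,
  then ranks are mapped monotonically onto a log-normal scale. Building
  the correlation into the ranks (rather than drawing from a copula that
  is only correct in expectation) means recovery tests measure what the
  aggregation pipeline does to a known signal, not the luck of a draw.

Every simulator seed is an explicit argument, never global state, and
identical seeds give byte-identical FASTA/FASTQ output.

The simulator deliberately omits several features of real RNA-Seq:
quality-score error profiles (errors are uniform substitutions; no
indels, matching the ungapped aligner), intronic and chimeric reads,
coverage bias along the transcript, allelic imbalance by default, and
cross-mapping homologous non-HLA genes. Passing recovery tests therefore
demonstrates the correctness of the algorithms under the stated
generative model, not their accuracy on any particular sequencing
platform or tissue.

## Numerical and degenerate-input choices

* Empty or malformed FASTA, all-zero TPM input, constant vectors in a
  correlation, zero mapped reads, and fragment lengths exceeding an
  allele are all hard errors naming the offending entity; a locus with
  zero reads is a reported `no_call`, not an error, and a mate shorter
  than k is an unmapped pair, not an error.
* All tie-breaks (allele votes, hit ordering) resolve by sorted name, so
  every result is reproducible to the byte.
* Test and validation problem sizes were chosen as the smallest that
  exercise each property convincingly: toy references of 2–10 alleles of
  150–500 bp against a brute-force alignment oracle (100 random
  instances), 50 seeded replicates per genotype-recovery regime with
  30–50 pairs per allele, 2,500 pairs for expression-ratio recovery, a
  426-sample single-tissue cohort for outlier plant-and-recover, and 30
  tissues with 8 samples each for rank-correlation recovery.

## Known limitations

* 4-digit resolution only; no 6/8-digit calls, no novel-allele
  discovery, and no disambiguation of DRB3/4/5 paralogs.
* Ungapped alignment will miss reads spanning genuine indel differences
  between a donor allele and its nearest database representative.
* The composite class I number depends on the called alleles' lengths;
  with incomplete (e.g. exon-only) reference records, RPKM values are
  relative to those records, not to genomic transcript models.
* Correlations across tissue medians treat tissues as independent
  observations; no phylogeny of tissue types or donor overlap is
  modelled.
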