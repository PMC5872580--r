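# hlamap

HLA genotyping and locus-level expression quantification from paired-end
RNA-Seq, with cohort aggregation into tissue "body-map" statistics.

The HLA genes are the most polymorphic loci in the human genome, so
standard single-reference RNA-Seq pipelines both mistype them and
misestimate their expression. `hlamap` aligns read pairs directly against
a database of known allele sequences for twelve loci — classical class I
(HLA-A, -B, -C), non-classical class I (HLA-E, -F, -G) and the class II
alpha/beta chains (DPA1, DPB1, DQA1, DQB1, DRA, DRB1) — and from those
alignments produces, per sample:

* a **4-digit genotype** per locus (`locus*group:protein`, e.g. `A*02:01`),
  via a two-pass vote: the 2-digit allele group first, then the best
  4-digit allele within each called group, with an explicit
  heterozygosity threshold (θ_het, default 0.15);
* **locus-level expression** as RPKM,
  `count / ((length/1000) · (total/10⁶))`, and TPM,
  `rpkm / Σ rpkm · 10⁶`, plus two composite metrics:
  classical class I = RPKM(A) + RPKM(B) + RPKM(C), and the class II
  composite = min(DPA1, DPB1) + min(DQA1, DQB1) + min(DRA, DRB1) —
  each class II molecule needs one α and one β chain, so the scarcer
  chain bounds the assembled heterodimers;
* with an external gene count table, **proteasome summaries**:
  constitutive = median(PSMB5, PSMB6, PSMB7), immunoproteasome =
  median(PSMB8, PSMB9, PSMB10).

Across a cohort, `buildBodyMap()` aggregates per-tissue medians,
positivity fractions (share of samples strictly above a threshold,
default 1 RPKM), outlier flags (e.g. class I above 900 RPKM) and
Spearman rank correlations across tissue medians.

A deterministic read simulator (`simulateAlleleDb()`, `simulateSample()`,
`simulateCohort()`) emits references, paired FASTQ and cohorts with
known genotype/abundance ground truth, so the whole pipeline is
validated end to end without any external data. Intended users are
immunogenomics and tumour-immunology analysts who need HLA-aware
expression estimates, and method developers who need a transparent,
fully testable baseline.

## Worked example

Simulate a donor with known genotypes, type and quantify it:

```r
library(hlamap)

ref <- simulateAlleleDb(loci = c("A","B","C","G","DQA1","DQB1"),
                        allelesPerLocus = 4, alleleLength = 500, seed = 7)
ref <- buildKmerIndex(ref, k = 16)
sim <- simulateSample(ref,
  genotypes = list(A = c("A*01:01","A*02:01"), B = "B*01:02", C = "C*02:01",
                   G = "G*01:01", DQA1 = c("DQA1*01:01","DQA1*02:02"),
                   DQB1 = "DQB1*01:01"),
  levels = c(A = 10, B = 6, C = 5, G = 2, DQA1 = 3, DQB1 = 4),
  totalPairs = 3000, errorRate = 0.005, seed = 8)

ty <- typeSample(sim$fq1, sim$fq2, ref, sample = "donor1")
ty$genotypes
#>  sample locus    allele1    allele2 support1 support2     zygosity confidence
#>  donor1     A    A*01:01    A*02:01      519      486 heterozygous  0.9671642
#>  donor1     B    B*01:02       <NA>      576       NA   homozygous  1.0000000
#>  donor1     C    C*02:01       <NA>      492       NA   homozygous  1.0000000
#>  donor1     G    G*01:01       <NA>      220       NA   homozygous  1.0000000
#>  donor1  DQA1 DQA1*01:01 DQA1*02:02      155      136 heterozygous  0.9347079
#>  donor1  DQB1 DQB1*01:01       <NA>      413       NA   homozygous  0.9975845

prof <- quantifySample(ty, ref, sample = "donor1", tissue = "whole_blood")
round(profileRpkm(prof), 1)
#>        A        B        C        G     DQA1     DQB1
#> 670000.0 384000.0 328000.0 146666.7 194000.0 276000.0
round(expectedRpkm(sim$truth), 1)  # simulator's ground-truth oracle
#>        A        B        C        G     DQA1     DQB1
#> 670000.0 384000.0 328000.0 147333.3 194000.0 276666.7
```

Every simulated genotype is recovered, heterozygotes with balanced
support (confidence near 1), and the quantified RPKM matches the
truth-implied oracle to within the few reads lost to sequencing-error
mismatch budgets (the absolute values are large only because this toy
sample has 3,000 pairs in the RPKM denominator). With more loci the
profile also reports `classI_classical`, `classII_composite` and — given
a PSMB5–10 count table — the proteasome summaries, and a list of
profiles feeds `cohortMatrix()` → `buildBodyMap()`.

A thin command-line front end over the same functions is installed at
`inst/scripts/hlamap-cli.R` with `type`, `quantify`, `bodymap`,
`simulate-db`, `simulate-sample` and `simulate-cohort` subcommands.

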