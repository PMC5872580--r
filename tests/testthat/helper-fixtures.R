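# In-code fixtures: toy references and read pairs built on the fly.

writeToyFasta <- function(seqs) {
  fa <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(seqs), "\n", seqs), fa)
  fa
}

makeToyRef <- function(seqs, k = 16) {
  ref <- readAlleleReference(writeToyFasta(seqs))
  if (!is.null(k)) ref <- buildKmerIndex(ref, k)
  ref
}

randSeq <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# Deterministic substitutions at given 1-based positions.
mutateAt <- function(s, pos) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}

# An exact (error-free) FR pair copied from a template sequence.
pairFrom <- function(s, start, readLen = 40, fragLen = 80) {
  m1 <- substr(s, start, start + readLen - 1)
  m2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    substr(s, start + fragLen - readLen, start + fragLen - 1))))
  list(mate1 = m1, mate2 = m2)
}

readsDf <- function(pairs) data.frame(
  read_id = sprintf("r%03d", seq_along(pairs)),
  mate1 = vapply(pairs, `[[`, character(1), "mate1"),
  mate2 = vapply(pairs, `[[`, character(1), "mate2"),
  stringsAsFactors = FALSE
)

# One heterozygote-recovery replicate: two same-locus alleles a fixed
# number of substitutions apart, balanced 1:1 simulation, full typing.
# Returns TRUE when the 4-digit call equals the simulated truth.
hetRecovered <- function(seed, errorRate = 0, pairsPerAllele = 40,
                         nDiff = 8, alleleLength = 400) {
  set.seed(seed)
  a1 <- randSeq(alleleLength)
  a2 <- mutateAt(a1, sample(seq(60, alleleLength - 60), nDiff))
  ref <- makeToyRef(c("A*01:01" = a1, "A*02:01" = a2), k = 16)
  sim <- simulateSample(ref, genotypes = list(A = c("A*01:01", "A*02:01")),
                        levels = c(A = 1), totalPairs = 2 * pairsPerAllele,
                        errorRate = errorRate, seed = seed + 7)
  ty <- typeSample(sim$fq1, sim$fq2, ref)
  g <- ty$genotypes[ty$genotypes$locus == "A", ]
  identical(sort(c(g$allele1, g$allele2)), c("A*01:01", "A*02:01"))
}
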