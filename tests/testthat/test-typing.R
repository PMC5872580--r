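test_that("exact pairs hit exactly the alleles containing both mates", {
  set.seed(10)
  shared <- randSeq(120)
  a1 <- paste0(randSeq(30), shared, randSeq(30))
  a2 <- paste0(randSeq(25), shared, randSeq(35))
  a3 <- randSeq(180)
  ref <- makeToyRef(c("A*01:01" = a1, "A*02:01" = a2, "B*01:01" = a3), k = 16)
  p <- pairFrom(shared, 1, readLen = 40, fragLen = 100)
  hits <- alignReadPairs(readsDf(list(p)), ref, maxMismatch = 0)
  expect_setequal(hits$name, c("A*01:01", "A*02:01"))
  expect_true(all(hits$mismatches == 0))
})

test_that("pairs beyond the mismatch budget return no hits", {
  set.seed(11)
  a1 <- randSeq(200)
  ref <- makeToyRef(c("A*01:01" = a1), k = 16)
  p <- pairFrom(a1, 10, readLen = 40, fragLen = 100)
  p$mate1 <- mutateAt(p$mate1, c(1, 9, 18, 27, 36)) # 5 substitutions
  hits <- alignReadPairs(readsDf(list(p)), ref, maxMismatch = 4)
  expect_equal(nrow(hits), 0L)
})

test_that("an equidistant pair reports both same-group alleles in the best stratum", {
  set.seed(12)
  a1 <- randSeq(200)
  a2 <- mutateAt(a1, c(20, 30)) # two diagnostic positions inside mate1 window
  ref <- makeToyRef(c("A*01:01" = a1, "A*01:02" = a2), k = 8)
  p <- pairFrom(a1, 11, readLen = 40, fragLen = 100) # covers 11..50 and 71..110
  # give mate1 allele2's base at position 20 -> 1 mismatch to each allele
  p$mate1 <- paste0(substr(p$mate1, 1, 9),
                    substr(a2, 20, 20), substr(p$mate1, 11, 40))
  hits <- alignReadPairs(readsDf(list(p)), ref, maxMismatch = 2)
  expect_setequal(hits$name, c("A*01:01", "A*01:02"))
  expect_equal(hits$mismatches, c(1, 1))
  # agrees with the brute-force oracle
  bf <- bfPairHits(p$mate1, p$mate2,
                   setNames(as.character(alleleSequences(ref)),
                            alleleInfo(ref)$record), 2)
  expect_setequal(hits$record, bf$record)
})

test_that("a mate shorter than k leaves the pair unmapped, not an error", {
  set.seed(13)
  a1 <- randSeq(100)
  ref <- makeToyRef(c("A*01:01" = a1), k = 16)
  reads <- data.frame(read_id = "r1", mate1 = substr(a1, 1, 10),
                      mate2 = substr(a1, 1, 40), stringsAsFactors = FALSE)
  hits <- alignReadPairs(reads, ref, maxMismatch = 2)
  expect_equal(nrow(hits), 0L)
  asg <- assignReadsToLoci(hits, "r1")
  expect_equal(asg$counts$unmapped, 1L)
})

test_that("seeded aligner equals the brute-force oracle on random toy instances", {
  set.seed(14)
  for (inst in 1:25) {
    nAll <- sample(2:6, 1)
    base <- randSeq(160)
    seqs <- vapply(seq_len(nAll), function(i)
      mutateAt(base, sample(160, sample(0:6, 1))), character(1))
    names(seqs) <- paste0("A*", sprintf("%02d", seq_len(nAll)), ":01")
    ref <- makeToyRef(seqs, k = 8)
    recChars <- setNames(as.character(alleleSequences(ref)),
                         alleleInfo(ref)$record)
    maxMM <- sample(0:3, 1)
    for (r in 1:8) {
      src <- seqs[[sample(nAll, 1)]]
      p <- pairFrom(src, sample(1:60, 1), readLen = 40, fragLen = 90)
      nmut <- sample(0:3, 1)
      if (nmut) p$mate1 <- mutateAt(p$mate1, sample(40, nmut))
      hits <- alignReadPairs(readsDf(list(p)), ref, maxMismatch = maxMM)
      bf <- bfPairHits(p$mate1, p$mate2, recChars, maxMM)
      expect_setequal(hits$record, bf$record)
      if (nrow(bf)) {
        expect_equal(sort(hits$mismatches), sort(bf$mismatches))
      }
    }
  }
})

test_that("group vote arithmetic: stray reads do not trigger a second group", {
  # 100 pairs compatible only with A group 02, 1 stray pair on group 03
  hits <- data.frame(
    read_id = c(sprintf("r%03d", 1:100), "r101"),
    record = c(rep("A*02:01", 100), "A*03:01"),
    name = c(rep("A*02:01", 100), "A*03:01"),
    locus = "A",
    group = c(rep("02", 100), "03"),
    mismatches = 0L, pos1 = 0L, pos2 = 0L, orientation = "FR",
    stringsAsFactors = FALSE
  )
  ref <- makeToyRef(c("A*02:01" = strrep("ACGT", 10),
                      "A*03:01" = strrep("TGCA", 10)), k = NULL)
  asg <- assignReadsToLoci(hits, unique(hits$read_id))
  g <- callGenotypes(hits, asg, ref, thetaHet = 0.1)
  g <- g[g$locus == "A", ]
  expect_equal(g$allele1, "A*02:01")
  expect_equal(g$zygosity, "homozygous")
  expect_equal(g$support1, 100L)
  expect_equal(g$confidence, 1 - 1 / 101)
})

test_that("a balanced heterozygote across groups is called with both groups", {
  set.seed(15)
  a1 <- randSeq(300)
  a2 <- mutateAt(a1, sample(50:250, 25)) # >= 20 mismatches apart
  ref <- makeToyRef(c("A*02:01" = a1, "A*24:02" = a2), k = 16)
  sim <- simulateSample(ref, genotypes = list(A = c("A*02:01", "A*24:02")),
                        levels = c(A = 1), totalPairs = 60, seed = 77)
  ty <- typeSample(sim$fq1, sim$fq2, ref)
  g <- ty$genotypes[ty$genotypes$locus == "A", ]
  expect_equal(g$zygosity, "heterozygous")
  expect_setequal(c(g$allele1, g$allele2), c("A*02:01", "A*24:02"))
  expect_gte(g$support1, g$support2)
})

test_that("homozygous and within-group heterozygous calls recover simulation truth", {
  set.seed(16)
  g1 <- randSeq(350)
  ref <- makeToyRef(c("G*01:01" = g1, "G*01:02" = mutateAt(g1, seq(30, 330, by = 40))),
                    k = 16)
  sim <- simulateSample(ref, genotypes = list(G = "G*01:01"),
                        levels = c(G = 1), totalPairs = 50, seed = 5)
  ty <- typeSample(sim$fq1, sim$fq2, ref)
  g <- ty$genotypes[ty$genotypes$locus == "G", ]
  expect_equal(g$zygosity, "homozygous")
  expect_equal(g$allele1, "G*01:01")
  expect_true(is.na(g$allele2))

  # 1:1 within-locus heterozygote, different groups
  d1 <- randSeq(400)
  d2 <- mutateAt(d1, sample(60:340, 20))
  refD <- makeToyRef(c("DQA1*01:02" = d1, "DQA1*05:05" = d2), k = 16)
  simD <- simulateSample(refD, genotypes = list(DQA1 = c("DQA1*01:02", "DQA1*05:05")),
                         levels = c(DQA1 = 1), totalPairs = 80, seed = 6)
  tyD <- typeSample(simD$fq1, simD$fq2, refD)
  gD <- tyD$genotypes[tyD$genotypes$locus == "DQA1", ]
  expect_equal(gD$zygosity, "heterozygous")
  expect_setequal(c(gD$allele1, gD$allele2), c("DQA1*01:02", "DQA1*05:05"))
  expect_gte(gD$confidence, 0.9)
})

test_that("alleles identical at 4-digit truncation resolve by lexicographic tie-break", {
  set.seed(17)
  s <- randSeq(200)
  ref <- makeToyRef(c("A*01:02" = s, "A*01:01" = s), k = 16)
  sim <- simulateSample(ref, genotypes = list(A = "A*01:02"),
                        levels = c(A = 1), totalPairs = 30, seed = 9)
  ty <- typeSample(sim$fq1, sim$fq2, ref)
  g <- ty$genotypes[ty$genotypes$locus == "A", ]
  # identical sequences: every read supports both; deterministic winner
  expect_equal(g$allele1, "A*01:01")
  expect_equal(g$zygosity, "homozygous")
})

test_that("locus assignment excludes cross-locus ambiguity and conserves counts", {
  set.seed(18)
  shared <- randSeq(150)
  refAB <- makeToyRef(c("A*01:01" = paste0(shared, randSeq(50)),
                        "B*01:01" = paste0(shared, randSeq(50))), k = 16)
  pAmb <- pairFrom(shared, 1, readLen = 40, fragLen = 100)
  hits <- alignReadPairs(readsDf(list(pAmb)), refAB, maxMismatch = 0)
  expect_setequal(hits$locus, c("A", "B"))
  asg <- assignReadsToLoci(hits, "r001")
  expect_equal(asg$assignment$status, "ambiguous")
  expect_equal(asg$counts$ambiguous, 1L)

  # hand count: 1 unique DRA read, 99 DRB1 reads
  hits2 <- data.frame(
    read_id = sprintf("r%03d", 1:100),
    record = c("DRA*01:01", rep("DRB1*01:01", 99)),
    name = c("DRA*01:01", rep("DRB1*01:01", 99)),
    locus = c("DRA", rep("DRB1", 99)),
    group = "01", mismatches = 0L, pos1 = 0L, pos2 = 0L, orientation = "FR",
    stringsAsFactors = FALSE
  )
  asg2 <- assignReadsToLoci(hits2, sprintf("r%03d", 1:100))
  expect_equal(asg2$locusCounts[["DRA"]], 1L)
  expect_equal(asg2$locusCounts[["DRB1"]], 99L)

  # conservation over random simulated samples
  ref <- simulateAlleleDb(loci = c("A", "B", "E"), allelesPerLocus = 2,
                          alleleLength = 300, seed = 31)
  ref <- buildKmerIndex(ref, 16)
  sim <- simulateSample(ref, genotypes = list(A = "A*01:01", E = "E*01:02"),
                        levels = c(A = 3, E = 1), totalPairs = 120,
                        errorRate = 0.01, seed = 32)
  ty <- typeSample(sim$fq1, sim$fq2, ref)
  cc <- ty$assignment$counts
  expect_equal(cc$assigned + cc$ambiguous + cc$unmapped, cc$total)
  expect_equal(cc$total, 120L)
})

test_that("error-free heterozygote recovery is exact across seeded replicates", {
  ok <- vapply(1:12, hetRecovered, logical(1), errorRate = 0)
  expect_true(all(ok))
})

test_that("genotype table round-trips through its TSV writer", {
  g <- data.frame(sample = "s1", locus = "A", allele1 = "A*01:01",
                  allele2 = NA_character_, support1 = 10L,
                  support2 = NA_integer_, zygosity = "homozygous",
                  confidence = 1, stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  writeGenotypes(g, f)
  back <- read.delim(f, stringsAsFactors = FALSE)
  expect_equal(back$allele1, "A*01:01")
  expect_equal(back$support1, 10L)
})
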