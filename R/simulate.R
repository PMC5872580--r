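# Mutate a nucleotide string at a per-base substitution rate (always to
# a different base). Uses the caller's RNG stream.
.mutateSeq <- function(s, rate) {
  if (rate <= 0) return(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    for (i in hit)
      chars[i] <- sample(setdiff(bases, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

.randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a synthetic HLA allele reference with known structure
#'
#' Draws one ancestral sequence per locus by mutating a global root at
#' the between-locus rate, then derives each allele from its locus
#' ancestor at the within-locus rate. Names are assigned sequentially
#' as \code{locus*GG:PP}: groups advance every two alleles (alleles
#' \code{2i-1, 2i} are \code{GG=i}, proteins 01/02), so both
#' group-level and within-group 4-digit resolution are represented.
#' Fully deterministic for a fixed seed.
#'
#' @param loci Character vector of loci (subset of [hlaLoci()]).
#' @param allelesPerLocus Alleles per locus.
#' @param alleleLength Allele length in bp.
#' @param withinDivergence Per-base substitution rate allele vs locus
#'   ancestor, in (0, 0.5).
#' @param betweenDivergence Per-base rate locus ancestor vs global
#'   root, in (0, 0.5); must exceed \code{withinDivergence}.
#' @param seed Integer seed (mandatory).
#' @return An [HLAReference] (no k-mer index yet).
#' @export
simulateAlleleDb <- function(loci = hlaLoci(), allelesPerLocus = 4L,
                             alleleLength = 500L,
                             withinDivergence = 0.02,
                             betweenDivergence = 0.2, seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  if (!all(loci %in% hlaLoci()))
    stop("unsupported locus in 'loci'")
  if (withinDivergence < 0 || withinDivergence >= 0.5 ||
      betweenDivergence <= 0 || betweenDivergence >= 0.5)
    stop("divergences must lie in (0, 0.5)")
  if (betweenDivergence <= withinDivergence)
    stop("betweenDivergence must exceed withinDivergence")
  withSeed(seed, {
    root <- .randomSeq(alleleLength)
    seqs <- character(0)
    toks <- character(0)
    for (L in loci) {
      anc <- .mutateSeq(root, betweenDivergence)
      for (a in seq_len(allelesPerLocus)) {
        gg <- sprintf("%02d", (a - 1L) %/% 2L + 1L)
        pp <- sprintf("%02d", (a - 1L) %% 2L + 1L)
        toks <- c(toks, paste0(L, "*", gg, ":", pp))
        seqs <- c(seqs, .mutateSeq(anc, withinDivergence))
      }
    }
    fa <- tempfile(fileext = ".fasta")
    writeLines(paste0(">", toks, "\n", seqs), fa)
    ref <- readAlleleReference(fa)
    unlink(fa)
    ref
  })
}

#' Simulate a paired-end RNA-Seq sample with known truth
#'
#' Pairs are drawn multinomially over the genotype's alleles with
#' probability proportional to expression level times allele length
#' (length-proportional fragment sampling, so RPKM — a
#' length-normalised quantity — has a clean expected value). Fragment
#' starts are uniform over valid positions; mate 2 is the
#' reverse-complemented fragment end; substitution errors are i.i.d.
#' per base. Heterozygous loci split their level between the two
#' alleles according to \code{imbalance} (default 1:1).
#'
#' @param ref An [HLAReference] containing every genotype allele.
#' @param genotypes Named list: locus -> character vector of one
#'   (homozygous) or two (heterozygous) 4-digit allele names.
#' @param levels Named numeric: locus -> relative expression level
#'   (>= 0).
#' @param totalPairs Number of read pairs to draw.
#' @param readLength,fragmentLength Read and fragment lengths in bp
#'   (\code{fragmentLength >= readLength}; fragments must fit in every
#'   expressed allele).
#' @param errorRate Per-base substitution error rate in [0, 1).
#' @param seed Integer seed (mandatory).
#' @param dir Output directory for \code{R1.fastq}/\code{R2.fastq}
#'   (default: a fresh tempdir).
#' @return list with \code{fq1}, \code{fq2} (paths) and \code{truth}:
#'   genotypes, per-allele expected and realised pair counts
#'   (\code{abundances}), allele lengths, read/fragment length, error
#'   rate, seed, totalPairs.
#' @export
simulateSample <- function(ref, genotypes, levels, totalPairs,
                           readLength = 50L, fragmentLength = 150L,
                           errorRate = 0, seed, dir = NULL) {
  stopifnot(is(ref, "HLAReference"))
  if (missing(seed)) stop("'seed' is mandatory")
  if (fragmentLength < readLength)
    stop("fragmentLength must be >= readLength")
  if (errorRate < 0 || errorRate >= 1) stop("errorRate must be in [0, 1)")
  info <- ref@info
  if (is.null(names(genotypes)) || !all(names(genotypes) %in% info$locus))
    stop("genotype loci must exist in the reference")
  .checkNonNegative(unlist(levels), "levels")

  # one representative record per 4-digit truth allele
  alleleRec <- character(0)
  alleleLocus <- character(0)
  weight <- numeric(0)
  for (L in names(genotypes)) {
    als <- genotypes[[L]]
    if (!length(als) || length(als) > 2L)
      stop("genotype for ", L, " must list 1 or 2 alleles")
    if (!all(als %in% info$name))
      stop("allele(s) not in reference: ",
           paste(setdiff(als, info$name), collapse = ", "))
    lev <- if (L %in% names(levels)) levels[[L]] else 0
    split <- if (length(als) == 2L) c(0.5, 0.5) else 1
    for (j in seq_along(als)) {
      rec <- info$record[info$name == als[j]][1]
      alleleRec <- c(alleleRec, rec)
      alleleLocus <- c(alleleLocus, L)
      weight <- c(weight, lev * split[j] * info$length[info$record == rec])
    }
  }
  recLens <- setNames(info$length, info$record)
  tooShort <- recLens[alleleRec] < fragmentLength & weight > 0
  if (any(tooShort))
    stop("fragment longer than allele(s): ",
         paste(alleleRec[tooShort], collapse = ", "))
  if (sum(weight) == 0) stop("all expression levels are zero")

  withSeed(seed, {
    drawn <- as.integer(rmultinom(1, totalPairs, weight / sum(weight)))
    chars <- setNames(as.character(ref@sequences), info$record)
    m1 <- character(totalPairs)
    m2 <- character(totalPairs)
    src <- character(totalPairs)
    pos <- 1L
    for (j in seq_along(alleleRec)) {
      nj <- drawn[j]
      if (nj == 0L) next
      s <- chars[[alleleRec[j]]]
      L <- nchar(s)
      starts <- sample.int(L - fragmentLength + 1L, nj, replace = TRUE)
      frag1 <- substring(s, starts, starts + readLength - 1L)
      frag2 <- .revComp(substring(s, starts + fragmentLength - readLength,
                                  starts + fragmentLength - 1L))
      if (errorRate > 0) {
        frag1 <- vapply(frag1, .mutateSeq, character(1), rate = errorRate,
                        USE.NAMES = FALSE)
        frag2 <- vapply(frag2, .mutateSeq, character(1), rate = errorRate,
                        USE.NAMES = FALSE)
      }
      idx <- pos:(pos + nj - 1L)
      m1[idx] <- frag1
      m2[idx] <- frag2
      src[idx] <- alleleRec[j]
      pos <- pos + nj
    }
    ids <- sprintf("read%06d", seq_len(totalPairs))

    if (is.null(dir)) dir <- tempfile("sim")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fq1 <- file.path(dir, "R1.fastq")
    fq2 <- file.path(dir, "R2.fastq")
    writeFq <- function(seqs, path) {
      x <- DNAStringSet(seqs)
      names(x) <- ids
      writeXStringSet(x, filepath = path, format = "fastq",
                      qualities = BStringSet(strrep("I", nchar(seqs))))
    }
    writeFq(m1, fq1)
    writeFq(m2, fq2)

    truth <- list(
      genotypes = genotypes,
      abundances = setNames(drawn, alleleRec),
      alleleLocus = setNames(alleleLocus, alleleRec),
      alleleLengths = recLens[alleleRec],
      sourceAllele = setNames(src, ids),
      readLength = as.integer(readLength),
      fragmentLength = as.integer(fragmentLength),
      errorRate = errorRate,
      seed = as.integer(seed),
      totalPairs = as.integer(totalPairs)
    )
    list(fq1 = fq1, fq2 = fq2, truth = truth)
  })
}

#' Expected per-locus RPKM implied by simulation truth
#'
#' For each simulated locus: realised pair count over its alleles,
#' mean truth-allele length, and the sample's total pairs, pushed
#' through the RPKM formula. This is the oracle quantification against
#' which [quantifySample()] output is compared in recovery tests.
#'
#' @param truth The \code{truth} element of [simulateSample()].
#' @param totalPairs Optional override of the denominator (default:
#'   the truth's total).
#' @return Named numeric: locus -> expected RPKM.
#' @export
expectedRpkm <- function(truth, totalPairs = truth$totalPairs) {
  loci <- unique(truth$alleleLocus)
  out <- setNames(numeric(length(loci)), loci)
  for (L in loci) {
    recs <- names(truth$alleleLocus)[truth$alleleLocus == L]
    cnt <- sum(truth$abundances[recs])
    len <- mean(truth$alleleLengths[recs])
    out[L] <- if (cnt == 0) 0 else rpkm(cnt, len, totalPairs)
  }
  out
}

#' Simulate tissue medians with a target Spearman correlation
#'
#' Builds two metric median vectors across tissues whose rank
#' correlation equals the target by construction: metric B's rank
#' permutation is derived from metric A's by seeded random swaps until
#' the Spearman statistic \code{1 - 6*sum(d^2)/(n(n^2-1))} is as close
#' to \code{rho} as the rank lattice allows (within one swap step).
#' Ranks are then mapped monotonically onto a log-normal RPKM scale,
#' which leaves the rank correlation untouched.
#'
#' @param nTissues Number of tissues (>= 4).
#' @param rho Target Spearman correlation in (-1, 1].
#' @param seed Integer seed.
#' @param meanlog,sdlog Log-scale location/spread of the median
#'   magnitudes.
#' @return data.frame \code{tissue}, \code{metricA}, \code{metricB}.
#' @export
simulateCorrelatedMedians <- function(nTissues, rho, seed,
                                      meanlog = log(50), sdlog = 1) {
  if (rho > 1 || rho <= -1) stop("'rho' must be in (-1, 1]")
  if (nTissues < 4) stop("need at least 4 tissues")
  withSeed(seed, {
    n <- nTissues
    rankA <- seq_len(n)
    rankB <- seq_len(n)
    targetSS <- (1 - rho) * n * (n^2 - 1) / 6
    ss <- 0
    # random transpositions, accepted while they move sum(d^2) toward target
    for (iter in seq_len(50L * n)) {
      if (abs(ss - targetSS) < n) break
      ij <- sample.int(n, 2L)
      newB <- rankB
      newB[ij] <- newB[rev(ij)]
      newSS <- sum((rankA - newB)^2)
      if (abs(newSS - targetSS) < abs(ss - targetSS)) {
        rankB <- newB
        ss <- newSS
      }
    }
    # monotone rank -> magnitude map preserves Spearman exactly
    mags <- function(rk) exp(meanlog + sdlog * qnorm(rk / (n + 1)))
    shuffle <- sample.int(n) # decouple tissue label from rank order
    data.frame(
      tissue = sprintf("tissue%02d", seq_len(n)),
      metricA = mags(rankA)[shuffle],
      metricB = mags(rankB)[shuffle],
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a cohort matrix around given tissue medians
#'
#' Per-sample metric values are drawn log-normally around each
#' tissue's median (the median of a log-normal is exp(mu), so the
#' generating medians are recovered as sample medians). Outliers can
#' be planted at fixed values. Deterministic per seed.
#'
#' @param tissueMedians data.frame with a \code{tissue} column and one
#'   numeric column per metric holding the tissue median (zeros stay
#'   exactly zero).
#' @param samplesPerTissue Integer scalar or per-tissue vector.
#' @param sdlog Log-normal spread of samples around their tissue
#'   median (0 = every sample equals the median).
#' @param outliers Optional data.frame \code{tissue}, \code{metric},
#'   \code{n}, \code{value}: in each listed tissue, \code{n} samples
#'   have \code{metric} overwritten with \code{value}.
#' @param seed Integer seed (mandatory).
#' @return list with \code{cohort} (data.frame \code{sample},
#'   \code{tissue}, metrics), \code{manifest} (\code{sample},
#'   \code{tissue}) and \code{truth} (the inputs, plus planted outlier
#'   sample ids).
#' @export
simulateCohort <- function(tissueMedians, samplesPerTissue, sdlog = 0.5,
                           outliers = NULL, seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  if (!"tissue" %in% names(tissueMedians))
    stop("tissueMedians needs a 'tissue' column")
  metrics <- setdiff(names(tissueMedians), "tissue")
  if (!length(metrics)) stop("tissueMedians has no metric columns")
  tissues <- tissueMedians$tissue
  nPer <- rep_len(samplesPerTissue, length(tissues))
  withSeed(seed, {
    rows <- list()
    plantedIds <- character(0)
    for (ti in seq_along(tissues)) {
      tt <- tissues[ti]
      n <- nPer[ti]
      ids <- sprintf("%s_s%03d", tt, seq_len(n))
      d <- data.frame(sample = ids, tissue = tt, stringsAsFactors = FALSE)
      for (m in metrics) {
        mu <- tissueMedians[[m]][ti]
        d[[m]] <- if (mu == 0) rep(0, n) else mu * exp(rnorm(n, 0, sdlog))
      }
      if (!is.null(outliers)) {
        ol <- outliers[outliers$tissue == tt, , drop = FALSE]
        for (oi in seq_len(nrow(ol))) {
          pick <- sample.int(n, ol$n[oi])
          d[[ol$metric[oi]]][pick] <- ol$value[oi]
          plantedIds <- c(plantedIds, ids[pick])
        }
      }
      rows[[ti]] <- d
    }
    cohort <- do.call(rbind, rows)
    list(
      cohort = cohort,
      manifest = cohort[, c("sample", "tissue")],
      truth = list(tissueMedians = tissueMedians, sdlog = sdlog,
                   samplesPerTissue = nPer, seed = as.integer(seed),
                   plantedOutliers = sort(unique(plantedIds)))
    )
  })
}
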