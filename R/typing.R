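#' Read a pair of FASTQ files into a read-pair table
#'
#' @param fq1,fq2 Paths to the mate-1 and mate-2 FASTQ files (4-line
#'   records, Phred+33; qualities are ignored by the default aligner
#'   configuration).
#' @return data.frame with columns \code{read_id}, \code{mate1},
#'   \code{mate2} (plain character sequences).
#' @export
readFastqPairs <- function(fq1, fq2) {
  s1 <- readDNAStringSet(fq1, format = "fastq")
  s2 <- readDNAStringSet(fq2, format = "fastq")
  if (length(s1) != length(s2))
    stop("mate files differ in read count: ", length(s1), " vs ", length(s2))
  ids <- sub("[/ ].*$", "", names(s1))
  data.frame(read_id = ids,
             mate1 = as.character(s1),
             mate2 = as.character(s2),
             stringsAsFactors = FALSE)
}

# Best ungapped end-to-end placement per reference record for one mate
# sequence in one orientation. Candidates come from k-mer seeds at
# non-overlapping offsets (plus the final window); by pigeonhole this is
# exhaustive whenever the mate carries fewer than floor(len/k)
# mismatches against the record.
.matePlacements <- function(s, k, idxEnv, recChars, recLens, maxMM) {
  len <- nchar(s)
  if (len < k) return(NULL)
  offs <- unique(c(seq.int(1L, len - k + 1L, by = k), len - k + 1L))
  recs <- integer(0)
  st <- integer(0)
  for (off in offs) {
    km <- substr(s, off, off + k - 1L)
    m <- get0(km, envir = idxEnv, inherits = FALSE)
    if (is.null(m)) next
    start0 <- m[, "pos"] - (off - 1L)
    ok <- start0 >= 0L & (start0 + len) <= recLens[m[, "rec"]]
    if (!any(ok)) next
    recs <- c(recs, m[ok, "rec"])
    st <- c(st, start0[ok])
  }
  if (!length(recs)) return(NULL)
  keep <- !duplicated(recs * (max(st) + 1) + st)
  recs <- recs[keep]
  st <- st[keep]
  mm <- vapply(seq_along(recs), function(j)
    .mismatchCount(s, substr(recChars[recs[j]], st[j] + 1L, st[j] + len)),
    numeric(1))
  ok <- mm <= maxMM
  if (!any(ok)) return(NULL)
  recs <- recs[ok]; st <- st[ok]; mm <- mm[ok]
  o <- order(recs, mm, st)
  first <- !duplicated(recs[o])
  list(rec = recs[o][first], pos = st[o][first], mm = mm[o][first])
}

# Combine mate-1 and mate-2 placements on shared records.
.combineMates <- function(p1, p2, label) {
  if (is.null(p1) || is.null(p2)) return(NULL)
  j <- match(p2$rec, p1$rec)
  ok <- !is.na(j)
  if (!any(ok)) return(NULL)
  data.frame(rec = p2$rec[ok],
             mismatches = p1$mm[j[ok]] + p2$mm[ok],
             pos1 = p1$pos[j[ok]], pos2 = p2$pos[ok],
             orientation = label, stringsAsFactors = FALSE)
}

#' Align read pairs to an indexed allele reference
#'
#' For every pair, finds all alleles on which both mates admit an
#' ungapped end-to-end alignment in a mate-consistent orientation
#' (\code{FR}: mate 1 forward / mate 2 reverse-complement, or
#' \code{RF}: the converse), with total mismatches over both mates at
#' most \code{maxMismatch}. Only hits in the best (minimum-mismatch)
#' stratum of each pair are returned. Positions where either sequence
#' has N are not counted as mismatches. Pairs with a mate shorter than
#' the seed length are unmapped, not errors.
#'
#' The seeded search is exhaustive (identical to brute force over all
#' alleles, offsets and orientations) whenever each mate carries fewer
#' than \code{floor(mateLength / refK(ref))} mismatches against the
#' allele, by the pigeonhole principle over non-overlapping seeds.
#'
#' @param reads data.frame from [readFastqPairs()] (columns
#'   \code{read_id}, \code{mate1}, \code{mate2}).
#' @param ref An indexed [HLAReference].
#' @param maxMismatch Maximum total mismatches across both mates
#'   (default 4).
#' @return data.frame of hits: \code{read_id}, \code{record},
#'   \code{name}, \code{locus}, \code{group}, \code{mismatches},
#'   \code{pos1}, \code{pos2} (0-based), \code{orientation}.
#' @export
alignReadPairs <- function(reads, ref, maxMismatch = 4L) {
  stopifnot(is(ref, "HLAReference"))
  if (ref@k == 0L) stop("reference has no k-mer index; run buildKmerIndex()")
  if (maxMismatch < 0) stop("'maxMismatch' must be >= 0")
  k <- ref@k
  idx <- ref@index
  recChars <- as.character(ref@sequences)
  recLens <- ref@info$length
  m1 <- reads$mate1
  m2 <- reads$mate2
  m1rc <- .revComp(m1)
  m2rc <- .revComp(m2)

  out <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    p1F <- .matePlacements(m1[i], k, idx, recChars, recLens, maxMismatch)
    p2R <- .matePlacements(m2rc[i], k, idx, recChars, recLens, maxMismatch)
    p1R <- .matePlacements(m1rc[i], k, idx, recChars, recLens, maxMismatch)
    p2F <- .matePlacements(m2[i], k, idx, recChars, recLens, maxMismatch)
    h <- rbind(.combineMates(p1F, p2R, "FR"), .combineMates(p1R, p2F, "RF"))
    if (is.null(h) || !nrow(h)) next
    h <- h[h$mismatches <= maxMismatch, , drop = FALSE]
    if (!nrow(h)) next
    # best orientation per record, then best stratum across records
    o <- order(h$rec, h$mismatches)
    h <- h[o, , drop = FALSE]
    h <- h[!duplicated(h$rec), , drop = FALSE]
    h <- h[h$mismatches == min(h$mismatches), , drop = FALSE]
    h$read_id <- reads$read_id[i]
    out[[i]] <- h
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(rec = integer(0), mismatches = integer(0),
                      pos1 = integer(0), pos2 = integer(0),
                      orientation = character(0), read_id = character(0),
                      stringsAsFactors = FALSE)
  info <- ref@info
  res <- data.frame(
    read_id = out$read_id,
    record = info$record[out$rec],
    name = info$name[out$rec],
    locus = info$locus[out$rec],
    group = info$group[out$rec],
    mismatches = out$mismatches,
    pos1 = out$pos1, pos2 = out$pos2,
    orientation = out$orientation,
    stringsAsFactors = FALSE
  )
  # deterministic ordering: by read then allele name
  res[order(res$read_id, res$name, res$record), , drop = FALSE]
}

#' Assign read pairs to loci
#'
#' Each pair goes to the locus holding its best-stratum hits; pairs
#' whose best stratum spans two or more loci are cross-locus-ambiguous
#' and excluded from locus counts; pairs with no hits are unmapped.
#'
#' @param hits Hit table from [alignReadPairs()].
#' @param readIds Character vector of all pair identifiers in the
#'   sample (so unmapped pairs are accounted for).
#' @return list with \code{assignment} (data.frame \code{read_id},
#'   \code{status} in assigned/ambiguous/unmapped, \code{locus}),
#'   \code{locusCounts} (named integer), and \code{counts} (assigned,
#'   ambiguous, unmapped, total).
#' @export
assignReadsToLoci <- function(hits, readIds) {
  lociPerRead <- tapply(hits$locus, hits$read_id,
                        function(x) unique(x), simplify = FALSE)
  n <- vapply(lociPerRead, length, integer(1))
  status <- setNames(rep("unmapped", length(readIds)), readIds)
  locus <- setNames(rep(NA_character_, length(readIds)), readIds)
  mapped <- names(lociPerRead)
  status[mapped[n == 1L]] <- "assigned"
  status[mapped[n >= 2L]] <- "ambiguous"
  locus[mapped[n == 1L]] <- vapply(lociPerRead[n == 1L], `[`, character(1), 1L)
  assignment <- data.frame(read_id = readIds,
                           status = unname(status[readIds]),
                           locus = unname(locus[readIds]),
                           stringsAsFactors = FALSE)
  assigned <- assignment$locus[assignment$status == "assigned"]
  locusCounts <- if (length(assigned)) table(assigned) else table(character(0))
  list(
    assignment = assignment,
    locusCounts = setNames(as.integer(locusCounts), names(locusCounts)),
    counts = list(
      assigned = sum(assignment$status == "assigned"),
      ambiguous = sum(assignment$status == "ambiguous"),
      unmapped = sum(assignment$status == "unmapped"),
      total = length(readIds)
    )
  )
}

# Per-read group sets and vote shares for one locus' hits.
.groupVotes <- function(h) {
  groupsPerRead <- tapply(h$group, h$read_id, unique, simplify = FALSE)
  votes <- numeric(0)
  for (gs in groupsPerRead) {
    w <- 1 / length(gs)
    for (g in gs) votes[g] <- (if (is.na(votes[g])) 0 else votes[g]) + w
  }
  votes[order(-votes, names(votes))]
}

# Compatible-read counts and tie-break mismatch totals per 4-digit name.
.alleleSupport <- function(h) {
  # min mismatch per (read, name) over synonymous representatives
  key <- paste(h$read_id, h$name, sep = "\r")
  mm <- tapply(h$mismatches, key, min)
  parts <- strsplit(names(mm), "\r", fixed = TRUE)
  nm <- vapply(parts, `[`, character(1), 2L)
  reads <- vapply(parts, `[`, character(1), 1L)
  count <- tapply(reads, nm, function(x) length(unique(x)))
  mmTot <- tapply(mm, nm, sum)
  ord <- order(-as.numeric(count), as.numeric(mmTot), names(count))
  list(name = names(count)[ord],
       count = as.integer(count)[ord],
       mmTot = as.numeric(mmTot)[ord],
       readsByName = split(reads, nm))
}

#' Call a 4-digit genotype for every locus
#'
#' Two-pass procedure per locus over the pairs assigned to it:
#' \enumerate{
#'   \item \strong{Group pass} — each pair contributes one vote, split
#'     equally among the distinct 2-digit groups in its best stratum.
#'     The top group is always called; a second group is called iff its
#'     vote share among pairs incompatible with the top group exceeds
#'     \code{thetaHet} of all locus-informative pairs.
#'   \item \strong{Allele pass} — within each called group the 4-digit
#'     allele with the most compatible pairs wins (ties: fewer total
#'     mismatches, then lexicographic name).
#' }
#' Zygosity is heterozygous iff two groups were called, or two alleles
#' within one group each hold more than \code{thetaHet} of locus pairs
#' after exclusive assignment. Heterozygote confidence is the support
#' balance \code{min(1, 2*support2/(support1+support2))}; homozygote
#' confidence is one minus the exclusive share of the best non-called
#' allele.
#'
#' @param hits Hit table from [alignReadPairs()].
#' @param assignment Result of [assignReadsToLoci()].
#' @param ref The [HLAReference] (supplies the locus universe).
#' @param thetaHet Heterozygosity threshold in (0, 1); default 0.15.
#' @param sample Sample identifier for the output table.
#' @return data.frame with one row per locus present in the reference:
#'   \code{sample}, \code{locus}, \code{allele1}, \code{allele2},
#'   \code{support1}, \code{support2}, \code{zygosity}
#'   (homozygous/heterozygous/no_call), \code{confidence}.
#' @export
callGenotypes <- function(hits, assignment, ref, thetaHet = 0.15,
                          sample = "sample") {
  stopifnot(is(ref, "HLAReference"))
  if (thetaHet <= 0 || thetaHet >= 1) stop("'thetaHet' must be in (0, 1)")
  loci <- intersect(hlaLoci(), unique(ref@info$locus))
  asg <- assignment$assignment
  rows <- vector("list", length(loci))
  for (li in seq_along(loci)) {
    L <- loci[li]
    readsL <- asg$read_id[asg$status == "assigned" & asg$locus %in% L]
    nL <- length(readsL)
    if (nL == 0L) {
      rows[[li]] <- data.frame(sample = sample, locus = L,
                               allele1 = NA_character_, allele2 = NA_character_,
                               support1 = 0L, support2 = NA_integer_,
                               zygosity = "no_call", confidence = NA_real_,
                               stringsAsFactors = FALSE)
      next
    }
    hL <- hits[hits$read_id %in% readsL, , drop = FALSE]

    ## group pass
    votes <- .groupVotes(hL)
    g1 <- names(votes)[1]
    readsInG1 <- unique(hL$read_id[hL$group == g1])
    rest <- setdiff(readsL, readsInG1)
    g2 <- NA_character_
    if (length(rest)) {
      vRest <- .groupVotes(hL[hL$read_id %in% rest, , drop = FALSE])
      if (length(vRest) && vRest[1] / nL > thetaHet)
        g2 <- names(vRest)[1]
    }

    ## allele pass
    supG1 <- .alleleSupport(hL[hL$group == g1, , drop = FALSE])
    a1 <- supG1$name[1]
    s1 <- supG1$count[1]
    readsA1 <- unique(supG1$readsByName[[a1]])

    a2 <- NA_character_
    s2 <- NA_integer_
    zyg <- "homozygous"
    conf <- 1
    if (!is.na(g2)) {
      supG2 <- .alleleSupport(hL[hL$group == g2, , drop = FALSE])
      a2 <- supG2$name[1]
      s2 <- supG2$count[1]
      zyg <- "heterozygous"
    } else if (length(supG1$name) >= 2L) {
      # within-group heterozygote: both top alleles must own >thetaHet of
      # locus pairs after exclusive assignment
      cand <- supG1$name[2]
      readsCand <- unique(supG1$readsByName[[cand]])
      e1 <- length(setdiff(readsA1, readsCand))
      e2 <- length(setdiff(readsCand, readsA1))
      if (e1 / nL > thetaHet && e2 / nL > thetaHet) {
        a2 <- cand
        s2 <- supG1$count[2]
        zyg <- "heterozygous"
      }
    }

    if (zyg == "heterozygous") {
      if (s2 > s1) { # keep support1 >= support2
        tmp <- a1; a1 <- a2; a2 <- tmp
        tmp <- s1; s1 <- s2; s2 <- tmp
      }
      conf <- min(1, 2 * s2 / (s1 + s2))
    } else {
      others <- setdiff(supG1$name, a1)
      if (!is.na(g2)) stop("internal: homozygous with second group")
      if (length(others)) {
        exclShare <- max(vapply(others, function(nm)
          length(setdiff(unique(supG1$readsByName[[nm]]), readsA1)),
          numeric(1))) / nL
        conf <- 1 - exclShare
      }
      # stray groups never called also bound homozygote confidence
      otherGroupReads <- length(setdiff(readsL, readsInG1))
      conf <- min(conf, 1 - otherGroupReads / nL)
    }

    rows[[li]] <- data.frame(sample = sample, locus = L,
                             allele1 = a1, allele2 = a2,
                             support1 = as.integer(s1),
                             support2 = if (is.na(a2)) NA_integer_ else as.integer(s2),
                             zygosity = zyg, confidence = conf,
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Type one sample end to end
#'
#' Convenience wrapper: read the FASTQ pair, align against the indexed
#' reference, assign pairs to loci, and call per-locus genotypes.
#'
#' @param fq1,fq2 FASTQ paths (mate 1 / mate 2).
#' @param ref Indexed [HLAReference].
#' @param maxMismatch,thetaHet See [alignReadPairs()] and
#'   [callGenotypes()].
#' @param sample Sample identifier.
#' @return list with \code{genotypes} (data.frame), \code{hits},
#'   \code{assignment} (see [assignReadsToLoci()]), and
#'   \code{locusCounts}.
#' @export
typeSample <- function(fq1, fq2, ref, maxMismatch = 4L, thetaHet = 0.15,
                       sample = "sample") {
  reads <- readFastqPairs(fq1, fq2)
  hits <- alignReadPairs(reads, ref, maxMismatch = maxMismatch)
  assignment <- assignReadsToLoci(hits, reads$read_id)
  genotypes <- callGenotypes(hits, assignment, ref, thetaHet = thetaHet,
                             sample = sample)
  list(genotypes = genotypes, hits = hits, assignment = assignment,
       locusCounts = assignment$locusCounts)
}

#' Write a genotype table as TSV
#'
#' @param genotypes data.frame from [callGenotypes()].
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
writeGenotypes <- function(genotypes, file) {
  write.table(genotypes, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
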