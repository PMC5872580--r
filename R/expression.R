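#' Reads per kilobase per million mapped reads
#'
#' \code{rpkm = count / ((length_bp/1000) * (total_mapped/1e6))}. The
#' denominator counts each read pair once by convention in this
#' package (see [quantifySample()]).
#'
#' @param count Numeric vector of read (pair) counts, >= 0.
#' @param lengthBp Gene/allele length(s) in bp, > 0.
#' @param totalMapped Total mapped pairs in the sample, > 0.
#' @return Numeric vector of RPKM values.
#' @export
#' @examples
#' rpkm(100, 1000, 1e6) # 100
rpkm <- function(count, lengthBp, totalMapped) {
  .checkNonNegative(count, "count")
  if (any(lengthBp <= 0)) stop("'lengthBp' must be > 0")
  if (length(totalMapped) != 1L || totalMapped <= 0)
    stop("'totalMapped' must be a single value > 0")
  count / ((lengthBp / 1000) * (totalMapped / 1e6))
}

#' Convert RPKM values to TPM
#'
#' \code{tpm = rpkm / sum(rpkm) * 1e6}, so the output sums to one
#' million over the genes supplied.
#'
#' @param x Named numeric vector of RPKM values (>= 0, at least one
#'   positive).
#' @return Named numeric vector of TPM values.
#' @export
#' @examples
#' rpkmToTpm(c(g1 = 100, g2 = 300))
rpkmToTpm <- function(x) {
  .checkNonNegative(x, "rpkm")
  s <- sum(x)
  if (s == 0) stop("TPM undefined: all RPKM values are zero")
  x / s * 1e6
}

#' Composite HLA class II expression
#'
#' Each class II molecule is an alpha/beta heterodimer, so the
#' functional transcript level of a locus is bounded by its scarcer
#' chain. The composite is
#' \code{min(DPA1,DPB1) + min(DQA1,DQB1) + min(DRA,DRB1)}.
#'
#' @param dpa1,dpb1,dqa1,dqb1,dra,drb1 Non-negative RPKM values
#'   (vectorised).
#' @return Composite class II RPKM.
#' @export
#' @examples
#' classIIComposite(4, 2, 3, 5, 10, 6) # 2 + 3 + 6 = 11
classIIComposite <- function(dpa1, dpb1, dqa1, dqb1, dra, drb1) {
  vals <- cbind(dpa1, dpb1, dqa1, dqb1, dra, drb1)
  .checkNonNegative(vals, "class II chain RPKM")
  pmin(dpa1, dpb1) + pmin(dqa1, dqb1) + pmin(dra, drb1)
}

#' Total classical HLA class I expression
#'
#' The three classical heavy chains are summed: \code{A + B + C}.
#'
#' @param a,b,c Non-negative RPKM values (vectorised).
#' @return Total classical class I RPKM.
#' @export
classicalClassITotal <- function(a, b, c) {
  vals <- cbind(a, b, c)
  .checkNonNegative(vals, "class I RPKM")
  a + b + c
}

#' Read an external gene count table
#'
#' TSV with columns \code{gene}, \code{count}, \code{length_bp} for
#' non-HLA genes quantified outside this package (proteasome subunits
#' PSMB5..PSMB10, TAP1/2, marker genes, ...).
#'
#' @param file Path to the TSV.
#' @return data.frame with the three columns, checked for types.
#' @export
readGeneCounts <- function(file) {
  d <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("gene", "count", "length_bp")
  if (!all(need %in% names(d)))
    stop("count table must have columns: ", paste(need, collapse = ", "))
  if (any(is.na(d$count)) || any(d$count < 0))
    stop("counts must be non-negative")
  bad <- is.na(d$length_bp) | d$length_bp <= 0
  if (any(bad))
    stop("missing or non-positive length for gene(s): ",
         paste(d$gene[bad], collapse = ", "))
  d
}

#' Quantify one sample's HLA (and external gene) expression
#'
#' Per-locus counts are the pairs assigned to each locus by
#' [assignReadsToLoci()]; the effective locus length is the mean
#' sequence length of the called allele(s) (a single allele's length
#' when homozygous). RPKM and TPM are computed over the union of the
#' HLA loci and any externally counted genes; cross-locus-ambiguous
#' pairs are excluded from numerators but stay in the denominator. The
#' RPKM denominator defaults to all pairs in the sample (assigned +
#' ambiguous + unmapped); pass \code{totalMapped} to override, e.g.
#' for mate-counted compatibility runs.
#'
#' @param typed Result of [typeSample()] (or a list with
#'   \code{genotypes}, \code{assignment}).
#' @param ref The [HLAReference].
#' @param externalCounts Optional data.frame as from
#'   [readGeneCounts()].
#' @param totalMapped Optional override of the per-sample denominator.
#' @param sample,tissue Identifiers stored in the profile.
#' @return An [HLAExpressionProfile].
#' @export
quantifySample <- function(typed, ref, externalCounts = NULL,
                           totalMapped = NULL, sample = "sample",
                           tissue = NA_character_) {
  stopifnot(is(ref, "HLAReference"))
  genotypes <- typed$genotypes
  locusCounts <- typed$assignment$locusCounts
  if (is.null(locusCounts)) locusCounts <- typed$locusCounts
  if (is.null(totalMapped))
    totalMapped <- typed$assignment$counts$total
  if (is.null(totalMapped) || totalMapped <= 0)
    stop("'totalMapped' must be > 0")

  info <- ref@info
  loci <- intersect(hlaLoci(), unique(info$locus))
  # mean representative length per 4-digit name
  nameLen <- tapply(info$length, info$name, mean)

  counts <- setNames(numeric(length(loci)), loci)
  lens <- setNames(numeric(length(loci)), loci)
  for (L in loci) {
    counts[L] <- if (L %in% names(locusCounts)) locusCounts[[L]] else 0
    g <- genotypes[genotypes$locus == L, , drop = FALSE]
    called <- c(g$allele1, g$allele2)
    called <- called[!is.na(called)]
    lens[L] <- if (length(called)) mean(nameLen[called])
               else mean(info$length[info$locus == L])
  }

  genes <- loci
  geneCounts <- counts
  geneLens <- lens
  if (!is.null(externalCounts)) {
    need <- c("gene", "count", "length_bp")
    if (!all(need %in% names(externalCounts)))
      stop("externalCounts must have columns: ", paste(need, collapse = ", "))
    bad <- is.na(externalCounts$length_bp) | externalCounts$length_bp <= 0
    if (any(bad))
      stop("missing length for gene(s): ",
           paste(externalCounts$gene[bad], collapse = ", "))
    genes <- c(genes, externalCounts$gene)
    geneCounts <- c(geneCounts, setNames(externalCounts$count,
                                         externalCounts$gene))
    geneLens <- c(geneLens, setNames(externalCounts$length_bp,
                                     externalCounts$gene))
  }

  r <- rpkm(geneCounts, geneLens, totalMapped)
  names(r) <- genes
  t <- if (any(r > 0)) rpkmToTpm(r) else r * 0

  gv <- function(nm) if (nm %in% names(r)) r[[nm]] else 0
  metrics <- c(
    classI_classical = unname(classicalClassITotal(gv("A"), gv("B"), gv("C"))),
    classII_composite = unname(classIIComposite(
      gv("DPA1"), gv("DPB1"), gv("DQA1"), gv("DQB1"), gv("DRA"), gv("DRB1"))),
    hla_e = gv("E"), hla_f = gv("F"), hla_g = gv("G")
  )
  psmb <- paste0("PSMB", 5:10)
  if (all(psmb %in% genes)) {
    ps <- proteasomeSummary(gv("PSMB5"), gv("PSMB6"), gv("PSMB7"),
                            gv("PSMB8"), gv("PSMB9"), gv("PSMB10"))
    metrics <- c(metrics, proteasome_constitutive = unname(ps[["constitutive"]]),
                 proteasome_immuno = unname(ps[["immuno"]]))
  }

  new("HLAExpressionProfile", sample = sample, tissue = tissue,
      rpkm = r, tpm = t, metrics = metrics,
      totalMappedReads = as.numeric(totalMapped))
}

#' Write one profile (long) or a cohort matrix (wide) as TSV
#'
#' \code{writeProfile} emits gene, rpkm, tpm rows plus the composite
#' metrics; \code{cohortMatrix} binds many profiles into a wide
#' samples-by-metrics table suitable for [buildBodyMap()].
#'
#' @param profile An [HLAExpressionProfile].
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
writeProfile <- function(profile, file) {
  stopifnot(is(profile, "HLAExpressionProfile"))
  long <- rbind(
    data.frame(entry = names(profile@rpkm), rpkm = unname(profile@rpkm),
               tpm = unname(profile@tpm), stringsAsFactors = FALSE),
    data.frame(entry = names(profile@metrics),
               rpkm = unname(profile@metrics), tpm = NA_real_,
               stringsAsFactors = FALSE)
  )
  write.table(long, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeProfile
#' @param profiles list of [HLAExpressionProfile] objects.
#' @return \code{cohortMatrix}: data.frame with \code{sample},
#'   \code{tissue}, one column per metric, then one RPKM column per
#'   gene.
#' @export
cohortMatrix <- function(profiles) {
  stopifnot(length(profiles) > 0)
  rows <- lapply(profiles, function(p) {
    stopifnot(is(p, "HLAExpressionProfile"))
    cbind(data.frame(sample = p@sample, tissue = p@tissue,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(p@metrics)),
          as.data.frame(as.list(p@rpkm)))
  })
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    miss <- setdiff(cols, names(r))
    for (m in miss) r[[m]] <- NA_real_
    r[cols]
  })
  do.call(rbind, rows)
}
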