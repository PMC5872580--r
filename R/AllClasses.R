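#' HLAReference: an indexed polymorphic HLA allele reference
#'
#' Holds every reference allele sequence together with its parsed
#' 4-digit name, locus and 2-digit group, plus (after
#' [buildKmerIndex()]) a hashed k-mer seed index used by the read
#' aligner. Alleles identical at 4-digit resolution but differing in
#' later nomenclature fields are kept as multiple sequence
#' representatives of the same callable name.
#'
#' @slot sequences A [Biostrings::DNAStringSet] of allele sequences;
#'   names are unique record identifiers.
#' @slot info data.frame with one row per record: \code{record},
#'   \code{name} (4-digit, \code{locus*gg:pp}), \code{locus},
#'   \code{group} (2-digit field), \code{protein} (4-digit field),
#'   \code{length}, \code{raw} (original header token).
#' @slot k Integer seed length; 0 when no index has been built.
#' @slot index Environment hashing each k-mer (no Ns) to an integer
#'   matrix with columns \code{rec} (record index) and \code{pos}
#'   (0-based offset).
#' @slot skipped Integer count of records dropped for unsupported loci.
#'
#' @seealso [readAlleleReference()], [buildKmerIndex()], [alleleInfo()]
#' @export
setClass("HLAReference",
  slots = c(
    sequences = "DNAStringSet",
    info = "data.frame",
    k = "integer",
    index = "environment",
    skipped = "integer"
  )
)

setValidity("HLAReference", function(object) {
  msgs <- character(0)
  info <- object@info
  need <- c("record", "name", "locus", "group", "protein", "length", "raw")
  if (!all(need %in% names(info)))
    msgs <- c(msgs, paste("info must have columns:", paste(need, collapse = ", ")))
  else {
    if (length(object@sequences) != nrow(info))
      msgs <- c(msgs, "sequences and info row count differ")
    if (anyDuplicated(info$record))
      msgs <- c(msgs, "record identifiers must be unique")
    if (!all(info$locus %in% hlaLoci()))
      msgs <- c(msgs, "info contains unsupported loci")
    if (length(object@sequences) &&
        !identical(Biostrings::width(object@sequences), as.integer(info$length)))
      msgs <- c(msgs, "info$length disagrees with sequence widths")
  }
  if (length(object@k) != 1L || is.na(object@k) || object@k < 0L)
    msgs <- c(msgs, "k must be a single non-negative integer")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn HLAReference Number of allele records.
#' @param x,object An \code{HLAReference}.
#' @export
setMethod("length", "HLAReference", function(x) length(x@sequences))

setMethod("show", "HLAReference", function(object) {
  info <- object@info
  cat("HLAReference with", nrow(info), "allele records |",
      length(unique(info$name)), "4-digit alleles |",
      length(unique(info$locus)), "loci\n")
  if (nrow(info)) {
    tab <- table(info$locus)
    cat("  per locus:", paste(names(tab), as.integer(tab), sep = ":",
                              collapse = " "), "\n")
  }
  if (object@k > 0L)
    cat("  k-mer index: k =", object@k, "(",
        length(ls(object@index, sorted = FALSE)), "distinct k-mers )\n")
  else cat("  k-mer index: not built\n")
  if (object@skipped > 0L)
    cat("  skipped records (unsupported locus):", object@skipped, "\n")
})

#' Accessors for HLAReference
#'
#' \code{alleleInfo} returns the per-record annotation table;
#' \code{alleleSequences} the [Biostrings::DNAStringSet];
#' \code{refK} the seed length of the built index (0 if none);
#' \code{skippedRecords} the count of records dropped for unsupported
#' loci at parse time.
#'
#' @param x An \code{HLAReference}.
#' @return See above.
#' @export
alleleInfo <- function(x) {
  stopifnot(is(x, "HLAReference"))
  x@info
}

#' @rdname alleleInfo
#' @export
alleleSequences <- function(x) {
  stopifnot(is(x, "HLAReference"))
  x@sequences
}

#' @rdname alleleInfo
#' @export
refK <- function(x) {
  stopifnot(is(x, "HLAReference"))
  x@k
}

#' @rdname alleleInfo
#' @export
skippedRecords <- function(x) {
  stopifnot(is(x, "HLAReference"))
  x@skipped
}

#' HLAExpressionProfile: per-sample expression values
#'
#' Per-gene RPKM and TPM for one sample over the union of the twelve
#' HLA loci and any externally counted genes, plus the derived
#' composite metrics.
#'
#' @slot sample Sample identifier.
#' @slot tissue Tissue label (may be \code{NA}).
#' @slot rpkm Named numeric: RPKM per gene/locus.
#' @slot tpm Named numeric: TPM per gene/locus (sums to 1e6 when any
#'   gene is expressed).
#' @slot metrics Named numeric with the composites:
#'   \code{classI_classical} (A+B+C), \code{classII_composite}
#'   (sum of within-locus alpha/beta chain minima), \code{hla_e},
#'   \code{hla_f}, \code{hla_g}, and — when PSMB5..PSMB10 counts were
#'   supplied — \code{proteasome_constitutive} and
#'   \code{proteasome_immuno}.
#' @slot totalMappedReads Integer: read pairs used as the RPKM
#'   denominator.
#'
#' @seealso [quantifySample()], [profileRpkm()]
#' @export
setClass("HLAExpressionProfile",
  slots = c(
    sample = "character",
    tissue = "character",
    rpkm = "numeric",
    tpm = "numeric",
    metrics = "numeric",
    totalMappedReads = "numeric"
  )
)

setValidity("HLAExpressionProfile", function(object) {
  msgs <- character(0)
  if (any(object@rpkm < 0) || any(object@tpm < 0))
    msgs <- c(msgs, "expression values must be non-negative")
  if (any(object@rpkm > 0)) {
    s <- sum(object@tpm)
    if (abs(s - 1e6) > 1e-6 * 1e6)
      msgs <- c(msgs, "TPM values must sum to 1e6")
  }
  m <- object@metrics
  r <- object@rpkm
  if (all(.CLASS_II %in% names(r)) && "classII_composite" %in% names(m)) {
    expect <- classIIComposite(r["DPA1"], r["DPB1"], r["DQA1"],
                               r["DQB1"], r["DRA"], r["DRB1"])
    if (abs(m[["classII_composite"]] - expect) > 1e-8 * max(1, expect))
      msgs <- c(msgs, "classII_composite inconsistent with chain RPKMs")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "HLAExpressionProfile", function(object) {
  cat("HLAExpressionProfile for sample", object@sample,
      if (!is.na(object@tissue)) paste0("(", object@tissue, ")"), "\n")
  cat("  genes quantified:", length(object@rpkm),
      "| total mapped pairs:", object@totalMappedReads, "\n")
  m <- object@metrics
  cat(sprintf("  classical class I: %.2f RPKM | class II composite: %.2f RPKM\n",
              m[["classI_classical"]], m[["classII_composite"]]))
  cat(sprintf("  HLA-E %.2f | HLA-F %.2f | HLA-G %.2f RPKM\n",
              m[["hla_e"]], m[["hla_f"]], m[["hla_g"]]))
})

#' Accessors for HLAExpressionProfile
#'
#' @param x An \code{HLAExpressionProfile}.
#' @return \code{profileRpkm}/\code{profileTpm}: named numeric per gene;
#'   \code{profileMetrics}: named numeric of composite metrics;
#'   \code{sampleId}, \code{tissueLabel}: length-1 character.
#' @export
profileRpkm <- function(x) {
  stopifnot(is(x, "HLAExpressionProfile"))
  x@rpkm
}

#' @rdname profileRpkm
#' @export
profileTpm <- function(x) {
  stopifnot(is(x, "HLAExpressionProfile"))
  x@tpm
}

#' @rdname profileRpkm
#' @export
profileMetrics <- function(x) {
  stopifnot(is(x, "HLAExpressionProfile"))
  x@metrics
}

#' @rdname profileRpkm
#' @export
sampleId <- function(x) {
  stopifnot(is(x, "HLAExpressionProfile"))
  x@sample
}

#' @rdname profileRpkm
#' @export
tissueLabel <- function(x) {
  stopifnot(is(x, "HLAExpressionProfile"))
  x@tissue
}

#' BodyMapTable: cohort-level body-map statistics
#'
#' Aggregation of many sample profiles into per-tissue medians,
#' positivity fractions at a threshold, outlier flags and cross-tissue
#' rank correlations.
#'
#' @slot medians data.frame: one row per tissue, columns \code{tissue},
#'   \code{n_samples}, then one column per metric holding the tissue
#'   median.
#' @slot positivity data.frame: \code{tissue}, \code{metric}, \code{k},
#'   \code{n}, \code{percent} at the configured threshold.
#' @slot outliers data.frame: \code{sample}, \code{tissue},
#'   \code{value} for samples exceeding the outlier threshold on the
#'   outlier metric.
#' @slot correlations data.frame: \code{metric_x}, \code{metric_y},
#'   \code{rho}, \code{n} (number of tissues; \code{rho} is \code{NA}
#'   when fewer than 3 tissues are available).
#' @slot params list of the thresholds used.
#'
#' @seealso [buildBodyMap()]
#' @export
setClass("BodyMapTable",
  slots = c(
    medians = "data.frame",
    positivity = "data.frame",
    outliers = "data.frame",
    correlations = "data.frame",
    params = "list"
  )
)

setValidity("BodyMapTable", function(object) {
  msgs <- character(0)
  p <- object@positivity
  if (nrow(p)) {
    if (any(p$k < 0 | p$k > p$n))
      msgs <- c(msgs, "positivity requires 0 <= k <= n")
    if (any(p$percent != .roundHalfUp(100 * p$k / p$n)))
      msgs <- c(msgs, "positivity percent must be round(100*k/n)")
  }
  cc <- object@correlations
  if (nrow(cc) && any(abs(cc$rho) > 1, na.rm = TRUE))
    msgs <- c(msgs, "|rho| must be <= 1")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "BodyMapTable", function(object) {
  cat("BodyMapTable:", nrow(object@medians), "tissues,",
      sum(object@medians$n_samples), "samples\n")
  mets <- setdiff(names(object@medians), c("tissue", "n_samples"))
  cat("  metrics:", paste(mets, collapse = ", "), "\n")
  if (nrow(object@outliers))
    cat("  outliers flagged:", nrow(object@outliers), "\n")
  if (nrow(object@correlations)) {
    ok <- !is.na(object@correlations$rho)
    cat("  cross-tissue correlations:", sum(ok), "computed\n")
  }
})

#' Accessors for BodyMapTable
#'
#' @param x A \code{BodyMapTable}.
#' @return The corresponding slot (data.frame).
#' @export
tissueMedians <- function(x) {
  stopifnot(is(x, "BodyMapTable"))
  x@medians
}

#' @rdname tissueMedians
#' @export
tissuePositivity <- function(x) {
  stopifnot(is(x, "BodyMapTable"))
  x@positivity
}

#' @rdname tissueMedians
#' @export
bodyMapOutliers <- function(x) {
  stopifnot(is(x, "BodyMapTable"))
  x@outliers
}

#' @rdname tissueMedians
#' @export
bodyMapCorrelations <- function(x) {
  stopifnot(is(x, "BodyMapTable"))
  x@correlations
}
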