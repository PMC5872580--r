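#' Positivity fraction at an expression threshold
#'
#' Counts values strictly greater than the threshold (per the usual
#' "greater than 1 RPKM" convention; set \code{strict = FALSE} for
#' >=). The percent is rounded half-up to the nearest integer.
#'
#' @param values Numeric vector, length >= 1.
#' @param threshold Non-negative threshold (default 1 RPKM).
#' @param strict Logical; strictly-greater comparison (default TRUE).
#' @return list with \code{k} (positives), \code{n} (total),
#'   \code{percent}.
#' @seealso [positivityPercent()] for the percent of a known k of n.
#' @export
#' @examples
#' positivityFraction(c(0.2, 1.5, 3, 1), threshold = 1) # k = 2 of 4, 50%
positivityFraction <- function(values, threshold = 1, strict = TRUE) {
  if (!length(values)) stop("positivity of an empty vector is undefined")
  if (threshold < 0) stop("'threshold' must be >= 0")
  k <- if (strict) sum(values > threshold) else sum(values >= threshold)
  list(k = as.integer(k), n = length(values),
       percent = positivityPercent(k, length(values)))
}

#' Integer percent of k positives out of n
#'
#' @param k,n Counts with \code{0 <= k <= n}, \code{n >= 1}.
#' @return Nearest integer (half-up) of \code{100 * k / n}.
#' @export
#' @examples
#' positivityPercent(96, 123) # 78
positivityPercent <- function(k, n) {
  if (any(n < 1) || any(k < 0) || any(k > n))
    stop("need 0 <= k <= n with n >= 1")
  as.integer(.roundHalfUp(100 * k / n))
}

#' Flag samples exceeding an expression threshold
#'
#' @param values Numeric vector of a metric, one per sample.
#' @param ids Sample identifiers, same length as \code{values}.
#' @param threshold Samples with value strictly above this are flagged.
#' @return Sorted character vector of flagged sample ids.
#' @export
flagOutliers <- function(values, ids, threshold) {
  if (length(values) != length(ids))
    stop("'values' and 'ids' lengths differ")
  if (threshold < 0) stop("'threshold' must be >= 0")
  sort(as.character(ids[values > threshold]))
}

#' Constitutive and immunoproteasome expression summaries
#'
#' The constitutive proteasome is approximated by the median
#' expression of its proteolytic subunits PSMB5, PSMB6, PSMB7; the
#' immunoproteasome by the median of the interferon-inducible subunits
#' PSMB8 (LMP7), PSMB9 (LMP2), PSMB10 (LMP10).
#'
#' @param psmb5,psmb6,psmb7,psmb8,psmb9,psmb10 Non-negative RPKM (or
#'   TPM) values.
#' @return Named numeric: \code{constitutive}, \code{immuno}.
#' @export
#' @examples
#' proteasomeSummary(10, 20, 30, 1, 2, 3) # constitutive 20, immuno 2
proteasomeSummary <- function(psmb5, psmb6, psmb7, psmb8, psmb9, psmb10) {
  vals <- c(psmb5, psmb6, psmb7, psmb8, psmb9, psmb10)
  .checkNonNegative(vals, "proteasome subunit expression")
  c(constitutive = median(c(psmb5, psmb6, psmb7)),
    immuno = median(c(psmb8, psmb9, psmb10)))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive average
#' ranks), as implemented by \code{stats::cor(method = "spearman")}.
#'
#' @param x,y Equal-length numeric vectors, length >= 3, neither
#'   constant.
#' @return list with \code{rho} and \code{n}.
#' @export
#' @examples
#' spearmanRho(1:3, c(10, 20, 30))$rho # 1
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("Spearman correlation undefined for a constant vector")
  list(rho = cor(x, y, method = "spearman"), n = length(x))
}

#' Build a body-map table from a cohort of sample profiles
#'
#' Aggregates a wide cohort matrix (one row per sample) into
#' per-tissue medians for every metric, positivity fractions at a
#' threshold, samples flagged on an outlier metric, and cross-tissue
#' Spearman correlations computed over the tissue medians (n = number
#' of tissues; correlations are reported as not computable, rho = NA,
#' when fewer than 3 tissues are present). Set
#' \code{correlationLevel = "sample"} to correlate per-sample values
#' instead (the within-individuals mode, e.g. PSMB9 vs TAP1).
#'
#' @param cohort data.frame from [cohortMatrix()] (or the same shape:
#'   \code{sample}, optional \code{tissue}, numeric metric columns).
#' @param manifest Optional data.frame \code{sample}, \code{tissue};
#'   overrides/supplies the tissue labels. Every manifest sample must
#'   be present in the cohort.
#' @param positivityThreshold RPKM threshold for positivity (default
#'   1).
#' @param positivityMetrics Metrics to compute positivity for (default
#'   all numeric metrics).
#' @param outlierMetric,outlierThreshold Metric and threshold for
#'   outlier flagging (default: none).
#' @param correlationPairs Optional 2-column character matrix or list
#'   of metric pairs; default: all pairs of the composite metrics
#'   present.
#' @param correlationLevel \code{"tissue"} (medians; default) or
#'   \code{"sample"}.
#' @return A [BodyMapTable].
#' @export
buildBodyMap <- function(cohort, manifest = NULL,
                         positivityThreshold = 1,
                         positivityMetrics = NULL,
                         outlierMetric = NULL, outlierThreshold = Inf,
                         correlationPairs = NULL,
                         correlationLevel = c("tissue", "sample")) {
  correlationLevel <- match.arg(correlationLevel)
  if (!"sample" %in% names(cohort)) stop("cohort must have a 'sample' column")
  if (!is.null(manifest)) {
    if (!all(c("sample", "tissue") %in% names(manifest)))
      stop("manifest must have columns 'sample' and 'tissue'")
    missing <- setdiff(manifest$sample, cohort$sample)
    if (length(missing))
      stop("manifest sample(s) not in cohort: ",
           paste(missing, collapse = ", "))
    cohort <- cohort[cohort$sample %in% manifest$sample, , drop = FALSE]
    cohort$tissue <- manifest$tissue[match(cohort$sample, manifest$sample)]
  }
  if (!"tissue" %in% names(cohort) || any(is.na(cohort$tissue)))
    stop("every sample needs a tissue label (supply a manifest)")

  metrics <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
  metrics <- setdiff(metrics, c("sample", "tissue"))
  if (!length(metrics)) stop("cohort has no numeric metric columns")
  tissues <- sort(unique(cohort$tissue))

  med <- data.frame(tissue = tissues,
                    n_samples = as.integer(table(cohort$tissue)[tissues]),
                    stringsAsFactors = FALSE)
  for (m in metrics)
    med[[m]] <- vapply(tissues, function(tt)
      median(cohort[[m]][cohort$tissue == tt], na.rm = TRUE), numeric(1))

  if (is.null(positivityMetrics)) positivityMetrics <- metrics
  pos <- do.call(rbind, lapply(tissues, function(tt) {
    do.call(rbind, lapply(positivityMetrics, function(m) {
      v <- cohort[[m]][cohort$tissue == tt]
      v <- v[!is.na(v)]
      if (!length(v)) return(NULL)
      p <- positivityFraction(v, positivityThreshold)
      data.frame(tissue = tt, metric = m, k = p$k, n = p$n,
                 percent = p$percent, stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(pos))
    pos <- data.frame(tissue = character(0), metric = character(0),
                      k = integer(0), n = integer(0), percent = integer(0))

  outliers <- data.frame(sample = character(0), tissue = character(0),
                         value = numeric(0), stringsAsFactors = FALSE)
  if (!is.null(outlierMetric)) {
    if (!outlierMetric %in% metrics)
      stop("unknown outlier metric: ", outlierMetric)
    ids <- flagOutliers(cohort[[outlierMetric]], cohort$sample,
                        outlierThreshold)
    j <- match(ids, cohort$sample)
    outliers <- data.frame(sample = ids, tissue = cohort$tissue[j],
                           value = cohort[[outlierMetric]][j],
                           stringsAsFactors = FALSE)
  }

  if (is.null(correlationPairs)) {
    base <- intersect(c("classI_classical", "classII_composite",
                        "proteasome_immuno", "proteasome_constitutive"),
                      metrics)
    correlationPairs <- if (length(base) >= 2) t(utils::combn(base, 2)) else
      matrix(character(0), ncol = 2)
  }
  if (is.list(correlationPairs) && !is.matrix(correlationPairs))
    correlationPairs <- do.call(rbind, correlationPairs)
  corRows <- lapply(seq_len(nrow(correlationPairs)), function(i) {
    mx <- correlationPairs[i, 1]; my <- correlationPairs[i, 2]
    if (!mx %in% metrics || !my %in% metrics)
      stop("unknown correlation metric: ", mx, " / ", my)
    if (correlationLevel == "tissue") {
      x <- med[[mx]]; y <- med[[my]]
    } else {
      x <- cohort[[mx]]; y <- cohort[[my]]
    }
    res <- tryCatch(spearmanRho(x, y), error = function(e)
      list(rho = NA_real_, n = sum(is.finite(x) & is.finite(y))))
    data.frame(metric_x = mx, metric_y = my, rho = res$rho, n = res$n,
               stringsAsFactors = FALSE)
  })
  correlations <- if (length(corRows)) do.call(rbind, corRows) else
    data.frame(metric_x = character(0), metric_y = character(0),
               rho = numeric(0), n = integer(0))

  new("BodyMapTable", medians = med, positivity = pos, outliers = outliers,
      correlations = correlations,
      params = list(positivityThreshold = positivityThreshold,
                    outlierMetric = outlierMetric,
                    outlierThreshold = outlierThreshold,
                    correlationLevel = correlationLevel))
}

#' Write body-map outputs as TSV files
#'
#' Emits \code{bodymap.tsv} (tissue-by-metric medians),
#' \code{positivity.tsv}, \code{correlations.tsv} and
#' \code{outliers.tsv} under \code{dir}.
#'
#' @param bm A [BodyMapTable].
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeBodyMap <- function(bm, dir) {
  stopifnot(is(bm, "BodyMapTable"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) write.table(d, file.path(dir, f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)
  w(bm@medians, "bodymap.tsv")
  w(bm@positivity, "positivity.tsv")
  w(bm@correlations, "correlations.tsv")
  w(bm@outliers, "outliers.tsv")
  invisible(dir)
}

#' Barplot of constitutive vs immunoproteasome tissue medians
#'
#' A plain two-series barplot across tissues, sorted by ascending
#' immunoproteasome expression.
#'
#' @param bm A [BodyMapTable] whose medians include
#'   \code{proteasome_constitutive} and \code{proteasome_immuno}.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the matrix plotted.
#' @export
plotProteasomeMap <- function(bm, ...) {
  stopifnot(is(bm, "BodyMapTable"))
  med <- bm@medians
  need <- c("proteasome_constitutive", "proteasome_immuno")
  if (!all(need %in% names(med)))
    stop("body map lacks proteasome summary metrics")
  ord <- order(med$proteasome_immuno)
  m <- t(as.matrix(med[ord, need]))
  colnames(m) <- med$tissue[ord]
  rownames(m) <- c("constitutive", "immuno")
  graphics::barplot(m, beside = TRUE, las = 2,
                    legend.text = rownames(m),
                    ylab = "median RPKM", ...)
  invisible(m)
}
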