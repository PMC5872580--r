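# Independent oracles. These deliberately avoid the package's own code
# paths: the aligner oracle is brute force over every allele, offset and
# orientation (Biostrings edit counting); the Spearman oracle builds
# average ranks from first principles and applies the Pearson formula
# explicitly.

bfMateMin <- function(s, subjChar) {
  L <- nchar(subjChar)
  l <- nchar(s)
  if (l > L) return(Inf)
  min(Biostrings::neditStartingAt(Biostrings::DNAString(s),
                                  Biostrings::DNAString(subjChar),
                                  starting.at = seq_len(L - l + 1L),
                                  with.indels = FALSE))
}

bfPairHits <- function(m1, m2, recChars, maxMM) {
  rc <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  m1r <- rc(m1)
  m2r <- rc(m2)
  mm <- vapply(recChars, function(s)
    min(bfMateMin(m1, s) + bfMateMin(m2r, s),
        bfMateMin(m1r, s) + bfMateMin(m2, s)), numeric(1))
  keep <- which(mm <= maxMM)
  if (!length(keep))
    return(data.frame(record = character(0), mismatches = numeric(0),
                      stringsAsFactors = FALSE))
  best <- min(mm[keep])
  keep <- keep[mm[keep] == best]
  data.frame(record = names(recChars)[keep], mismatches = unname(mm[keep]),
             stringsAsFactors = FALSE)
}

avgRankOracle <- function(v)
  vapply(v, function(x) sum(v < x) + (sum(v == x) + 1) / 2, numeric(1))

spearmanOracle <- function(x, y) {
  rx <- avgRankOracle(x)
  ry <- avgRankOracle(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}
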