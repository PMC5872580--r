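#' Parse an HLA allele nomenclature token
#'
#' Accepts the common header dialects (\code{"A*02:01:01:01"},
#' \code{"HLA-A*02:01"}, \code{"DQA1*05:05"}), strips an optional
#' \code{HLA-} prefix, and retains the first two nomenclature fields —
#' the 2-digit serological group and the 4-digit protein — so the
#' callable 4-digit name \code{locus*gg:pp} is reconstructible.
#'
#' @param token Character scalar, the allele name token.
#' @return A list with elements \code{locus}, \code{field1} (group),
#'   \code{field2} (protein), \code{name} (the 4-digit name) and
#'   \code{raw} (the original token).
#' @export
#' @examples
#' parseAlleleName("HLA-G*01:01:01:01")
#' parseAlleleName("DQA1*05:05")$name
parseAlleleName <- function(token) {
  if (!is.character(token) || length(token) != 1L || !nzchar(token))
    stop("allele name token must be a non-empty string")
  tok <- sub("^HLA-", "", token)
  if (!grepl("*", tok, fixed = TRUE))
    stop("malformed allele name (missing '*'): ", token)
  parts <- strsplit(tok, "*", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !nzchar(parts[1]) || !nzchar(parts[2]))
    stop("malformed allele name: ", token)
  fields <- strsplit(parts[2], ":", fixed = TRUE)[[1]]
  if (length(fields) < 2L || !nzchar(fields[1]) || !nzchar(fields[2]))
    stop("allele name needs at least two colon-separated fields: ", token)
  list(
    locus = parts[1],
    field1 = fields[1],
    field2 = fields[2],
    name = paste0(parts[1], "*", fields[1], ":", fields[2]),
    raw = token
  )
}

# Pull the allele token out of a full FASTA header line. IMGT-style
# headers ("HLA:HLA00005 A*01:01:01:01 3503 bp") carry the name as the
# first whitespace-separated word containing '*'.
.headerAlleleToken <- function(header) {
  words <- strsplit(trimws(header), "[[:space:]]+")[[1]]
  hit <- grep("*", words, fixed = TRUE)
  if (!length(hit)) return(NA_character_)
  words[hit[1]]
}

# Uppercase and resolve IUPAC ambiguity codes. strict: anything outside
# ACGTN is an error; lenient: converted to N.
.normalizeSequence <- function(seq, id, strict) {
  s <- toupper(seq)
  if (grepl("[^ACGTN]", s)) {
    if (strict)
      stop("record '", id, "' contains non-ACGTN characters (strict mode)")
    s <- gsub("[^ACGTN]", "N", s)
  }
  s
}

#' Read and validate an HLA allele reference FASTA
#'
#' Parses a multi-record allele FASTA whose headers carry an allele
#' nomenclature token, truncates names to 4-digit resolution for
#' grouping, and keeps duplicate 4-digit names with distinct sequences
#' as synonymous representatives of one callable allele. Records at
#' loci outside [hlaLoci()] are skipped (default) or rejected
#' (\code{strict = TRUE}); the skip count is retained in the returned
#' object. Sequences are uppercased; IUPAC codes other than N are
#' converted to N (or rejected when strict).
#'
#' @param file Path to a FASTA file (wrapped or unwrapped lines).
#' @param strict Logical; if \code{TRUE}, unsupported loci, unparseable
#'   headers and ambiguity codes raise errors instead of being skipped
#'   or normalized.
#' @return An [HLAReference] (without a k-mer index; see
#'   [buildKmerIndex()]).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">A*01:01", "ACGTACGTACGT", ">HLA-B*07:02", "ACGTTTTTACGT"), fa)
#' ref <- readAlleleReference(fa)
#' alleleInfo(ref)
readAlleleReference <- function(file, strict = FALSE) {
  if (!file.exists(file)) stop("FASTA file not found: ", file)
  lines <- readLines(file, warn = FALSE)
  nonEmpty <- which(nzchar(trimws(lines)))
  if (!length(nonEmpty)) stop("empty FASTA input: ", file)
  first <- nonEmpty[1]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("malformed FASTA: line ", first, " does not start a record ('>')")
  seqs <- readDNAStringSet(file, format = "fasta")
  if (!length(seqs)) stop("empty FASTA input: ", file)
  headers <- names(seqs)
  chars <- as.character(seqs)

  keepIdx <- integer(0)
  name <- locus <- group <- protein <- raw <- character(0)
  skipped <- 0L
  for (i in seq_along(headers)) {
    tok <- .headerAlleleToken(headers[i])
    if (is.na(tok)) {
      if (strict)
        stop("header without a parseable allele token: '", headers[i], "'")
      skipped <- skipped + 1L
      next
    }
    an <- tryCatch(parseAlleleName(tok), error = function(e) NULL)
    if (is.null(an)) {
      if (strict)
        stop("header without a parseable allele token: '", headers[i], "'")
      skipped <- skipped + 1L
      next
    }
    if (!an$locus %in% hlaLoci()) {
      if (strict)
        stop("unsupported locus '", an$locus, "' in record '", headers[i],
             "' (strict mode)")
      skipped <- skipped + 1L
      next
    }
    keepIdx <- c(keepIdx, i)
    name <- c(name, an$name)
    locus <- c(locus, an$locus)
    group <- c(group, an$field1)
    protein <- c(protein, an$field2)
    raw <- c(raw, tok)
  }
  if (!length(keepIdx))
    stop("no supported allele records in FASTA: ", file)

  chars <- vapply(seq_along(keepIdx), function(j)
    .normalizeSequence(chars[keepIdx[j]], name[j], strict), character(1))
  # synonymous 4-digit representatives get a #i suffix for a unique id
  rec <- name
  dup <- ave(seq_along(name), name, FUN = seq_along)
  multi <- name %in% name[duplicated(name)]
  rec[multi] <- paste0(name[multi], "#", dup[multi])

  sequences <- DNAStringSet(chars)
  names(sequences) <- rec
  info <- data.frame(
    record = rec, name = name, locus = locus, group = group,
    protein = protein, length = nchar(chars), raw = raw,
    stringsAsFactors = FALSE
  )
  new("HLAReference", sequences = sequences, info = info,
      k = 0L, index = new.env(parent = emptyenv()), skipped = skipped)
}

#' Build the k-mer seed index of an allele reference
#'
#' Indexes every k-mer occurring on the forward strand of every allele
#' (reads are later searched in both orientations, so only the forward
#' strand is needed). K-mers containing N are excluded. Coordinates are
#' 0-based.
#'
#' @param ref An [HLAReference].
#' @param k Integer seed length, at least 8. Default 16: long enough to
#'   be specific on kilobase-scale alleles, short enough that a typical
#'   short read still carries several clean seeds at realistic
#'   mismatch loads.
#' @return The reference with its index populated (\code{refK(ref)}
#'   returns \code{k}).
#' @export
buildKmerIndex <- function(ref, k = 16L) {
  stopifnot(is(ref, "HLAReference"))
  k <- as.integer(k)
  if (is.na(k) || k < 8L) stop("'k' must be an integer >= 8")
  lens <- ref@info$length
  short <- lens < k
  if (any(short))
    stop("allele(s) shorter than k=", k, ": ",
         paste(ref@info$record[short], collapse = ", "))
  env <- new.env(hash = TRUE, parent = emptyenv(),
                 size = max(64L, sum(lens - k + 1L)))
  chars <- as.character(ref@sequences)
  for (i in seq_along(chars)) {
    s <- chars[i]
    L <- nchar(s)
    starts <- seq_len(L - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    ok <- !grepl("N", kmers, fixed = TRUE)
    if (!any(ok)) next
    kmers <- kmers[ok]
    pos0 <- starts[ok] - 1L
    sp <- split(pos0, kmers)
    for (km in names(sp)) {
      m <- cbind(rec = rep.int(i, length(sp[[km]])), pos = sp[[km]])
      prev <- get0(km, envir = env, inherits = FALSE)
      assign(km, if (is.null(prev)) m else rbind(prev, m), envir = env)
    }
  }
  ref@k <- k
  ref@index <- env
  validObject(ref)
  ref
}

#' Look up a k-mer in the reference index
#'
#' Mainly for inspection and testing of index completeness.
#'
#' @param ref An indexed [HLAReference].
#' @param kmer Character scalar of length \code{refK(ref)}.
#' @return Integer matrix with columns \code{rec} (record index into
#'   \code{alleleInfo(ref)}) and \code{pos} (0-based offset), or a
#'   0-row matrix when the k-mer is absent.
#' @export
kmerHits <- function(ref, kmer) {
  stopifnot(is(ref, "HLAReference"))
  if (ref@k == 0L) stop("reference has no k-mer index; run buildKmerIndex()")
  m <- get0(kmer, envir = ref@index, inherits = FALSE)
  if (is.null(m))
    m <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("rec", "pos")))
  m
}

#' Write a normalized allele reference back to FASTA
#'
#' Headers are the original allele tokens so a write/re-parse round
#' trip preserves names, sequences and grouping.
#'
#' @param ref An [HLAReference].
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
writeAlleleReference <- function(ref, file) {
  stopifnot(is(ref, "HLAReference"))
  out <- ref@sequences
  names(out) <- ref@info$raw
  writeXStringSet(out, filepath = file, format = "fasta")
  invisible(file)
}

#' Tabular summary of an allele reference
#'
#' @param ref An [HLAReference].
#' @param file Optional path; when given the table is also written as
#'   TSV.
#' @return data.frame with columns \code{allele}, \code{locus},
#'   \code{group}, \code{length_bp}.
#' @export
alleleSummary <- function(ref, file = NULL) {
  stopifnot(is(ref, "HLAReference"))
  out <- data.frame(
    allele = ref@info$name,
    locus = ref@info$locus,
    group = ref@info$group,
    length_bp = ref@info$length,
    stringsAsFactors = FALSE
  )
  if (!is.null(file))
    write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
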