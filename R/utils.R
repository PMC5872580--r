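# Internal helpers shared across modules.

# Evaluate expr with a private RNG stream; the caller's .Random.seed is
# restored on exit so simulation seeds never leak into global state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Hamming distance between two equal-length strings; positions where either
# side is 'N' are treated as uninformative and never counted.
.mismatchCount <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  nraw <- as.raw(78L) # 'N'
  sum(ra != rb & ra != nraw & rb != nraw)
}

# Vectorised reverse complement on plain character vectors.
.revComp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(reverseComplement(DNAStringSet(x)))
}

# Round-half-up to nearest integer (base round() is round-half-even and
# would turn an exact .5 percent downward depending on parity).
.roundHalfUp <- function(x) floor(x + 0.5)

.checkNonNegative <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("'", what, "' must be finite and non-negative")
  invisible(x)
}
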