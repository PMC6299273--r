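# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero to a fixed number of decimals
#'
#' Report-time rounding used for printed percentages and skews; internal
#' values are kept at full precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up (away from zero on ties).
#' @export
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Length of a feature on a circular genome; end < start means the feature
## spans the origin.
.featLength <- function(start, end, genomeLength) {
  ifelse(end >= start, end - start + 1L, genomeLength - start + 1L + end)
}

## Map an arbitrary integer offset onto 1..L (circular coordinates).
.wrapPos <- function(pos, genomeLength) {
  ((pos - 1L) %% genomeLength) + 1L
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Split an in-frame nucleotide string into codons (character vector).
.splitCodons <- function(x) {
  n <- nchar(x)
  stopifnot(n %% 3 == 0)
  if (n == 0) return(character(0))
  substring(x, seq(1, n, by = 3), seq(3, n, by = 3))
}

## Evaluate expr with a reproducible RNG state, leaving the caller's
## RNG untouched. All generators funnel through this.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}
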