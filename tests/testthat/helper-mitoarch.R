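# Shared fixtures and independent oracles for the test suite.

## Small 6-gene layout (two strands, one abbreviated stop) for fast
## curation tests.
miniLayout <- function() {
  data.frame(
    name = c("pcgA", "trnX", "pcgB", "trnY", "pcgC", "trnZ"),
    kind = c("PCG", "tRNA", "PCG", "tRNA", "PCG", "tRNA"),
    strand = c("+", "+", "+", "+", "-", "+"),
    len = c(300L, 65L, 241L, 68L, 300L, 66L),
    gapAfter = c(11L, 5L, 0L, 78L, 12L, 9L),
    startCodon = c("ATG", NA, "ATG", NA, "ATA", NA),
    stringsAsFactors = FALSE)
}

## Brute-force common-interval oracle: for every window of the first
## order, test set-contiguity in the second by explicit set comparison.
bruteCommonIntervals <- function(ga, gb) {
  n <- length(ga)
  count <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s <- ga[i:j]
    hit <- FALSE
    for (k in seq_len(n - (j - i))) {
      if (setequal(gb[k:(k + j - i)], s)) { hit <- TRUE; break }
    }
    if (hit) count <- count + 1L
  }
  count
}

## Random signed permutation as a linear GeneOrder anchored at gene "1"
## (anchor forced positive and first so canonicalization is a no-op).
randomSignedOrder <- function(n, taxon = "x") {
  g <- c("1", sample(as.character(2:n)))
  s <- c(1L, sample(c(-1L, 1L), n - 1L, replace = TRUE))
  methods::new("GeneOrder", taxon = taxon, genes = g, signs = s,
               circular = FALSE, anchor = "1")
}

## Minimal BranchModelFit stub for LRT arithmetic tests.
fitStub <- function(logLik, nParams) {
  methods::new("BranchModelFit", variant = "one_ratio", logLik = logLik,
               kappa = 2, omega = 0.5, branchLengths = numeric(0),
               tree = NULL, foreground = NA_integer_,
               nParams = as.integer(nParams), converged = TRUE,
               freqs = numeric(0))
}
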