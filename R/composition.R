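#' Nucleotide composition of a sequence
#'
#' Base percentages are computed over counted A/C/G/T only; ambiguity codes
#' (N) are excluded so the four percentages always total 100. AT and GC
#' skews measure strand compositional asymmetry:
#' \deqn{AT\,skew = (A - T)/(A + T), \qquad GC\,skew = (G - C)/(G + C).}
#'
#' @param seq nucleotide string.
#' @return one-row data.frame with columns \code{A}, \code{C}, \code{G},
#'   \code{T} (percent), \code{AT}, \code{GC} (percent), \code{at_skew},
#'   \code{gc_skew}, at full precision (round at report time).
#' @examples
#' baseComposition("ACGT")          # 25% each
#' skewStat(36.1, 15.0)             # AT skew of the large rRNA, 0.413
#' @export
baseComposition <- function(seq) {
  seq <- toupper(seq)
  if (!nchar(seq)) stop("empty sequence")
  counts <- vapply(c("A", "C", "G", "T"), function(b)
    lengths(regmatches(seq, gregexpr(b, seq, fixed = TRUE))), numeric(1))
  tot <- sum(counts)
  if (tot == 0) stop("sequence contains no unambiguous A/C/G/T bases")
  pct <- 100 * counts / tot
  data.frame(A = pct[["A"]], C = pct[["C"]], G = pct[["G"]], T = pct[["T"]],
             AT = pct[["A"]] + pct[["T"]], GC = pct[["G"]] + pct[["C"]],
             at_skew = skewStat(pct[["A"]], pct[["T"]]),
             gc_skew = skewStat(pct[["G"]], pct[["C"]]))
}

#' @describeIn baseComposition the skew statistic \eqn{(x-y)/(x+y)};
#'   \code{NA} when \eqn{x+y=0}.
#' @param x,y percentages (or counts) of the two bases.
#' @export
skewStat <- function(x, y) {
  ifelse(x + y == 0, NA_real_, (x - y) / (x + y))
}

#' Per-region composition table of a mitogenome
#'
#' One composition row per requested region: the whole genome plus named
#' features (by default every PCG, rRNA and the control region). Regions
#' are computed on the plus strand as the printed coordinates define them;
#' set \code{codingStrand = TRUE} to compute minus-strand genes on their
#' transcribed strand instead.
#'
#' @param record a \linkS4class{GenomeRecord}.
#' @param regions character vector of feature names, or \code{NULL} for the
#'   default selection; the whole genome row is always first.
#' @param codingStrand compute each gene on its coding strand
#'   (default \code{FALSE}: plus strand as annotated).
#' @return data.frame with a \code{region} column followed by the
#'   \code{\link{baseComposition}} columns.
#' @export
compositionTable <- function(record, regions = NULL, codingStrand = FALSE) {
  f <- record@features
  if (is.null(regions))
    regions <- f$name[f$kind %in% c("PCG", "rRNA", "control_region")]
  unknown <- setdiff(regions, f$name)
  if (length(unknown))
    stop("unknown region name(s): ", paste(unknown, collapse = ", "))
  rows <- list(cbind(region = "whole_genome",
                     baseComposition(genomeSequence(record))))
  for (nm in regions) {
    ft <- f[f$name == nm, , drop = FALSE][1, ]
    if (!codingStrand) ft$strand <- "+"
    rows[[length(rows) + 1L]] <-
      cbind(region = nm, baseComposition(extractGeneSequence(record, ft)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
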