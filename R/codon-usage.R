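#' Codon counts over a set of coding sequences
#'
#' Counts every sense codon across a set of in-frame coding sequences
#' (typically the concatenated protein-coding genes of one mitogenome).
#' Terminal stop codons -- full, or abbreviated ones completed by
#' polyadenylation -- are excluded; an internal in-frame stop is an error
#' naming the offending sequence.
#'
#' @slot species species/record identifier.
#' @slot counts named integer vector over the sense codons of the code.
#' @slot families codon-to-family map (see \code{\link{codonFamilies}}).
#' @export
setClass("CodonCountTable",
  representation(species = "character", counts = "numeric",
                 families = "character"),
  validity = function(object) {
    msg <- character(0)
    if (!identical(sort(names(object@counts)), sort(names(object@families))))
      msg <- c(msg, "counts and family map must cover the same sense codons")
    if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "CodonCountTable", function(object) {
  cat("CodonCountTable", object@species, "-", sum(object@counts),
      "codons over", length(unique(object@families)), "families\n")
})

#' @param cdsSet named list (or character vector) of in-frame CDS strings,
#'   or a \code{DNAStringSet}.
#' @param code a \linkS4class{GeneticCode}, default table 5.
#' @param species species label for the table.
#' @return a \code{CodonCountTable}.
#' @examples
#' ct <- codonCounts(list(toy = "ATGGGATTTTAA"))
#' sum(codonCountsVector(ct))  # 3 sense codons; the stop is excluded
#' @rdname codonCounts
#' @export
codonCounts <- function(cdsSet, code = geneticCode(5L), species = "") {
  if (methods::is(cdsSet, "DNAStringSet")) {
    nm <- names(cdsSet)
    cdsSet <- stats::setNames(as.character(cdsSet), nm)
  }
  if (!length(cdsSet)) stop("empty CDS set")
  sense <- senseCodons(code)
  counts <- stats::setNames(numeric(length(sense)), sense)
  nms <- names(cdsSet) %||% as.character(seq_along(cdsSet))
  for (i in seq_along(cdsSet)) {
    cds <- completeAbbreviatedStop(toupper(cdsSet[[i]]))
    codons <- .splitCodons(cds)
    aa <- .translateCodon(codons, code)
    internal <- which(aa == "*")
    if (length(internal) && any(internal < length(codons)))
      stop("internal stop codon in CDS '", nms[i], "'")
    if (length(aa) && aa[length(aa)] == "*") codons <- codons[-length(codons)]
    tab <- table(codons)
    hit <- intersect(names(tab), sense)
    counts[hit] <- counts[hit] + as.numeric(tab[hit])
  }
  new("CodonCountTable", species = species, counts = counts,
      families = codonFamilies(code))
}

#' @describeIn codonCounts codon counts of a mitogenome's PCGs (coding
#'   strand, terminal stops excluded).
#' @param record a \linkS4class{GenomeRecord} with curated PCG annotations.
#' @export
pcgCodonCounts <- function(record, code = geneticCode(5L)) {
  f <- record@features[record@features$kind == "PCG", , drop = FALSE]
  cds <- lapply(seq_len(nrow(f)), function(i)
    extractGeneSequence(record, f[i, , drop = FALSE]))
  names(cds) <- f$name
  codonCounts(cds, code = code, species = recordId(record))
}

#' @describeIn codonCounts raw counts vector accessor.
#' @param x a \code{CodonCountTable}.
#' @export
codonCountsVector <- function(x) x@counts

#' Relative synonymous codon usage
#'
#' RSCU is a codon's count divided by the mean count within its synonymous
#' family: \eqn{RSCU(c) = k\,n_c / \sum_{c'} n_{c'}} with \eqn{k} the family
#' degeneracy, so values sum to \eqn{k} within each used family and 1 means
#' no bias. Families with zero total usage get \code{NA}.
#'
#' @param counts a \code{CodonCountTable}.
#' @return data.frame with columns \code{codon}, \code{family},
#'   \code{count}, \code{rscu}, ordered by family.
#' @export
rscu <- function(counts) {
  fam <- counts@families
  n <- counts@counts[names(fam)]
  famTotals <- tapply(n, fam, sum)
  k <- table(fam)
  out <- data.frame(codon = names(fam), family = unname(fam),
                    count = unname(n),
                    rscu = unname(ifelse(famTotals[fam] > 0,
                                         as.numeric(k[fam]) * n / famTotals[fam],
                                         NA_real_)),
                    stringsAsFactors = FALSE)
  out[order(out$family, out$codon), ]
}

#' Per-family chi-square comparison of codon usage between two species
#'
#' For one codon family, the observed counts are the focal species' codon
#' counts; the expected count of a codon is the focal family total times
#' the pooled proportion of that codon across both species (i.e. the count
#' expected if the codon were equally used in the two species). The
#' statistic is \eqn{\sum_i (o_i - e_i)^2 / e_i} with \eqn{k-1} degrees of
#' freedom. Families where any expected count is below 5 are flagged, not
#' excluded; a family unused in both species is untestable.
#'
#' @param focal,other \code{CodonCountTable}s sharing a family map.
#' @param family family label, or \code{NULL} to test every family.
#' @return data.frame with columns \code{family}, \code{chi2}, \code{df},
#'   \code{p}, \code{low_expected} (any \eqn{e_i < 5}), \code{testable}.
#' @export
familyChisq <- function(focal, other, family = NULL) {
  if (!identical(focal@families, other@families))
    stop("the two tables must share the same family map")
  fams <- if (is.null(family)) unique(unname(focal@families)) else family
  rows <- lapply(fams, function(fm) {
    codons <- names(focal@families)[focal@families == fm]
    if (!length(codons)) stop("unknown codon family: ", fm)
    o <- focal@counts[codons]
    pooled <- o + other@counts[codons]
    if (sum(pooled) == 0)
      return(data.frame(family = fm, chi2 = NA_real_, df = length(codons) - 1L,
                        p = NA_real_, low_expected = NA, testable = FALSE))
    e <- sum(o) * pooled / sum(pooled)
    use <- e > 0
    chi2 <- sum((o[use] - e[use])^2 / e[use])
    df <- length(codons) - 1L
    data.frame(family = fm, chi2 = chi2, df = df,
               p = stats::pchisq(chi2, df, lower.tail = FALSE),
               low_expected = any(e < 5), testable = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sequential Bonferroni (Holm step-down) decisions
#'
#' Sorts p-values ascending and rejects \eqn{p_{(i)}} while
#' \eqn{p_{(i)} \le \alpha/(m - i + 1)}, stopping at the first failure;
#' decisions are mapped back to the input order. Implemented through
#' \code{stats::p.adjust(method = "holm")}, which is the same step-down
#' procedure.
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed: never rejected).
#' @param alpha family-wise error level, default 0.05.
#' @return logical vector of reject decisions, same order as \code{p}.
#' @examples
#' sequentialBonferroni(c(0.001, 0.02, 0.04))  # all TRUE
#' sequentialBonferroni(c(0.03, 0.04))         # both FALSE
#' @export
sequentialBonferroni <- function(p, alpha = 0.05) {
  if (!length(p)) return(logical(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "holm")
  out <- !is.na(adj) & adj <= alpha
  out
}

#' Compare codon usage between two species across all families
#'
#' Runs \code{\link{familyChisq}} on every codon family and applies the
#' sequential Bonferroni correction over the testable families. All
#' families present in the family map are attempted and the testable count
#' is reported alongside, so an untestable family is never silently
#' dropped.
#'
#' @inheritParams familyChisq
#' @param alpha family-wise level for the Holm correction.
#' @return data.frame as \code{\link{familyChisq}} plus columns
#'   \code{reject_raw} and \code{holm_reject}; the number of testable
#'   families is attached as attribute \code{"n_testable"}.
#' @export
codonUsageTest <- function(focal, other, alpha = 0.05) {
  res <- familyChisq(focal, other)
  res$reject_raw <- !is.na(res$p) & res$p <= alpha
  res$holm_reject <- FALSE
  idx <- which(res$testable)
  res$holm_reject[idx] <- sequentialBonferroni(res$p[idx], alpha = alpha)
  attr(res, "n_testable") <- length(idx)
  res
}

#' Start- and stop-codon usage over the protein-coding genes
#'
#' Tallies annotated start codons and full stop codons (abbreviated stops
#' are tallied under their annotated abbreviation) over a record's PCGs.
#' Percentages are reported to the nearest integer.
#'
#' @param record a \linkS4class{GenomeRecord} with curated PCG annotations.
#' @return list with data.frames \code{starts} and \code{stops} (columns
#'   \code{codon}, \code{n}, \code{percent}) and \code{n_missing_stop}.
#' @export
startStopUsage <- function(record) {
  f <- record@features[record@features$kind == "PCG", , drop = FALSE]
  tally <- function(x) {
    x <- x[!is.na(x)]
    tab <- sort(table(x), decreasing = TRUE)
    data.frame(codon = names(tab), n = as.integer(tab),
               percent = as.integer(roundHalfUp(100 * as.integer(tab) / sum(tab))),
               stringsAsFactors = FALSE)
  }
  list(starts = tally(f$start_codon), stops = tally(f$stop_codon),
       n_missing_stop = sum(is.na(f$stop_codon)))
}
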