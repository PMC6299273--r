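#' Annotated circular mitogenome
#'
#' A \code{GenomeRecord} couples a nucleotide sequence (a
#' \linkS4class{DNAString}) with an ordered table of gene features, the data
#' model every analysis stage consumes. Coordinates are 1-based inclusive
#' throughout, the IRanges/GenBank convention; a feature whose \code{end} is
#' smaller than its \code{start} spans the origin of a circular genome.
#'
#' The feature table has columns \code{name}, \code{kind} (one of
#' \code{PCG}, \code{tRNA}, \code{rRNA}, \code{control_region}),
#' \code{strand} (\code{"+"}/\code{"-"}), \code{start}, \code{end},
#' \code{start_codon}, \code{stop_codon} (full \code{TAA}/\code{TAG} or
#' abbreviated \code{TA-}/\code{T--}; \code{NA} for non-coding features) and
#' \code{quality} (optional annotation confidence score).
#'
#' @slot id accession-like identifier.
#' @slot sequence genome sequence as a \code{DNAString}.
#' @slot circular is the genome circular?
#' @slot features data.frame of gene features, sorted by start.
#' @export
setClass("GenomeRecord",
  representation(id = "character", sequence = "ANY",
                 circular = "logical", features = "data.frame"),
  validity = function(object) {
    msg <- character(0)
    f <- object@features
    L <- length(object@sequence)
    need <- c("name", "kind", "strand", "start", "end",
              "start_codon", "stop_codon", "quality")
    if (L < 1) msg <- c(msg, "sequence length must be positive")
    if (!all(need %in% names(f)))
      msg <- c(msg, paste("feature table must have columns:",
                          paste(need, collapse = ", ")))
    else if (nrow(f)) {
      if (any(f$start < 1 | f$start > L | f$end < 1 | f$end > L))
        msg <- c(msg, "feature coordinates outside 1..genome length")
      if (is.unsorted(f$start))
        msg <- c(msg, "features must be sorted ascending by start")
      if (anyDuplicated(f[, c("name", "start")]))
        msg <- c(msg, "duplicate (name, start) feature pair")
      if (!all(f$strand %in% c("+", "-")))
        msg <- c(msg, "strand must be '+' or '-'")
      if (!all(f$kind %in% c("PCG", "tRNA", "rRNA", "control_region")))
        msg <- c(msg, "unknown feature kind")
      if (any(f$end < f$start & !object@circular))
        msg <- c(msg, "origin-spanning feature on a non-circular genome")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a GenomeRecord
#'
#' @param id record identifier.
#' @param sequence genome sequence (character or \code{DNAString}).
#' @param features feature data.frame (see \linkS4class{GenomeRecord});
#'   missing optional columns are filled with \code{NA}.
#' @param circular logical, default \code{TRUE}.
#' @return a validated \code{GenomeRecord}, features sorted by start.
#' @export
genomeRecord <- function(id, sequence, features, circular = TRUE) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  for (col in c("start_codon", "stop_codon"))
    if (is.null(features[[col]])) features[[col]] <- NA_character_
  if (is.null(features$quality)) features$quality <- NA_real_
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features <- features[order(features$start), , drop = FALSE]
  rownames(features) <- NULL
  new("GenomeRecord", id = id, sequence = sequence,
      circular = circular, features = features)
}

#' @describeIn genomeRecord feature table accessor.
#' @param record a \code{GenomeRecord}.
#' @export
gbFeatures <- function(record) record@features

#' @describeIn genomeRecord genome sequence as a character string.
#' @export
genomeSequence <- function(record) as.character(record@sequence)

#' @describeIn genomeRecord genome length in nucleotides.
#' @export
genomeLength <- function(record) length(record@sequence)

#' @describeIn genomeRecord record identifier.
#' @export
recordId <- function(record) record@id

#' @describeIn genomeRecord is the genome circular?
#' @export
isCircularGenome <- function(record) record@circular

#' @describeIn genomeRecord replace the feature table (re-sorted, re-validated).
#' @param value replacement feature data.frame.
#' @export
`gbFeatures<-` <- function(record, value) {
  value <- value[order(value$start), , drop = FALSE]
  rownames(value) <- NULL
  record@features <- value
  methods::validObject(record)
  record
}

setMethod("show", "GenomeRecord", function(object) {
  f <- object@features
  cat("GenomeRecord", object@id, "\n")
  cat(" ", length(object@sequence), "bp,",
      if (object@circular) "circular" else "linear", "\n")
  cat(" ", nrow(f), "features:",
      paste(sprintf("%d %s", table(f$kind)[unique(f$kind)], unique(f$kind)),
            collapse = ", "), "\n")
})

#' Signed circular gene order
#'
#' Gene orders are signed permutations of gene symbols: the sign records the
#' coding strand. Two orders can be compared only over the same symbol set.
#'
#' @slot taxon taxon identifier.
#' @slot genes character vector of gene symbols, unique.
#' @slot signs integer vector of +1/-1, parallel to \code{genes}.
#' @slot circular is the order circular?
#' @slot anchor gene used to canonicalize rotations/reflections.
#' @export
setClass("GeneOrder",
  representation(taxon = "character", genes = "character",
                 signs = "integer", circular = "logical", anchor = "character"),
  validity = function(object) {
    msg <- character(0)
    if (anyDuplicated(object@genes)) msg <- c(msg, "gene symbols must be unique")
    if (length(object@genes) != length(object@signs))
      msg <- c(msg, "genes and signs differ in length")
    if (!all(object@signs %in% c(-1L, 1L)))
      msg <- c(msg, "signs must be +1 or -1")
    if (length(msg)) msg else TRUE
  })

#' Construct a gene order
#'
#' @param symbols character vector of signed symbols (\code{"+cox1"},
#'   \code{"-trnM"}; a bare symbol is taken as plus strand).
#' @param taxon taxon id.
#' @param circular logical, default \code{TRUE}.
#' @param anchor canonicalization anchor gene, default \code{"cox1"}.
#' @return a \code{GeneOrder}.
#' @examples
#' geneOrder(c("+cox1", "-trnM", "+cox2"), taxon = "toy")
#' @export
geneOrder <- function(symbols, taxon = "", circular = TRUE, anchor = "cox1") {
  signs <- ifelse(startsWith(symbols, "-"), -1L, 1L)
  genes <- sub("^[+-]", "", symbols)
  new("GeneOrder", taxon = taxon, genes = genes, signs = signs,
      circular = circular, anchor = anchor)
}

#' @describeIn geneOrder signed symbols of an order.
#' @param order a \code{GeneOrder}.
#' @export
orderSymbols <- function(order) {
  paste0(ifelse(order@signs < 0, "-", "+"), order@genes)
}

setMethod("show", "GeneOrder", function(object) {
  cat("GeneOrder", object@taxon,
      if (object@circular) "(circular)" else "(linear)", "\n ",
      paste(orderSymbols(object), collapse = " "), "\n")
})

#' Branch-model fit of a codon substitution model
#'
#' Result container for \code{\link{fitBranchModel}}: the maximized
#' log-likelihood, the transition/transversion ratio kappa, per-branch
#' omega (dN/dS) estimates, branch lengths in expected substitutions per
#' codon, and bookkeeping needed for likelihood-ratio tests.
#'
#' @slot variant one of \code{"one_ratio"}, \code{"two_ratios"},
#'   \code{"free_ratios"}.
#' @slot logLik maximized log-likelihood.
#' @slot kappa transition/transversion rate ratio estimate.
#' @slot omega per-branch omega estimates (named by edge).
#' @slot branchLengths per-edge branch lengths.
#' @slot tree the (unrooted) phylo object the fit used.
#' @slot foreground foreground edge index (two-ratios only), otherwise NA.
#' @slot nParams number of free parameters.
#' @slot converged optimizer convergence flag.
#' @slot freqs equilibrium codon frequencies used.
#' @export
setClass("BranchModelFit",
  representation(variant = "character", logLik = "numeric", kappa = "numeric",
                 omega = "numeric", branchLengths = "numeric", tree = "ANY",
                 foreground = "integer", nParams = "integer",
                 converged = "logical", freqs = "numeric"),
  validity = function(object) {
    if (!is.finite(object@logLik)) "log-likelihood must be finite" else TRUE
  })

setMethod("show", "BranchModelFit", function(object) {
  cat("BranchModelFit (", object@variant, ")\n", sep = "")
  cat("  logLik:", format(object@logLik, digits = 8),
      " kappa:", signif(object@kappa, 4),
      " np:", object@nParams,
      if (!object@converged) " [not converged]" else "", "\n")
  om <- unique(signif(object@omega, 4))
  if (length(om) <= 2) cat("  omega:", paste(om, collapse = ", "), "\n")
  else cat("  omega: per-branch,", length(object@omega), "values\n")
})

#' @describeIn fitBranchModel log-likelihood of a fit (with \code{df}
#'   attribute set to the number of free parameters).
#' @param object a \code{BranchModelFit}.
#' @param ... ignored.
#' @export
setMethod("logLik", "BranchModelFit", function(object, ...) {
  structure(object@logLik, df = object@nParams, class = "logLik")
})

#' @describeIn fitBranchModel per-branch omega estimates.
#' @param fit a \code{BranchModelFit}.
#' @export
omegaEstimates <- function(fit) fit@omega
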