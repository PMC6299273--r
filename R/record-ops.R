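#' Extract a gene's nucleotide sequence from a genome record
#'
#' Plus-strand features yield the substring \code{start..end}; minus-strand
#' features yield its reverse complement, i.e. the coding-strand sequence.
#' Features whose end coordinate is smaller than their start span the origin
#' of a circular genome and are assembled from the tail and head of the
#' sequence.
#'
#' @param record a \linkS4class{GenomeRecord}.
#' @param feature a gene name present in the record, a row index, or a
#'   one-row feature data.frame.
#' @return nucleotide string (character scalar).
#' @examples
#' rec <- genomeRecord("toy", "ACGTACGTAC",
#'   data.frame(name = "g", kind = "tRNA", strand = "+", start = 9, end = 2))
#' extractGeneSequence(rec, "g")  # "ACAC": spans the origin
#' @export
extractGeneSequence <- function(record, feature) {
  f <- .resolveFeature(record, feature)
  s <- genomeSequence(record)
  L <- nchar(s)
  if (f$end >= f$start) {
    out <- substr(s, f$start, f$end)
  } else {
    if (!record@circular)
      stop("origin-spanning feature '", f$name, "' on a non-circular genome")
    out <- paste0(substr(s, f$start, L), substr(s, 1, f$end))
  }
  if (f$strand == "-") out <- .revcomp(out)
  out
}

.resolveFeature <- function(record, feature) {
  f <- record@features
  if (is.data.frame(feature)) {
    stopifnot(nrow(feature) == 1)
    return(feature)
  }
  if (is.numeric(feature)) return(f[feature, , drop = FALSE])
  hit <- which(f$name == feature)
  if (!length(hit)) stop("no feature named '", feature, "' in record ",
                         record@id)
  f[hit[1], , drop = FALSE]
}

#' Complete an abbreviated stop codon
#'
#' Mitochondrial transcripts cut at tRNA boundaries can end in an incomplete
#' stop codon (TA- or T--) that is completed to TAA by polyadenylation of
#' the mRNA. This helper materializes that completion: a sequence whose
#' length is not a multiple of three and whose trailing partial codon is
#' \code{T} or \code{TA} is padded with \code{A}s to a full \code{TAA}.
#'
#' @param cds in-frame coding sequence, possibly ending in a partial codon.
#' @return coding sequence with length a multiple of three.
#' @export
completeAbbreviatedStop <- function(cds) {
  r <- nchar(cds) %% 3
  if (r == 0) return(cds)
  tail <- substr(cds, nchar(cds) - r + 1, nchar(cds))
  if ((r == 1 && tail == "T") || (r == 2 && tail == "TA"))
    return(paste0(cds, strrep("A", 3 - r)))
  stop("sequence length not a multiple of 3 and trailing '", tail,
       "' is not an abbreviated stop (T/TA)")
}

#' Translate an in-frame coding sequence
#'
#' Translates codon by codon under the given genetic code (default NCBI
#' table 5, invertebrate mitochondrial). An abbreviated terminal stop is
#' completed first; the terminal stop residue is dropped. Codons containing
#' ambiguity codes translate to \code{X}. An internal in-frame stop is a
#' validation error naming the offending codon offset.
#'
#' @param cds coding sequence (character scalar), length a multiple of 3
#'   after abbreviated-stop completion.
#' @param code a \linkS4class{GeneticCode}; default table 5.
#' @return amino-acid string.
#' @examples
#' translateCDS("ATAAGATGA")  # "MSW" under the invertebrate mito code
#' translateCDS("ATGTAA")     # "M"
#' @export
translateCDS <- function(cds, code = geneticCode(5L)) {
  cds <- completeAbbreviatedStop(toupper(cds))
  codons <- .splitCodons(cds)
  aa <- .translateCodon(codons, code)
  stops <- which(aa == "*")
  if (length(stops) && any(stops < length(codons)))
    stop("internal in-frame stop codon at codon offset ",
         stops[stops < length(codons)][1])
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

#' Read a FASTA file as a named sequence set
#'
#' Thin wrapper over \code{Biostrings::readDNAStringSet} that enforces
#' unique sequence names.
#'
#' @param path FASTA file.
#' @return a \code{DNAStringSet}.
#' @export
readFastaFile <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1)
  names(x) <- nm
  if (anyDuplicated(nm))
    stop("duplicate FASTA headers: ", paste(unique(nm[duplicated(nm)]),
                                            collapse = ", "))
  x
}

#' Read a newick tree with branch lengths
#'
#' Wrapper over \code{ape::read.tree} enforcing unique leaf names and
#' non-negative branch lengths; unnamed internal nodes are auto-labelled.
#'
#' @param path newick file.
#' @return an \code{ape} \code{phylo} object.
#' @export
readTreeFile <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick file: ", path)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf names: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch length in tree")
  if (is.null(tr$node.label) || any(!nzchar(tr$node.label)))
    tr <- ape::makeNodeLabel(tr, method = "number", prefix = "n")
  tr
}
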