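#' Genetic code tables and synonymous codon families
#'
#' \code{GeneticCode} wraps an NCBI translation table (default table 5, the
#' invertebrate mitochondrial code, under which AGA/AGG encode Ser, ATA
#' encodes Met and TGA encodes Trp, leaving TAA/TAG as the only stops).
#' Synonymous codon families group the sense codons into two- and four-fold
#' degenerate classes; under table 5 there are 22 families covering all 62
#' sense codons, with leucine and serine each split into two families
#' following mitochondrial tRNA naming (Leu1 = CTN, Leu2 = TTR, Ser1 = AGN,
#' Ser2 = TCN).
#'
#' @name GeneticCode
NULL

#' @slot tableId NCBI translation table number.
#' @slot codons named character vector of length 64 mapping codon to
#'   one-letter amino acid (\code{"*"} for stop).
#' @slot startCodons codons accepted as translation initiators.
#' @slot stopCodons stop codons of the table.
#' @rdname GeneticCode
#' @export
setClass("GeneticCode",
  representation(tableId = "integer", codons = "character",
                 startCodons = "character", stopCodons = "character"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@codons) != 64) msg <- c(msg, "exactly 64 codons must be mapped")
    if (!all(object@stopCodons %in% names(object@codons)[object@codons == "*"]))
      msg <- c(msg, "stop set inconsistent with codon map")
    if (length(msg)) msg else TRUE
  })

#' Construct a genetic code
#'
#' @param tableId NCBI translation table number; default 5 (invertebrate
#'   mitochondrial).
#' @return a \code{GeneticCode} object.
#' @examples
#' code <- geneticCode(5)
#' stopCodons(code)
#' @export
geneticCode <- function(tableId = 5L) {
  tab <- Biostrings::getGeneticCode(as.character(tableId))
  alt <- attr(tab, "alt_init_codons")
  new("GeneticCode",
      tableId = as.integer(tableId),
      codons = stats::setNames(as.character(tab), names(tab)),
      startCodons = unique(c("ATG", alt)),
      stopCodons = names(tab)[tab == "*"])
}

#' @param code a \code{GeneticCode}.
#' @rdname geneticCode
#' @export
stopCodons <- function(code) code@stopCodons

#' @rdname geneticCode
#' @export
startCodons <- function(code) code@startCodons

#' @rdname geneticCode
#' @export
senseCodons <- function(code) names(code@codons)[code@codons != "*"]

#' Translate one codon (internal); returns "X" for ambiguous codons.
#' @noRd
.translateCodon <- function(codons, code) {
  aa <- unname(code@codons[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' Synonymous codon families
#'
#' Partitions the sense codons of a genetic code into degenerate families.
#' Codons are grouped by encoded amino acid and, within an amino acid, by the
#' first two codon positions, which splits six- and eight-fold amino acids
#' (Leu, Ser under table 5) into the conventional two families each.
#'
#' @param code a \code{GeneticCode}; default table 5.
#' @return named character vector mapping each sense codon to its family
#'   label. Under table 5 there are 22 families (9 four-fold, 13 two-fold).
#' @examples
#' fam <- codonFamilies()
#' table(table(fam))  # family sizes
#' @export
codonFamilies <- function(code = geneticCode(5L)) {
  sense <- senseCodons(code)
  aa <- .translateCodon(sense, code)
  aa3 <- c(F = "Phe", L = "Leu", I = "Ile", M = "Met", V = "Val", S = "Ser",
           P = "Pro", T = "Thr", A = "Ala", Y = "Tyr", H = "His", Q = "Gln",
           N = "Asn", K = "Lys", D = "Asp", E = "Glu", C = "Cys", W = "Trp",
           R = "Arg", G = "Gly")
  fam <- character(length(sense))
  names(fam) <- sense
  for (a in unique(aa)) {
    idx <- which(aa == a)
    boxes <- substr(sense[idx], 1, 2)
    ub <- unique(boxes)
    if (length(ub) == 1L) {
      fam[idx] <- aa3[[a]]
    } else {
      ## split families; number them so that the family decoded by the
      ## tRNA with the anticodon matching the box keeps the mito convention:
      ## Leu1 = CTN, Leu2 = TTR, Ser1 = AGN, Ser2 = TCN.
      ord <- if (a == "L") c("CT", "TT") else if (a == "S") c("AG", "TC") else sort(ub)
      for (k in seq_along(ord)) {
        fam[idx[boxes == ord[k]]] <- paste0(aa3[[a]], k)
      }
    }
  }
  fam
}
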