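#' Published annotation of the Melarhaphe neritoides mitogenome
#'
#' The feature table (gene, kind, strand, 1-based coordinates, start and
#' stop codons) of the 15,676-bp \emph{Melarhaphe neritoides} mitogenome
#' annotation, as shipped in \code{inst/extdata}. Only the printed
#' coordinates and codons are included -- not the nucleotide sequence --
#' so the table supports coordinate-based analyses: gene geometry
#' (spacers/overlaps), start/stop-codon usage and feature accounting.
#'
#' @return feature data.frame suitable for \code{\link{genomeRecord}}.
#' @examples
#' f <- mneritoidesFeatures()
#' table(f$kind)  # 13 PCG + 22 tRNA + 2 rRNA + control region
#' @export
mneritoidesFeatures <- function() {
  path <- system.file("extdata", "mneritoides_features.tsv",
                      package = "mitoarch", mustWork = TRUE)
  f <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = "NA")
  names(f)[names(f) == "gene"] <- "name"
  f
}

#' @describeIn mneritoidesFeatures the annotation wrapped in a
#'   \linkS4class{GenomeRecord} around a synthetic placeholder sequence
#'   (poly-A) of the correct length. Coordinate-based statistics are
#'   meaningful; sequence-based ones (composition, RSCU) are not and need
#'   the real genome sequence.
#' @param genomeLength genome length in bp, default 15676.
#' @export
mneritoidesAnnotationRecord <- function(genomeLength = 15676L) {
  genomeRecord("MelarhapheNeritoides_annotation",
               strrep("A", genomeLength), mneritoidesFeatures(),
               circular = TRUE)
}

#' Published per-region composition of the M. neritoides mitogenome
#'
#' Base percentages and AT/GC skews per region (whole genome, each PCG,
#' the rRNAs and the control region) as shipped in \code{inst/extdata},
#' for skew arithmetic and conformance checks.
#'
#' @return data.frame with columns \code{region}, \code{A}, \code{C},
#'   \code{G}, \code{T}, \code{AT}, \code{GC}, \code{at_skew},
#'   \code{gc_skew}.
#' @export
mneritoidesComposition <- function() {
  path <- system.file("extdata", "mneritoides_composition.tsv",
                      package = "mitoarch", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
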