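## Annotation curation: gene geometry, start/stop selection, duplicate
## resolution, overlap legality. PCG logic runs in "oriented" coordinates
## (the coding strand read 5'->3') so plus and minus strands share one code
## path: for a minus-strand gene the oriented genome is the reverse
## complement and oriented position p maps to genomic position L - p + 1.

.circSub <- function(seqChr, pos, len) {
  L <- nchar(seqChr)
  idx <- .wrapPos(pos:(pos + len - 1L), L)
  if (all(diff(idx) == 1L)) substr(seqChr, idx[1], idx[len])
  else paste(substring(seqChr, idx, idx), collapse = "")
}

## Oriented view of a record for a given strand.
.orientedSeq <- function(record, strand) {
  s <- genomeSequence(record)
  if (strand == "-") .revcomp(s) else s
}
.toOriented <- function(pos, strand, L) if (strand == "-") L - pos + 1L else pos
.fromOriented <- .toOriented  # involution

#' Gene geometry: intergenic spacers and overlaps
#'
#' Computes, for every pair of consecutive features in genomic order
#' (including the wrap-around junction of a circular genome), the gap
#' between them: \code{gap = start(downstream) - end(upstream) - 1}.
#' Negative gaps are overlapping genes, zero gaps abutting genes, positive
#' gaps intergenic spacers.
#'
#' @param record a \linkS4class{GenomeRecord} with at least two features.
#' @param includeControlRegion treat the control region as a feature so its
#'   flanks contribute their own gaps (default \code{TRUE}).
#' @return data.frame with columns \code{upstream}, \code{downstream},
#'   \code{gap}. For a circular record there is one row per feature.
#' @seealso \code{\link{geometrySummary}}
#' @export
computeGeneGeometry <- function(record, includeControlRegion = TRUE) {
  f <- record@features
  if (!includeControlRegion) f <- f[f$kind != "control_region", , drop = FALSE]
  n <- nrow(f)
  if (n < 2) stop("record must have at least two features")
  L <- genomeLength(record)
  up <- seq_len(n - 1L)
  gaps <- f$start[up + 1L] - f$end[up] - 1L
  out <- data.frame(upstream = f$name[up], downstream = f$name[up + 1L],
                    gap = as.integer(gaps), stringsAsFactors = FALSE)
  if (record@circular) {
    wrap <- f$start[1L] - f$end[n] - 1L + L
    out <- rbind(out, data.frame(upstream = f$name[n], downstream = f$name[1L],
                                 gap = as.integer(wrap)))
  }
  ## a feature fully inside another makes "adjacency" ambiguous: flag it
  contained <- which(f$end[-n] >= f$end[-1L] & f$start[-n] <= f$start[-1L])
  if (length(contained))
    warning("feature(s) fully containing the next one: ",
            paste(f$name[contained], collapse = ", "))
  out
}

#' @describeIn computeGeneGeometry summary counts over an adjacency table:
#'   number and total length of positive spacers and number of overlaps.
#' @param geometry the data.frame returned by \code{computeGeneGeometry}.
#' @export
geometrySummary <- function(geometry) {
  list(n_spacers = sum(geometry$gap > 0),
       total_spacer_bp = sum(geometry$gap[geometry$gap > 0]),
       n_overlaps = sum(geometry$gap < 0),
       max_overlap = if (any(geometry$gap < 0)) min(geometry$gap) else 0L)
}

## 5'-flank and 3'-neighbour boundaries of feature i, in oriented
## coordinates of that feature's strand. The transcriptional upstream
## neighbour of a minus-strand gene is the genomically *next* feature.
.pcgContext <- function(record, i) {
  f <- record@features
  n <- nrow(f)
  L <- genomeLength(record)
  strand <- f$strand[i]
  prevI <- if (i == 1L) n else i - 1L
  nextI <- if (i == n) 1L else i + 1L
  ## backSpan: nt between the transcriptional upstream neighbour and the
  ## gene's 5' start (0 when abutting, clamped at 0 for overlaps);
  ## span: nt from the 5' start up to (excluding) the downstream neighbour.
  ## Computed linearly; the genome length is added only at the true
  ## wrap-around junction, so overlaps never wrap the whole circle.
  if (strand == "+") {
    gapUp <- f$start[i] - f$end[prevI] - 1L + if (i == 1L) L else 0L
    span <- f$start[nextI] - f$start[i] + if (i == n) L else 0L
    upS5 <- f$start[prevI]
    upKind <- f$kind[prevI]; upStrand <- f$strand[prevI]
    nextKind <- f$kind[nextI]
    list(strand = strand, s5 = f$start[i], e3 = f$end[i],
         gapUp = gapUp, backSpan = max(gapUp, 0L), span = span,
         upS5 = upS5, upKind = upKind, upStrand = upStrand,
         nextKind = nextKind)
  } else {
    gapUp <- f$start[nextI] - f$end[i] - 1L + if (i == n) L else 0L
    span <- f$end[i] - f$end[prevI] + if (i == 1L) L else 0L
    list(strand = strand,
         s5 = .toOriented(f$end[i], "-", L),
         e3 = .toOriented(f$start[i], "-", L),
         gapUp = gapUp, backSpan = max(gapUp, 0L), span = span,
         upS5 = .toOriented(f$end[nextI], "-", L),
         upKind = f$kind[nextI], upStrand = f$strand[nextI],
         nextKind = f$kind[prevI])
  }
}

#' Select the start codon of a protein-coding gene
#'
#' Applies the first curation rule: a PCG begins at the first eligible
#' in-frame start codon nearest to the preceding gene without overlapping
#' it. An annotated start that already is a valid start codon is kept
#' unless an eligible candidate lies strictly nearer the preceding gene
#' (this preserves genuine, frame-legal overlaps such as the conserved
#' nad4l/nad4 arrangement). When reference protein lengths are supplied,
#' candidates producing a protein outside the range are passed over.
#'
#' @param record a \linkS4class{GenomeRecord}.
#' @param gene PCG name (or feature row index).
#' @param startSet eligible start codons; default
#'   \code{c("ATG","ATA","ATT","ATC","GTG")} with ATG implicitly preferred
#'   because candidates nearer the upstream gene are tried first.
#' @param referenceLength optional numeric \code{c(min, max)} of acceptable
#'   protein lengths (residues).
#' @param window how far into the annotated gene (nt) to search, default 90.
#' @return list with \code{position} (genomic coordinate of the chosen
#'   5' start; for minus-strand genes this is the feature \code{end}),
#'   \code{codon}, \code{changed}, \code{unresolved}, and \code{diff}
#'   (one-row curation-diff data.frame or NULL).
#' @export
selectStartCodon <- function(record, gene,
                             startSet = c("ATG", "ATA", "ATT", "ATC", "GTG"),
                             referenceLength = NULL, window = 90L) {
  i <- if (is.numeric(gene)) gene else which(record@features$name == gene)[1]
  if (is.na(i)) stop("no feature named '", gene, "'")
  f <- record@features[i, ]
  if (f$kind != "PCG") stop("start-codon selection applies to PCGs only")
  ctx <- .pcgContext(record, i)
  oseq <- .orientedSeq(record, ctx$strand)
  L <- nchar(oseq)
  s <- ctx$s5
  gapUp <- ctx$gapUp
  ## candidates may reach into a same-strand upstream PCG when the overlap
  ## is frame-legal (polycistronic transcription forbids same-frame
  ## overlap only); they never overlap a tRNA/rRNA/control region
  ovAllowed <- ctx$upKind == "PCG" && ctx$upStrand == ctx$strand
  maxBack <- max(gapUp, 0L) + if (ovAllowed) 45L else 0L
  offs <- seq.int(-3L * (maxBack %/% 3L), window, by = 3L)
  eligible <- function(o) {
    p <- .wrapPos(s + o, L)
    cod <- .circSub(oseq, p, 3L)
    if (!cod %in% startSet) return(FALSE)
    ov <- max(0L, -(gapUp + o))
    if (ov > 0L) {
      if (!ovAllowed) return(FALSE)
      if ((s + o - ctx$upS5) %% 3L == 0L) return(FALSE)  # same frame
    }
    if (!is.null(referenceLength)) {
      aalen <- ((ctx$e3 - p) %% L + 1L) / 3 - 1
      if (aalen < referenceLength[1] || aalen > referenceLength[2]) return(FALSE)
    }
    TRUE
  }
  cand <- offs[vapply(offs, eligible, logical(1))]
  curCodon <- .circSub(oseq, s, 3L)
  ## an annotated start that is itself a valid start codon is always a
  ## candidate (conservative: reference filters never evict it)
  if (curCodon %in% startSet && !0L %in% cand) cand <- c(cand, 0L)
  chosen <- NA_integer_
  if (length(cand)) {
    ov <- pmax(0L, -(gapUp + cand))
    chosen_o <- cand[order(ov, cand)][1]  # least overlap, then nearest 5'
    chosen <- .wrapPos(s + chosen_o, L)
  }
  if (is.na(chosen)) {
    return(list(position = if (ctx$strand == "+") f$start else f$end,
                codon = curCodon, changed = FALSE, unresolved = TRUE,
                diff = NULL))
  }
  genomic <- .fromOriented(chosen, ctx$strand, L)
  changed <- chosen != s
  diff <- NULL
  if (changed) {
    field <- if (ctx$strand == "+") "start" else "end"
    diff <- data.frame(gene = f$name, field = field,
                       old = as.character(if (ctx$strand == "+") f$start else f$end),
                       new = as.character(genomic), rule = 1L,
                       stringsAsFactors = FALSE)
  }
  list(position = genomic, codon = .circSub(oseq, chosen, 3L),
       changed = changed, unresolved = FALSE, diff = diff)
}

#' Resolve the stop codon of a protein-coding gene
#'
#' Applies the third curation rule: scanning in frame from the (already
#' fixed) start, the gene ends at the first full TAA/TAG stop codon; if
#' none occurs before the downstream feature, it ends with an abbreviated
#' stop (TA- or T--) immediately before that feature, to be completed to
#' TAA by polyadenylation of the transcript. A full stop is allowed to
#' overlap the downstream feature by at most two nucleotides (as observed
#' for stops abutting tRNAs).
#'
#' @inheritParams selectStartCodon
#' @param code genetic code, default table 5.
#' @return list with \code{end} (genomic coordinate of the 3' end; for a
#'   minus-strand gene this is the feature \code{start}), \code{stopCodon}
#'   (\code{TAA}/\code{TAG}/\code{TA-}/\code{T--}), \code{changed},
#'   \code{unresolved} and \code{diff}.
#' @export
resolveStopCodon <- function(record, gene, code = geneticCode(5L)) {
  i <- if (is.numeric(gene)) gene else which(record@features$name == gene)[1]
  if (is.na(i)) stop("no feature named '", gene, "'")
  f <- record@features[i, ]
  if (f$kind != "PCG") stop("stop-codon resolution applies to PCGs only")
  ctx <- .pcgContext(record, i)
  oseq <- .orientedSeq(record, ctx$strand)
  L <- nchar(oseq)
  s <- ctx$s5
  span <- ctx$span                      # nt from start up to downstream feature
  ## a full stop must begin before the downstream feature (it may then end
  ## up to 2 nt inside it, as stops abutting tRNAs do); when the neighbour
  ## is a PCG the scan continues into it, where overlap is frame-legal
  slack <- if (ctx$nextKind == "PCG") 45L else 0L
  newEnd <- NA_integer_
  stopCod <- NA_character_
  k <- 1L
  while (3L * k <= span - 1L + slack) {
    cod <- .circSub(oseq, .wrapPos(s + 3L * k, L), 3L)
    if (cod %in% stopCodons(code)) {
      newEnd <- .wrapPos(s + 3L * k + 2L, L)
      stopCod <- cod
      break
    }
    k <- k + 1L
  }
  if (is.na(newEnd)) {
    r <- span %% 3L
    tail <- if (r > 0) .circSub(oseq, .wrapPos(s + span - r, L), r) else ""
    if (r == 1L && tail == "T") { newEnd <- .wrapPos(s + span - 1L, L); stopCod <- "T--" }
    if (r == 2L && tail == "TA") { newEnd <- .wrapPos(s + span - 1L, L); stopCod <- "TA-" }
  }
  if (is.na(newEnd)) {
    return(list(end = if (ctx$strand == "+") f$end else f$start,
                stopCodon = f$stop_codon, changed = FALSE, unresolved = TRUE,
                diff = NULL))
  }
  genomic <- .fromOriented(newEnd, ctx$strand, L)
  oldEnd <- if (ctx$strand == "+") f$end else f$start
  changed <- genomic != oldEnd
  diff <- NULL
  if (changed) {
    field <- if (ctx$strand == "+") "end" else "start"
    diff <- data.frame(gene = f$name, field = field,
                       old = as.character(oldEnd), new = as.character(genomic),
                       rule = 3L, stringsAsFactors = FALSE)
  }
  list(end = genomic, stopCodon = stopCod, changed = changed,
       unresolved = FALSE, diff = diff)
}

#' Check legality of PCG-PCG overlaps
#'
#' Both mitochondrial strands are transcribed as polycistronic RNA, so two
#' protein-coding genes on the same strand cannot overlap in the same
#' reading frame; overlaps across strands or in different frames are
#' possible. Frames are compared on the codon grid of the coding strand.
#'
#' @param record a \linkS4class{GenomeRecord}.
#' @return data.frame of overlapping PCG pairs with columns \code{gene1},
#'   \code{gene2}, \code{overlap} (nt), \code{same_strand},
#'   \code{same_frame}, \code{violation}; zero rows if no PCGs overlap.
#' @export
checkPcgOverlapLegality <- function(record) {
  f <- record@features[record@features$kind == "PCG", , drop = FALSE]
  L <- genomeLength(record)
  out <- list()
  n <- nrow(f)
  if (n >= 2) for (a in 1:(n - 1)) for (b in (a + 1):n) {
    ov <- min(f$end[a], f$end[b]) - max(f$start[a], f$start[b]) + 1L
    if (ov <= 0) next
    sameStrand <- f$strand[a] == f$strand[b]
    sameFrame <- if (!sameStrand) NA else {
      if (f$strand[a] == "+") (f$start[b] - f$start[a]) %% 3L == 0L
      else (f$end[a] - f$end[b]) %% 3L == 0L
    }
    out[[length(out) + 1L]] <- data.frame(
      gene1 = f$name[a], gene2 = f$name[b], overlap = ov,
      same_strand = sameStrand, same_frame = sameFrame,
      violation = isTRUE(sameStrand) && isTRUE(sameFrame),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene1 = character(0), gene2 = character(0),
                      overlap = integer(0), same_strand = logical(0),
                      same_frame = logical(0), violation = logical(0)))
  do.call(rbind, out)
}

#' Resolve duplicated gene annotations by quality
#'
#' When an annotation pipeline reports a gene more than once, the candidate
#' with the highest quality score is retained; ties keep the earliest
#' candidate by start coordinate, with a warning.
#'
#' @param features feature data.frame (with \code{quality} column) or a
#'   \linkS4class{GenomeRecord}.
#' @return list with \code{features} (retained rows, original order) and
#'   \code{diffs} (one curation-diff row per removed candidate, rule 4).
#' @export
deduplicateCandidates <- function(features) {
  if (methods::is(features, "GenomeRecord")) features <- features@features
  keep <- rep(TRUE, nrow(features))
  diffs <- list()
  for (nm in unique(features$name[duplicated(features$name)])) {
    idx <- which(features$name == nm)
    q <- features$quality[idx]
    q[is.na(q)] <- -Inf
    best <- idx[q == max(q)]
    if (length(best) > 1) {
      warning("quality tie for duplicated gene '", nm,
              "': keeping earliest by start coordinate")
      best <- best[which.min(features$start[best])]
    }
    drop <- setdiff(idx, best)
    keep[drop] <- FALSE
    for (d in drop)
      diffs[[length(diffs) + 1L]] <- data.frame(
        gene = nm, field = "removed_duplicate",
        old = sprintf("%d..%d", features$start[d], features$end[d]),
        new = "", rule = 4L, stringsAsFactors = FALSE)
  }
  list(features = features[keep, , drop = FALSE],
       diffs = if (length(diffs)) do.call(rbind, diffs) else
         data.frame(gene = character(0), field = character(0),
                    old = character(0), new = character(0), rule = integer(0)))
}

#' Curate an annotated mitogenome record
#'
#' Applies the rule-based curation procedure: duplicate resolution by
#' quality (rule 4) once, then stop-codon resolution (rule 3) and
#' start-codon selection (rule 1) iterated to a fixpoint (start selection
#' reads the upstream neighbour's end, so stops -- which depend only on
#' the gene's reading frame -- are settled first in each pass), and
#' finally same-strand same-frame overlap checks (rule 2). tRNA and rRNA
#' boundaries are left untouched (rules 5-6). If reference records are supplied, per-gene length deltas against
#' the reference mean are reported but never auto-applied (rule 7), and
#' reference protein lengths (\eqn{\pm}{+/-}10\% by default) constrain
#' start-codon candidates. Unresolvable genes are flagged, never dropped.
#'
#' @param record a \linkS4class{GenomeRecord}.
#' @param referenceRecords optional list of \code{GenomeRecord}s from
#'   related taxa.
#' @param startSet eligible start codons (see \code{\link{selectStartCodon}}).
#' @param window start-search window (nt into the gene), default 90.
#' @param referenceTolerance relative tolerance around the reference mean
#'   protein length, default 0.1.
#' @param code genetic code, default table 5.
#' @return list with elements \code{record} (curated), \code{diffs}
#'   (curation-diff data.frame: gene, field, old, new, rule),
#'   \code{violations} (overlap-legality table), \code{referenceDeltas}
#'   (per-gene length differences vs the reference mean, or NULL) and
#'   \code{unresolved} (gene names whose start or stop could not be fixed).
#' @examples
#' sim <- makeAnnotatedGenome(seed = 7, pStartShift = 0.5)
#' cur <- curateRecord(sim$corrupted)
#' identical(gbFeatures(cur$record), gbFeatures(sim$truth))
#' @export
curateRecord <- function(record, referenceRecords = NULL,
                         startSet = c("ATG", "ATA", "ATT", "ATC", "GTG"),
                         window = 90L, referenceTolerance = 0.1,
                         code = geneticCode(5L)) {
  dd <- deduplicateCandidates(record)
  rec <- record
  gbFeatures(rec) <- dd$features
  diffs <- list(dd$diffs)
  unresolved <- character(0)

  refLen <- NULL
  if (!is.null(referenceRecords)) {
    lens <- list()
    for (rr in referenceRecords) {
      fr <- rr@features[rr@features$kind == "PCG", ]
      aalen <- .featLength(fr$start, fr$end, genomeLength(rr)) / 3 - 1
      for (j in seq_len(nrow(fr)))
        lens[[fr$name[j]]] <- c(lens[[fr$name[j]]], aalen[j])
    }
    refLen <- lapply(lens, function(v)
      mean(v) * c(1 - referenceTolerance, 1 + referenceTolerance))
  }

  ## start selection for one gene depends on its neighbours' (possibly
  ## also wrong) boundaries, so the start/stop passes iterate to a
  ## fixpoint; convergence is immediate on clean records
  pcgNames <- rec@features$name[rec@features$kind == "PCG"]
  for (pass in 1:3) {
    changedAny <- FALSE
    unresolved <- character(0)
    for (nm in pcgNames) {
      i <- which(rec@features$name == nm)
      res <- resolveStopCodon(rec, i, code = code)
      if (res$unresolved) { unresolved <- c(unresolved, nm); next }
      if (res$changed) {
        fld <- res$diff$field
        rec@features[[fld]][i] <- as.integer(res$diff$new)
        diffs[[length(diffs) + 1L]] <- res$diff
        changedAny <- TRUE
      }
      if (!identical(rec@features$stop_codon[i], res$stopCodon)) {
        if (!is.na(rec@features$stop_codon[i])) {
          diffs[[length(diffs) + 1L]] <- data.frame(
            gene = nm, field = "stop_codon",
            old = rec@features$stop_codon[i], new = res$stopCodon, rule = 3L)
          changedAny <- TRUE
        }
        rec@features$stop_codon[i] <- res$stopCodon
      }
    }
    for (nm in pcgNames) {
      i <- which(rec@features$name == nm)
      sel <- selectStartCodon(rec, i, startSet = startSet,
                              referenceLength = refLen[[nm]], window = window)
      if (sel$unresolved) { unresolved <- c(unresolved, nm); next }
      if (sel$changed) {
        fld <- sel$diff$field
        rec@features[[fld]][i] <- as.integer(sel$diff$new)
        diffs[[length(diffs) + 1L]] <- sel$diff
        changedAny <- TRUE
      }
      if (!identical(rec@features$start_codon[i], sel$codon)) {
        if (!is.na(rec@features$start_codon[i])) {
          diffs[[length(diffs) + 1L]] <- data.frame(
            gene = nm, field = "start_codon",
            old = rec@features$start_codon[i], new = sel$codon, rule = 1L)
          changedAny <- TRUE
        }
        rec@features$start_codon[i] <- sel$codon
      }
    }
    if (!changedAny) break
  }
  gbFeatures(rec) <- rec@features  # re-sort and re-validate

  refDeltas <- NULL
  if (!is.null(refLen)) {
    fr <- rec@features[rec@features$kind == "PCG", ]
    own <- .featLength(fr$start, fr$end, genomeLength(rec)) / 3 - 1
    mid <- vapply(refLen[fr$name], mean, numeric(1))
    refDeltas <- data.frame(gene = fr$name, length = own,
                            reference_mean = mid, delta = own - mid)
  }

  list(record = rec,
       diffs = .consolidateDiffs(do.call(rbind, diffs)),
       violations = checkPcgOverlapLegality(rec),
       referenceDeltas = refDeltas,
       unresolved = unique(unresolved))
}

## Collapse multi-pass diff rows: one row per (gene, field) with the
## original old value and the final new value; no-op rows are dropped,
## duplicate removals kept as-is.
.consolidateDiffs <- function(d) {
  if (is.null(d) || !nrow(d)) return(d)
  dup <- d[d$field == "removed_duplicate", , drop = FALSE]
  rest <- d[d$field != "removed_duplicate", , drop = FALSE]
  if (nrow(rest)) {
    key <- paste(rest$gene, rest$field)
    rows <- lapply(unique(key), function(k) {
      g <- rest[key == k, , drop = FALSE]
      g$new[1] <- g$new[nrow(g)]
      g$rule[1] <- g$rule[nrow(g)]
      g[1, , drop = FALSE]
    })
    rest <- do.call(rbind, rows)
    rest <- rest[rest$old != rest$new, , drop = FALSE]
  }
  out <- rbind(dup, rest)
  rownames(out) <- NULL
  out
}
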