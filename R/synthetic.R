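## Seeded generators producing inputs with the statistical structure each
## analysis stage assumes: annotated circular genomes whose true annotation
## satisfies every curation rule (with optional injected errors), codon
## alignments evolved under the branch model, scrambled gene orders, and
## clock trees with rate-accelerated lineages. Every generator is a pure
## function of its arguments and seed.

#' Mitogenome-like gene layout
#'
#' The default layout of \code{\link{makeAnnotatedGenome}}: a circular
#' 15.7-kb genome with 13 protein-coding genes, 22 tRNAs, 2 rRNAs and a
#' control region in the gene order, strand assignment, gene lengths and
#' intergenic gaps characteristic of littorinid gastropod mitogenomes,
#' including the conserved 7-nt nad4l/nad4 overlap and the tRNA/rRNA
#' overlaps around the small and large rRNA. \code{gapAfter} is the gap to
#' the next feature (negative = overlap); the last entry closes the circle.
#'
#' @return data.frame with columns \code{name}, \code{kind}, \code{strand},
#'   \code{len}, \code{gapAfter}, \code{startCodon}.
#' @export
defaultMitogenomeLayout <- function() {
  x <- rbind(
    c("cox1",      "PCG",  "+", 1536, 11), c("cox2",  "PCG",  "+",  687,  5),
    c("trnD(gtc)", "tRNA", "+",   68,  1), c("atp8",  "PCG",  "+",  159,  2),
    c("atp6",      "PCG",  "+",  696, 38), c("trnM(cat)", "tRNA", "-", 68, 1),
    c("trnY(gta)", "tRNA", "-",   68,  1), c("trnC(gca)", "tRNA", "-", 66, 1),
    c("trnW(tca)", "tRNA", "-",   66,  2), c("trnQ(ttg)", "tRNA", "-", 57, 7),
    c("trnG(tcc)", "tRNA", "-",   67,  0), c("trnE(ttc)", "tRNA", "-", 65, 78),
    c("rrnS",      "rRNA", "+",  882, -3), c("trnV(tac)", "tRNA", "+", 67, -23),
    c("rrnL",      "rRNA", "+", 1414, -36), c("trnL2(taa)", "tRNA", "+", 70, 2),
    c("trnL1(tag)", "tRNA", "+",  68,  0), c("nad1",  "PCG",  "+",  942,  0),
    c("trnP(tgg)", "tRNA", "+",   67,  1), c("nad6",  "PCG",  "+",  504,  8),
    c("cob",       "PCG",  "+", 1140,  9), c("trnS2(tga)", "tRNA", "+", 67, 0),
    c("trnT(tgt)", "tRNA", "-",   70,  8), c("nad4l", "PCG",  "+",  297, -7),
    c("nad4",      "PCG",  "+", 1371,  0), c("trnH(gtg)", "tRNA", "+", 64, 0),
    c("nad5",      "PCG",  "+", 1722, -1), c("trnF(gaa)", "tRNA", "+", 67, 0),
    c("CR", "control_region", "+", 474,  0), c("cox3", "PCG", "+", 780, 32),
    c("trnK(ttt)", "tRNA", "+",   72, 11), c("trnA(tgc)", "tRNA", "+", 68, 1),
    c("trnR(tcg)", "tRNA", "+",   69, 10), c("trnN(gtt)", "tRNA", "+", 67, 15),
    c("trnI(gat)", "tRNA", "+",   67,  3), c("nad3",  "PCG",  "+",  354,  0),
    c("trnS1(gct)", "tRNA", "+",  68,  0), c("nad2",  "PCG",  "+", 1062,  3))
  out <- data.frame(name = x[, 1], kind = x[, 2], strand = x[, 3],
                    len = as.integer(x[, 4]), gapAfter = as.integer(x[, 5]),
                    stringsAsFactors = FALSE)
  out$startCodon <- ifelse(out$kind == "PCG", "ATG", NA_character_)
  out$startCodon[out$name == "atp6"] <- "ATT"
  out
}

.randomCodon <- function(n, code, exclude = stopCodons(code)) {
  pool <- setdiff(names(code@codons), exclude)
  sample(pool, n, replace = TRUE)
}

## Write a CDS (already a character vector of bytes, coding strand) into a
## genome byte vector at genomic [start..end], honouring strand.
.writeCDS <- function(seqv, start, end, strand, cds) {
  if (strand == "-") cds <- strsplit(.revcomp(paste(cds, collapse = "")), "")[[1]]
  seqv[start:end] <- cds
  seqv
}

.buildCDS <- function(len, startCodon, code, abbreviated = FALSE) {
  rem <- len %% 3L
  m <- len %/% 3L
  if (rem == 0L && abbreviated) stop("abbreviated CDS length must not be a multiple of 3")
  body <- .randomCodon(m - 1L - (rem == 0L), code)
  if (rem == 0L) {
    cds <- c(startCodon, body, sample(stopCodons(code), 1))
  } else {
    cds <- c(startCodon, body, if (rem == 1L) "T" else "TA")
  }
  strsplit(paste(cds, collapse = ""), "")[[1]]
}

#' Generate an annotated circular genome, optionally corrupted
#'
#' Builds a circular genome whose true annotation satisfies every curation
#' rule: PCGs begin at the configured start codon (with no eligible
#' in-frame start codon between them and the preceding gene), contain no
#' internal stops, end at their first in-frame stop (or with an
#' abbreviated stop flush against the downstream tRNA), overlapping PCGs
#' sit in different frames, and gaps follow the layout. A corrupted copy
#' is produced by independently shifting PCG starts and stops by codon
#' multiples and/or duplicating tRNAs with lower quality scores, with the
#' injected changes returned as ground truth.
#'
#' @param seed integer seed (mandatory for reproducibility).
#' @param layout gene layout data.frame (see
#'   \code{\link{defaultMitogenomeLayout}}).
#' @param pStartShift,pStopShift per-PCG probability of shifting the
#'   annotated start / stop by 1-3 codons.
#' @param pDuplicate per-tRNA probability of adding a lower-quality
#'   duplicate annotation.
#' @param abbrevStopGenes names of PCGs that should end with an
#'   abbreviated stop (their layout length must be 1 or 2 mod 3).
#' @param code genetic code, default table 5.
#' @param id record id prefix.
#' @return list with \code{truth} and \code{corrupted}
#'   (\linkS4class{GenomeRecord}s) and \code{diffs}, the injected changes
#'   (data.frame gene/field/old/new/type).
#' @examples
#' sim <- makeAnnotatedGenome(seed = 1)
#' identical(sim$truth, sim$corrupted)  # no corruption switched on
#' @export
makeAnnotatedGenome <- function(seed, layout = defaultMitogenomeLayout(),
                                pStartShift = 0, pStopShift = 0,
                                pDuplicate = 0,
                                abbrevStopGenes = character(0),
                                code = geneticCode(5L), id = "synthetic") {
  .withSeed(seed, {
    lay <- layout
    n <- nrow(lay)
    starts <- integer(n); ends <- integer(n)
    pos <- 1L
    for (i in seq_len(n)) {
      starts[i] <- pos
      ends[i] <- pos + lay$len[i] - 1L
      pos <- ends[i] + lay$gapAfter[i] + 1L
    }
    L <- pos - 1L
    if (any(ends > L)) stop("layout overflow: genes do not fit the genome")
    seqv <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

    ## write PCG coding sequences; handle same-strand PCG-PCG overlaps by
    ## joint rejection sampling of the shared bytes
    pcgIdx <- which(lay$kind == "PCG")
    for (i in pcgIdx) {
      abbrev <- lay$name[i] %in% abbrevStopGenes
      if (!abbrev && lay$len[i] %% 3L != 0L)
        stop("PCG '", lay$name[i], "' length must be a multiple of 3")
      cds <- .buildCDS(lay$len[i], lay$startCodon[i], code, abbrev)
      seqv <- .writeCDS(seqv, starts[i], ends[i], lay$strand[i], cds)
      prev <- pcgIdx[pcgIdx < i]
      prev <- prev[ends[prev] >= starts[i]]
      for (j in prev) {
        if (lay$strand[j] != "+" || lay$strand[i] != "+")
          stop("overlapping PCGs are only generated on the plus strand")
        if ((starts[i] - starts[j]) %% 3L == 0L)
          stop("layout places same-frame PCG overlap: ", lay$name[j], "/",
               lay$name[i])
        seqv <- .fixPcgOverlap(seqv, starts[j], ends[j], starts[i], ends[i],
                               code)
        ## beyond the shared zone, keep the start-search window of the
        ## overlapping gene free of alternative in-frame start codons
        startSet <- c("ATG", "ATA", "ATT", "ATC", "GTG")
        safe <- setdiff(setdiff(names(code@codons), stopCodons(code)), startSet)
        ## cover the 90-nt search window even when the annotated start is
        ## later corrupted by up to 3 codons downstream
        for (cs in seq.int(starts[i], starts[i] + 99L, by = 3L)) {
          if (cs <= ends[j] + 2L || cs + 2L > ends[i]) next
          if (paste(seqv[cs:(cs + 2L)], collapse = "") %in% startSet)
            seqv[cs:(cs + 2L)] <- strsplit(sample(safe, 1), "")[[1]]
        }
      }
    }

    features <- data.frame(
      name = lay$name, kind = lay$kind, strand = lay$strand,
      start = starts, end = ends,
      start_codon = lay$startCodon,
      stop_codon = NA_character_,
      quality = round(stats::runif(n, 0.85, 0.99), 3),
      stringsAsFactors = FALSE)
    for (i in pcgIdx) {
      tail3 <- if (lay$strand[i] == "+")
        paste(seqv[(ends[i] - 2L):ends[i]], collapse = "")
      else .revcomp(paste(seqv[starts[i]:(starts[i] + 2L)], collapse = ""))
      features$stop_codon[i] <- if (lay$name[i] %in% abbrevStopGenes) {
        if (lay$len[i] %% 3L == 1L) "T--" else "TA-"
      } else tail3
    }
    truth <- genomeRecord(paste0(id, "_truth"), paste(seqv, collapse = ""),
                          features, circular = TRUE)
    ## an abbreviated stop must not be completed by chance: if the partial
    ## tail plus the first tRNA bases happens to read TAA/TAG, break it
    for (i in pcgIdx[lay$name[pcgIdx] %in% abbrevStopGenes]) {
      ctx <- .pcgContext(truth, i)
      oseq <- .orientedSeq(truth, lay$strand[i])
      r <- lay$len[i] %% 3L
      boundary <- .circSub(oseq, .wrapPos(ctx$e3 - r + 1L, L), 3L)
      if (boundary %in% stopCodons(code)) {
        p <- .wrapPos(ctx$e3 + 1L, L)
        gpos <- if (lay$strand[i] == "+") p else L - p + 1L
        seqv[gpos] <- if (lay$strand[i] == "+") "C" else "G"
        truth <- genomeRecord(paste0(id, "_truth"),
                              paste(seqv, collapse = ""), features,
                              circular = TRUE)
      }
    }
    ## remove eligible in-frame start codons from the region between each
    ## PCG and its upstream neighbour, so the annotated start is the first
    ## eligible one (curation rule 1 fixpoint)
    seqv <- .cleanStartWindows(truth, seqv, code)
    truth <- genomeRecord(paste0(id, "_truth"), paste(seqv, collapse = ""),
                          features, circular = TRUE)

    ## corruption
    corrupted <- features
    diffs <- list()
    for (i in pcgIdx) {
      ctx <- .pcgContext(truth, i)
      if (stats::runif(1) < pStartShift) {
        back <- min(ctx$backSpan %/% 3L, 3L)
        shifts <- c(if (back > 0) -seq_len(back), 1:3) * 3L
        fld <- if (lay$strand[i] == "+") "start" else "end"
        old <- corrupted[[fld]][i]
        cand <- old + if (lay$strand[i] == "+") shifts else -shifts
        shifts <- shifts[cand >= 1L & cand <= L]  # never cross the origin
        sh <- sample(shifts, 1)
        newPos <- old + if (lay$strand[i] == "+") sh else -sh
        corrupted[[fld]][i] <- newPos
        diffs[[length(diffs) + 1L]] <- data.frame(
          gene = lay$name[i], field = fld, old = old, new = newPos,
          type = "start_shift")
      }
      if (!(lay$name[i] %in% abbrevStopGenes) && stats::runif(1) < pStopShift) {
        room <- max(lay$gapAfter[i], 0L) %/% 3L
        shifts <- c(-(1:3), if (room > 0) seq_len(min(room, 3L))) * 3L
        fld <- if (lay$strand[i] == "+") "end" else "start"
        old <- corrupted[[fld]][i]
        cand <- old + if (lay$strand[i] == "+") shifts else -shifts
        shifts <- shifts[cand >= 1L & cand <= L]
        sh <- sample(shifts, 1)
        newPos <- old + if (lay$strand[i] == "+") sh else -sh
        corrupted[[fld]][i] <- newPos
        diffs[[length(diffs) + 1L]] <- data.frame(
          gene = lay$name[i], field = fld, old = old, new = newPos,
          type = "stop_shift")
      }
    }
    ## corrupted codon annotations follow the (possibly wrong) coordinates
    tmp <- genomeRecord("tmp", paste(seqv, collapse = ""), corrupted,
                        circular = TRUE)
    tf <- tmp@features
    for (k in which(tf$kind == "PCG")) {
      g <- extractGeneSequence(tmp, tf[k, , drop = FALSE])
      tf$start_codon[k] <- substr(g, 1, 3)
      tf$stop_codon[k] <- if (!is.na(tf$stop_codon[k]) &&
                              tf$stop_codon[k] %in% c("T--", "TA-"))
        tf$stop_codon[k] else substr(g, nchar(g) - 2, nchar(g))
    }
    corrupted <- tf
    for (i in which(lay$kind == "tRNA")) {
      if (stats::runif(1) < pDuplicate) {
        dup <- corrupted[corrupted$name == lay$name[i] &
                           corrupted$start == starts[i], , drop = FALSE][1, ]
        shift <- sample(c(-40L, -25L, 25L, 40L), 1)
        dup$start <- .wrapPos(dup$start + shift, L)
        dup$end <- .wrapPos(dup$end + shift, L)
        if (dup$end < dup$start) next  # avoid origin-spanning duplicates
        dup$quality <- round(stats::runif(1, 0.1, 0.5), 3)
        corrupted <- rbind(corrupted, dup)
        diffs[[length(diffs) + 1L]] <- data.frame(
          gene = lay$name[i], field = "duplicate",
          old = NA_integer_, new = dup$start, type = "duplicate_gene")
      }
    }
    corruptedRec <- genomeRecord(paste0(id, "_corrupt"),
                                 paste(seqv, collapse = ""), corrupted,
                                 circular = TRUE)
    list(truth = truth, corrupted = corruptedRec,
         diffs = if (length(diffs)) do.call(rbind, diffs) else
           data.frame(gene = character(0), field = character(0),
                      old = integer(0), new = integer(0), type = character(0)))
  })
}

## Resample the shared bytes of an overlapping plus-strand PCG pair until
## both coding sequences are valid (start codon intact, no internal stop,
## upstream gene ending in a full stop).
.fixPcgOverlap <- function(seqv, s1, e1, s2, e2, code, maxTries = 5000L,
                           startSet = c("ATG", "ATA", "ATT", "ATC", "GTG")) {
  stops <- stopCodons(code)
  zone <- max(s1, s2 - 2L):min(e1 + 2L, e2)
  fixedStart <- s2:(s2 + 2L)
  free <- setdiff(zone, fixedStart)
  ## early codons of the downstream gene inside/straddling the zone must
  ## not read as start codons, so the true start stays unambiguous
  kZone <- (min(e1 + 2L, e2) - s2 + 1L) %/% 3L  # codons fully inside the zone
  check <- function() {
    cds1 <- paste(seqv[s1:e1], collapse = "")
    cds2 <- paste(seqv[s2:e2], collapse = "")
    cod1 <- .splitCodons(cds1)
    cod2 <- .splitCodons(cds2)
    all(!cod1[-length(cod1)] %in% stops) &&
      cod1[length(cod1)] %in% stops &&
      all(!cod2[-length(cod2)] %in% stops) &&
      cod2[length(cod2)] %in% stops &&
      (kZone < 2L || all(!cod2[2:kZone] %in% startSet))
  }
  for (tries in seq_len(maxTries)) {
    if (check()) return(seqv)
    seqv[free] <- sample(c("A", "C", "G", "T"), length(free), replace = TRUE)
  }
  stop("could not satisfy the overlap constraints between PCGs at ",
       s1, " and ", s2)
}

## Mutate in-frame start-set and stop codons out of the upstream spacer
## of every PCG (oriented coordinates, strand-aware): a start codon there
## would pre-empt the annotated one under curation rule 1, and a stop
## codon there would truncate the gene when a corrupted (upstream-shifted)
## start pulls spacer codons into frame.
.cleanStartWindows <- function(record, seqv, code,
                               startSet = c("ATG", "ATA", "ATT", "ATC", "GTG")) {
  L <- length(seqv)
  f <- record@features
  avoid <- c(startSet, stopCodons(code))
  for (i in which(f$kind == "PCG")) {
    ctx <- .pcgContext(record, i)
    oseq <- .orientedSeq(record, ctx$strand)
    back <- ctx$backSpan %/% 3L
    if (back < 1) next
    for (k in seq_len(back)) {
      p <- .wrapPos(ctx$s5 - 3L * k, L)
      if (.circSub(oseq, p, 3L) %in% avoid) {
        gpos <- if (ctx$strand == "+") p else L - p + 1L
        seqv[gpos] <- if (ctx$strand == "+") "C" else "G"
        ## refresh the oriented view after mutating
        record@sequence <- Biostrings::DNAString(paste(seqv, collapse = ""))
        oseq <- .orientedSeq(record, ctx$strand)
      }
    }
  }
  seqv
}

#' Simulate a codon alignment under the branch model
#'
#' Evolves root codons drawn from the equilibrium frequencies down the
#' tree using exact matrix-exponential transition probabilities per
#' branch, with a (possibly branch-specific) omega. The simulated states
#' are sense codons only, so alignments never contain stops.
#'
#' @param tree \code{phylo} with branch lengths (expected substitutions
#'   per codon).
#' @param omega scalar, or per-edge vector in \code{tree$edge} order, or a
#'   named vector \code{c(tipOrNodeLabel = omega, .default = omega)}
#'   assigning a foreground omega to the branch above the named node.
#' @param kappa transition/transversion ratio, default 2.
#' @param freqs equilibrium codon frequencies (default uniform over the
#'   sense codons).
#' @param nCodons number of codon sites (> 0).
#' @param seed integer seed.
#' @param code genetic code, default table 5.
#' @return \code{DNAStringSet} of the tip sequences (3 x nCodons nt each).
#' @export
simulateCodonAlignment <- function(tree, omega, kappa = 2, freqs = NULL,
                                   nCodons, seed, code = geneticCode(5L)) {
  if (nCodons < 1) stop("nCodons must be positive")
  sense <- senseCodons(code)
  pi <- .checkFreqs(freqs, sense)
  nEdge <- nrow(tree$edge)
  if (!is.null(names(omega))) {
    if (!".default" %in% names(omega))
      stop("named omega needs a '.default' background value")
    om <- rep(omega[[".default"]], nEdge)
    for (nm in setdiff(names(omega), ".default"))
      om[.resolveForeground(tree, nm)] <- omega[[nm]]
    omega <- om
  } else if (length(omega) == 1L) omega <- rep(omega, nEdge)
  stopifnot(length(omega) == nEdge)
  .withSeed(seed, {
    nTip <- length(tree$tip.label)
    nNode <- max(tree$edge)
    states <- matrix(NA_integer_, nNode, nCodons)
    tr <- stats::reorder(tree, "postorder")
    root <- tr$edge[nrow(tr$edge), 1]
    states[root, ] <- sample.int(length(sense), nCodons, replace = TRUE,
                                 prob = pi)
    decs <- lapply(unique(omega), function(o) .codonEigen(kappa, o, pi, code))
    names(decs) <- as.character(unique(omega))
    ## preorder: reversed postorder edge sequence
    for (k in rev(seq_len(nEdge))) {
      parent <- tr$edge[k, 1]; child <- tr$edge[k, 2]
      ord <- match(paste(tr$edge[k, 1], tr$edge[k, 2]),
                   paste(tree$edge[, 1], tree$edge[, 2]))
      P <- .probMatrix(decs[[as.character(omega[ord])]],
                       tree$edge.length[ord])
      ps <- states[parent, ]
      cs <- integer(nCodons)
      for (s in unique(ps)) {
        w <- which(ps == s)
        cs[w] <- sample.int(length(sense), length(w), replace = TRUE,
                            prob = P[s, ])
      }
      states[child, ] <- cs
    }
    seqs <- vapply(seq_len(nTip), function(i)
      paste(sense[states[i, ]], collapse = ""), character(1))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- tree$tip.label
    out
  })
}

#' Scramble a circular gene order by random rearrangements
#'
#' Applies the requested number of random segment inversions
#' (sign-flipping reversals) and transpositions to a circular signed gene
#' order, returning the scrambled order and the event log. Segments never
#' cover the whole circle.
#'
#' @param order a \linkS4class{GeneOrder} with at least 3 genes.
#' @param nInversions,nTranspositions event counts.
#' @param seed integer seed.
#' @return list with \code{order} (scrambled \code{GeneOrder}) and
#'   \code{events} (data.frame type/from/to/insertAt).
#' @export
scrambleGeneOrder <- function(order, nInversions = 0L, nTranspositions = 0L,
                              seed) {
  n <- length(order@genes)
  if (n < 3) stop("gene order must have at least 3 genes")
  .withSeed(seed, {
    g <- order@genes; s <- order@signs
    ev <- list()
    for (k in seq_len(nInversions)) {
      len <- sample.int(n - 1L, 1)
      from <- sample.int(n, 1)
      idx <- .wrapPos(from:(from + len - 1L), n)
      g[idx] <- rev(g[idx]); s[idx] <- rev(-s[idx])
      ev[[length(ev) + 1L]] <- data.frame(type = "inversion", from = from,
                                          to = .wrapPos(from + len - 1L, n),
                                          insertAt = NA_integer_)
    }
    for (k in seq_len(nTranspositions)) {
      len <- sample.int(n - 2L, 1)
      from <- sample.int(n, 1)
      idx <- .wrapPos(from:(from + len - 1L), n)
      rest <- setdiff(seq_len(n), idx)
      at <- sample(seq_along(rest), 1)
      newIdx <- append(rest, idx, after = at)
      g <- g[newIdx]; s <- s[newIdx]
      ev[[length(ev) + 1L]] <- data.frame(type = "transposition", from = from,
                                          to = .wrapPos(from + len - 1L, n),
                                          insertAt = at)
    }
    list(order = methods::initialize(order, genes = g, signs = s),
         events = if (length(ev)) do.call(rbind, ev) else
           data.frame(type = character(0), from = integer(0),
                      to = integer(0), insertAt = integer(0)))
  })
}

#' Clock tree with designated rate-accelerated lineages
#'
#' Draws a random ultrametric (coalescent) topology scaled to the given
#' depth, then stretches the pendant edge of each named taxon so its
#' root-to-tip distance equals \code{depth * factor}. Optionally simulates
#' a nucleotide alignment on the resulting tree for bootstrap testing.
#'
#' @param nTaxa number of taxa (tips are labelled t1..tn).
#' @param depth root-to-tip distance of the clock-like taxa
#'   (substitutions/site).
#' @param rateMultipliers named numeric vector taxon -> factor (> 0).
#' @param seed integer seed.
#' @param alnLength if > 0, simulate this many nucleotide sites under a
#'   Jukes-Cantor model on the tree.
#' @return list with \code{tree} (rooted \code{phylo}) and
#'   \code{alignment} (character matrix of aligned sites, or \code{NULL}).
#' @export
makeClockTree <- function(nTaxa, depth = 1, rateMultipliers = NULL, seed,
                          alnLength = 0L) {
  stopifnot(is.null(rateMultipliers) || all(rateMultipliers > 0))
  .withSeed(seed, {
    tr <- ape::rcoal(nTaxa)
    d <- ape::node.depth.edgelength(tr)[seq_len(nTaxa)]
    tr$edge.length <- tr$edge.length * depth / max(d)
    if (!is.null(rateMultipliers)) {
      for (nm in names(rateMultipliers)) {
        tip <- match(nm, tr$tip.label)
        if (is.na(tip)) stop("unknown taxon in rateMultipliers: ", nm)
        e <- which(tr$edge[, 2] == tip)
        tr$edge.length[e] <- tr$edge.length[e] +
          depth * (rateMultipliers[[nm]] - 1)
      }
    }
    aln <- NULL
    if (alnLength > 0) {
      sim <- phangorn::simSeq(tr, l = alnLength, type = "DNA")
      aln <- as.character(sim)
    }
    list(tree = tr, alignment = aln)
  })
}
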