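## Branch-model dN/dS inference under a Goldman-Yang style codon model:
## single-nucleotide codon exchanges with rate proportional to the target
## codon frequency, multiplied by kappa for transitions and by omega for
## non-synonymous changes; omega may differ per branch.

.NUC <- c("T", "C", "A", "G")
.isTransition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
}

## Single-step exchange table among sense codons (cached per table id).
.stepCache <- new.env(parent = emptyenv())
.codonSteps <- function(code) {
  key <- as.character(code@tableId)
  if (!is.null(.stepCache[[key]])) return(.stepCache[[key]])
  sense <- senseCodons(code)
  aa <- .translateCodon(sense, code)
  n <- length(sense)
  mat <- do.call(rbind, strsplit(sense, ""))
  ii <- jj <- integer(0); ts <- syn <- logical(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dpos <- which(mat[i, ] != mat[j, ])
    if (length(dpos) != 1L) next
    ii <- c(ii, i); jj <- c(jj, j)
    ts <- c(ts, .isTransition(mat[i, dpos], mat[j, dpos]))
    syn <- c(syn, aa[i] == aa[j])
  }
  out <- list(sense = sense, i = ii, j = jj, ts = ts, syn = syn)
  .stepCache[[key]] <- out
  out
}

#' Codon substitution rate matrix
#'
#' Builds the generator matrix of the codon model over the sense codons:
#' \eqn{q_{ij} = 0} when codons differ at more than one position, and
#' otherwise proportional to \eqn{\pi_j}, times \eqn{\kappa} for a
#' transition and times \eqn{\omega} for a non-synonymous change. The
#' diagonal makes rows sum to zero and the matrix is scaled so the mean
#' substitution rate at stationarity is 1 (branch lengths are then
#' expected substitutions per codon).
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega non-synonymous/synonymous rate ratio (>= 0).
#' @param freqs equilibrium codon frequencies over the sense codons
#'   (named or in \code{senseCodons(code)} order); default uniform.
#' @param code a \linkS4class{GeneticCode}, default table 5.
#' @return square generator matrix with codon dimnames.
#' @export
codonRateMatrix <- function(kappa, omega, freqs = NULL, code = geneticCode(5L)) {
  st <- .codonSteps(code)
  n <- length(st$sense)
  pi <- .checkFreqs(freqs, st$sense)
  Q <- matrix(0, n, n, dimnames = list(st$sense, st$sense))
  rate <- ifelse(st$ts, kappa, 1) * ifelse(st$syn, 1, omega)
  Q[cbind(st$i, st$j)] <- rate * pi[st$j]
  Q[cbind(st$j, st$i)] <- rate * pi[st$i]
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q / scale
}

.checkFreqs <- function(freqs, sense) {
  if (is.null(freqs)) freqs <- rep(1 / length(sense), length(sense))
  if (!is.null(names(freqs))) freqs <- freqs[sense]
  stopifnot(length(freqs) == length(sense), all(freqs > 0))
  unname(freqs / sum(freqs))
}

## Eigendecomposition of the reversible generator via symmetrization;
## transition probabilities P(t) then cost two matrix products.
.codonEigen <- function(kappa, omega, pi, code) {
  Q <- codonRateMatrix(kappa, omega, pi, code)
  sq <- sqrt(pi)
  B <- (sq * Q) %*% diag(1 / sq)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(U = (1 / sq) * e$vectors, tU = t(e$vectors * sq), lambda = e$values)
}

.probMatrix <- function(dec, t) {
  P <- (dec$U %*% (exp(dec$lambda * t) * dec$tU))
  P[P < 0] <- 0
  P
}

## Coerce a codon alignment (DNAStringSet, named character vector, or
## character matrix of codons) to an integer matrix taxa x sites of sense
## codon indices. Columns containing gaps/ambiguity are dropped
## alignment-wide (complete deletion); stop codons are an error.
.alnToCodonIndex <- function(aln, code) {
  sense <- senseCodons(code)
  if (methods::is(aln, "DNAStringSet"))
    aln <- stats::setNames(as.character(aln), names(aln))
  if (is.character(aln) && is.null(dim(aln))) {
    w <- unique(nchar(aln))
    if (length(w) != 1) stop("aligned sequences must have equal length")
    if (w %% 3 != 0) stop("alignment length must be a multiple of 3")
    codons <- t(vapply(aln, .splitCodons, character(w / 3)))
    rownames(codons) <- names(aln)
  } else codons <- aln
  codons <- toupper(codons)
  idx <- matrix(match(codons, sense), nrow = nrow(codons),
                dimnames = dimnames(codons))
  clean <- grepl("^[ACGT]{3}$", codons)
  isStop <- clean & codons %in% stopCodons(code)
  if (any(isStop))
    stop("stop codon in alignment column ",
         which(apply(matrix(isStop, nrow(codons)), 2, any))[1])
  keep <- colSums(matrix(!clean, nrow(codons))) == 0
  idx <- idx[, keep, drop = FALSE]
  if (!ncol(idx)) stop("no complete codon columns left after gap removal")
  idx
}

#' Log-likelihood of a codon alignment on a tree
#'
#' Felsenstein pruning over the codon chain: tip partials are indicators,
#' internal partials multiply child contributions propagated through
#' \eqn{P(t) = e^{Qt}}, and the root sums against the equilibrium codon
#' frequencies. Site patterns are aggregated, and partials are rescaled
#' per node to avoid underflow. The model is reversible, so the value does
#' not depend on root placement.
#'
#' @param aln codon alignment (\code{DNAStringSet} or named character
#'   vector of equal-length in-frame sequences).
#' @param tree \code{ape} \code{phylo}; tip labels must match the
#'   alignment names.
#' @param kappa transition/transversion ratio.
#' @param omega scalar or per-edge vector (in \code{tree$edge} order).
#' @param branchLengths per-edge lengths; default \code{tree$edge.length}.
#' @param freqs equilibrium codon frequencies (default uniform).
#' @param code genetic code, default table 5.
#' @return log-likelihood (numeric scalar).
#' @export
codonLogLik <- function(aln, tree, kappa, omega,
                        branchLengths = tree$edge.length,
                        freqs = NULL, code = geneticCode(5L)) {
  idx <- .alnToCodonIndex(aln, code)
  pi <- .checkFreqs(freqs, senseCodons(code))
  .codonLogLikIdx(idx, tree, kappa, omega, branchLengths, pi, code)
}

## Precompute everything about (alignment, tree) that does not depend on
## model parameters: site patterns with weights and the postorder edge
## traversal. Shared by every objective evaluation during a fit.
.prepLikData <- function(idx, tree) {
  idx <- idx[tree$tip.label, , drop = FALSE]
  key <- apply(idx, 2, paste, collapse = ",")
  uq <- !duplicated(key)
  w <- as.numeric(table(key)[key[uq]])
  tr <- stats::reorder(tree, "postorder")
  ord <- match(paste(tr$edge[, 1], tr$edge[, 2]),
               paste(tree$edge[, 1], tree$edge[, 2]))
  list(pat = idx[, uq, drop = FALSE], w = w, tr = tr, ord = ord,
       nTip = length(tree$tip.label))
}

.codonLogLikIdx <- function(idx, tree, kappa, omega, branchLengths, pi, code,
                            decCache = NULL, prep = NULL) {
  nEdge <- nrow(tree$edge)
  if (length(omega) == 1L) omega <- rep(omega, nEdge)
  stopifnot(length(omega) == nEdge, length(branchLengths) == nEdge)
  if (is.null(prep)) prep <- .prepLikData(idx, tree)
  pat <- prep$pat; w <- prep$w; tr <- prep$tr; ord <- prep$ord
  npat <- ncol(pat)
  nTip <- prep$nTip

  decFor <- function(om) {
    if (is.null(decCache)) return(.codonEigen(kappa, om, pi, code))
    k <- paste(format(kappa, digits = 15), format(om, digits = 15))
    if (is.null(decCache[[k]])) decCache[[k]] <- .codonEigen(kappa, om, pi, code)
    decCache[[k]]
  }

  partial <- vector("list", nTip + tr$Nnode)
  logScale <- rep(0, npat)
  for (k in seq_len(nrow(tr$edge))) {
    child <- tr$edge[k, 2]
    parent <- tr$edge[k, 1]
    P <- .probMatrix(decFor(omega[ord[k]]), branchLengths[ord[k]])
    contrib <- if (child <= nTip) {
      P[, pat[child, ], drop = FALSE]
    } else {
      P %*% partial[[child]]
    }
    if (is.null(partial[[parent]])) partial[[parent]] <- contrib
    else partial[[parent]] <- partial[[parent]] * contrib
    ## rescale the parent's partial when it is complete enough to shrink
    mx <- matrixStats_colMax(partial[[parent]])
    small <- mx < 1e-80
    if (any(small & mx > 0)) {
      sc <- ifelse(mx > 0, mx, 1)
      partial[[parent]] <- sweep(partial[[parent]], 2, sc, "/")
      logScale <- logScale + log(sc)
    }
  }
  root <- tr$edge[nrow(tr$edge), 1]
  siteL <- colSums(pi * partial[[root]])
  if (any(siteL <= 0) || any(!is.finite(siteL)))
    stop("non-finite site likelihood at pattern ",
         which(siteL <= 0 | !is.finite(siteL))[1])
  sum(w * (log(siteL) + logScale))
}

matrixStats_colMax <- function(m) apply(m, 2, max)

#' Empirical F3x4 codon frequencies
#'
#' Codon frequencies from the product of position-specific nucleotide
#' frequencies observed in the alignment, zeroed on stop codons and
#' renormalized over the sense codons.
#'
#' @inheritParams codonLogLik
#' @return named frequency vector over the sense codons.
#' @export
f3x4Frequencies <- function(aln, code = geneticCode(5L)) {
  idx <- .alnToCodonIndex(aln, code)
  sense <- senseCodons(code)
  codons <- sense[idx]
  m <- do.call(rbind, strsplit(codons, ""))
  pi <- rep(1, length(sense))
  for (p in 1:3) {
    fr <- table(factor(m[, p], levels = .NUC)) + 0.5  # small prior, no zeros
    fr <- fr / sum(fr)
    pi <- pi * as.numeric(fr[substr(sense, p, p)])
  }
  stats::setNames(pi / sum(pi), sense)
}

.resolveForeground <- function(tree, foreground) {
  if (is.null(foreground)) stop("two-ratios model needs a foreground branch")
  if (is.numeric(foreground)) return(as.integer(foreground))
  nodeId <- match(foreground, tree$tip.label)
  if (is.na(nodeId) && !is.null(tree$node.label))
    nodeId <- length(tree$tip.label) + match(foreground, tree$node.label)
  if (is.na(nodeId)) stop("foreground '", foreground, "' not found in tree")
  e <- which(tree$edge[, 2] == nodeId)
  if (!length(e)) stop("foreground node has no parent edge (is it the root?)")
  e
}

#' Fit a branch model of codon evolution
#'
#' Maximizes the codon-model likelihood over kappa, branch lengths, and
#' either one omega for the whole tree (\code{one_ratio}), one foreground
#' plus one background omega (\code{two_ratios}), or one omega per branch
#' (\code{free_ratios}). Trees are treated as unrooted (rooted input is
#' unrooted first); optimization is bounded quasi-Newton on log-scale
#' parameters with seeded random restarts.
#'
#' @inheritParams codonLogLik
#' @param variant \code{"one_ratio"}, \code{"two_ratios"} or
#'   \code{"free_ratios"}.
#' @param foreground for \code{two_ratios}: a tip/node label or edge index
#'   identifying the foreground branch.
#' @param freqs \code{"F3x4"} (default: empirical position-specific
#'   frequencies), \code{"uniform"}, or a numeric frequency vector.
#' @param nStarts number of optimizer starts (first from neutral defaults,
#'   the rest jittered), default 3.
#' @param seed integer seed for the restart jitter.
#' @param maxOmega upper bound for omega estimates, default 999.
#' @return a \linkS4class{BranchModelFit}.
#' @examples
#' \donttest{
#' tr <- ape::read.tree(text = "((A:0.3,B:0.3):0.1,C:0.4,D:0.4);")
#' aln <- simulateCodonAlignment(tr, omega = 0.2, kappa = 2,
#'                               nCodons = 200, seed = 1)
#' fit <- fitBranchModel(aln, tr, "one_ratio", nStarts = 1)
#' omegaEstimates(fit)[1]
#' }
#' @export
fitBranchModel <- function(aln, tree,
                           variant = c("one_ratio", "two_ratios", "free_ratios"),
                           foreground = NULL, freqs = "F3x4",
                           code = geneticCode(5L), nStarts = 3L, seed = 1L,
                           maxOmega = 999) {
  variant <- match.arg(variant)
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  idx <- .alnToCodonIndex(aln, code)
  if (!all(tree$tip.label %in% rownames(idx)))
    stop("tree tips missing from alignment: ",
         paste(setdiff(tree$tip.label, rownames(idx)), collapse = ", "))
  pi <- if (is.numeric(freqs)) .checkFreqs(freqs, senseCodons(code))
  else if (freqs == "F3x4") unname(f3x4Frequencies(aln, code))
  else .checkFreqs(NULL, senseCodons(code))

  nEdge <- nrow(tree$edge)
  nOmega <- switch(variant, one_ratio = 1L, two_ratios = 2L, free_ratios = nEdge)
  fg <- if (variant == "two_ratios") .resolveForeground(tree, foreground) else NA_integer_
  omegaOf <- function(om) switch(variant,
    one_ratio = rep(om, nEdge),
    two_ratios = { v <- rep(om[1], nEdge); v[fg] <- om[2]; v },
    free_ratios = om)

  bl0 <- tree$edge.length
  if (is.null(bl0) || any(!is.finite(bl0)) ) bl0 <- rep(0.1, nEdge)
  bl0 <- pmax(bl0, 1e-4)
  start0 <- c(log(2), rep(log(0.5), nOmega), log(bl0))
  lower <- c(log(0.01), rep(log(1e-4), nOmega), rep(log(1e-7), nEdge))
  upper <- c(log(100), rep(log(maxOmega), nOmega), rep(log(50), nEdge))

  decCache <- new.env(parent = emptyenv())
  prep <- .prepLikData(idx, tree)
  obj <- function(theta) {
    kappa <- exp(theta[1])
    om <- exp(theta[2:(1 + nOmega)])
    bl <- exp(theta[-(1:(1 + nOmega))])
    ll <- tryCatch(
      .codonLogLikIdx(idx, tree, kappa, omegaOf(om), bl, pi, code, decCache,
                      prep = prep),
      error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  best <- NULL
  starts <- list(start0)
  if (nStarts > 1) {
    jit <- .withSeed(seed, lapply(seq_len(nStarts - 1L), function(k)
      start0 + stats::rnorm(length(start0), 0, 0.5)))
    starts <- c(starts, jit)
  }
  for (st in starts) {
    fit <- stats::nlminb(st, obj, lower = lower, upper = upper,
                         control = list(rel.tol = 1e-10, iter.max = 500,
                                        eval.max = 2000))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  theta <- best$par
  kappa <- exp(theta[1])
  om <- exp(theta[2:(1 + nOmega)])
  bl <- exp(theta[-(1:(1 + nOmega))])
  np <- 1L + nOmega + nEdge
  new("BranchModelFit", variant = variant, logLik = -best$objective,
      kappa = kappa, omega = omegaOf(om), branchLengths = bl, tree = tree,
      foreground = fg, nParams = np,
      converged = best$convergence == 0, freqs = pi)
}

#' Likelihood-ratio test between nested branch models
#'
#' The statistic is twice the log-likelihood difference, compared against a
#' chi-square with as many degrees of freedom as the difference in free
#' parameters; at df = 1 and the 5\% level this is the familiar 3.84
#' cutoff. A slightly negative statistic (within numerical tolerance) is
#' clamped to zero; a substantially negative one signals an optimization
#' failure and raises a warning advising a re-fit.
#'
#' @param nullFit,altFit \linkS4class{BranchModelFit}s, null nested in alt.
#' @param alpha significance level, default 0.05.
#' @param tolerance clamping tolerance for negative statistics.
#' @return data.frame with \code{statistic}, \code{df}, \code{p},
#'   \code{significant}.
#' @export
likelihoodRatioTest <- function(nullFit, altFit, alpha = 0.05,
                                tolerance = 1e-4) {
  stat <- 2 * (altFit@logLik - nullFit@logLik)
  df <- altFit@nParams - nullFit@nParams
  if (df < 1) stop("alternative model must have more parameters than the null")
  if (stat < -tolerance)
    warning("negative LRT statistic (", format(stat),
            "): optimization likely not converged, re-fit advised")
  stat <- max(stat, 0)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  data.frame(statistic = stat, df = df, p = p, significant = p < alpha)
}

#' Protein divergence of a focal taxon
#'
#' The proportion of aligned amino-acid sites at which the focal sequence
#' differs from at least one of the other sequences.
#'
#' @param alignedProteins named character vector of aligned amino-acid
#'   sequences of equal length (or an \code{AAStringSet}).
#' @param focal name of the focal taxon.
#' @param countGaps should sites where a compared residue is a gap count
#'   as differences? Default \code{FALSE} (gap sites are ignored for that
#'   comparison).
#' @return list with \code{n_diff}, \code{length}, \code{proportion}.
#' @examples
#' proteinDivergence(c(a = "MKV", b = "MKV", c = "MRV", d = "MKV"), "a")
#' @export
proteinDivergence <- function(alignedProteins, focal, countGaps = FALSE) {
  if (methods::is(alignedProteins, "AAStringSet"))
    alignedProteins <- stats::setNames(as.character(alignedProteins),
                                       names(alignedProteins))
  if (!focal %in% names(alignedProteins)) stop("focal taxon not in alignment")
  w <- unique(nchar(alignedProteins))
  if (length(w) != 1) stop("aligned proteins must have equal length")
  m <- do.call(rbind, strsplit(alignedProteins, ""))
  rownames(m) <- names(alignedProteins)
  fm <- m[focal, ]
  others <- m[setdiff(rownames(m), focal), , drop = FALSE]
  diffAny <- vapply(seq_len(w), function(s) {
    o <- others[, s]
    if (!countGaps) {
      keep <- o != "-" & fm[s] != "-"
      o <- o[keep]
    }
    any(o != fm[s])
  }, logical(1))
  list(n_diff = sum(diffAny), length = w, proportion = sum(diffAny) / w)
}

#' Pairwise dN/dS by the Nei-Gojobori counting method
#'
#' Counting-method estimate of synonymous and non-synonymous divergence
#' between two in-frame sequences: synonymous site counts average the
#' fraction of single-nucleotide changes at each codon position that
#' preserve the amino acid (changes to stop codons count as
#' non-synonymous); differences between codons differing at several
#' positions are averaged over all mutational pathways that avoid stop
#' codons; proportions are Jukes-Cantor corrected. Serves as an
#' independent sanity check on the maximum-likelihood branch fits.
#'
#' @param seqA,seqB equal-length in-frame nucleotide sequences.
#' @param code genetic code, default table 5.
#' @return list with \code{dN}, \code{dS}, \code{omega} (\code{NA} when
#'   \code{dS} is 0), and the underlying site/difference counts \code{N},
#'   \code{S}, \code{Nd}, \code{Sd}.
#' @export
ng86 <- function(seqA, seqB, code = geneticCode(5L)) {
  seqA <- toupper(seqA); seqB <- toupper(seqB)
  if (nchar(seqA) != nchar(seqB)) stop("sequences must have equal length")
  if (nchar(seqA) %% 3 != 0) stop("sequence length must be a multiple of 3")
  ca <- .splitCodons(seqA); cb <- .splitCodons(seqB)
  drop <- .translateCodon(ca, code) == "*" | .translateCodon(cb, code) == "*" |
    !grepl("^[ACGT]{3}$", ca) | !grepl("^[ACGT]{3}$", cb)
  ## trailing stop codons (and any ambiguous codon) are excluded
  ca <- ca[!drop]; cb <- cb[!drop]
  synSites <- function(codon) {
    aa <- .translateCodon(codon, code)
    s <- 0
    for (p in 1:3) for (b in setdiff(.NUC, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      if (.translateCodon(mut, code) == aa) s <- s + 1 / 3
    }
    s
  }
  pathDiffs <- function(a, b) {
    dpos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    if (!length(dpos)) return(c(0, 0))
    paths <- .permutations(dpos)
    acc <- matrix(0, 0, 2)
    for (ord in paths) {
      cur <- a; sd <- nd <- 0; ok <- TRUE
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(b, p, p)
        if (.translateCodon(nxt, code) == "*") { ok <- FALSE; break }
        if (.translateCodon(nxt, code) == .translateCodon(cur, code))
          sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) acc <- rbind(acc, c(sd, nd))
    }
    if (!nrow(acc)) return(c(0, length(dpos)))  # all paths cross stops
    colMeans(acc)
  }
  S <- sum(vapply(ca, synSites, numeric(1)) +
             vapply(cb, synSites, numeric(1))) / 2
  N <- 3 * length(ca) - S
  d <- rowSums(vapply(seq_along(ca), function(i) pathDiffs(ca[i], cb[i]),
                      numeric(2)))
  Sd <- d[1]; Nd <- d[2]
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  dS <- if (S > 0) jc(Sd / S) else NA_real_
  dN <- if (N > 0) jc(Nd / N) else NA_real_
  omega <- if (!is.na(dS) && dS > 0 && !is.na(dN)) dN / dS else NA_real_
  list(dN = dN, dS = dS, omega = omega, N = N, S = S, Nd = Nd, Sd = Sd)
}

.permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in .permutations(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}
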