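#' Root-to-tip distances of a rooted tree
#'
#' The distance of each leaf from the root: the sum of branch lengths on
#' the root-to-leaf path.
#'
#' @param tree rooted \code{ape} \code{phylo} with branch lengths.
#' @return named numeric vector, one distance per tip.
#' @export
rootToTipDistances <- function(tree) {
  if (!ape::is.rooted(tree))
    stop("tree is unrooted: root it (e.g. on the outgroup) before the test")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  nTip <- length(tree$tip.label)
  d <- ape::node.depth.edgelength(tree)[seq_len(nTip)]
  stats::setNames(d, tree$tip.label)
}

## Per-pair design matrix over edges (root child edges merged: the two
## edges incident to the root are not separately identifiable from
## distances, so they enter as one column and the fitted length is split
## back in the proportion the input tree used).
.edgePaths <- function(tree) {
  nTip <- length(tree$tip.label)
  root <- nTip + 1L
  parent <- integer(max(tree$edge))
  parentEdge <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  parentEdge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  toRoot <- function(node) {
    e <- integer(0)
    while (node != root) {
      e <- c(e, parentEdge[node])
      node <- parent[node]
    }
    e
  }
  lapply(seq_len(nTip), toRoot)
}

.refitBranchLengths <- function(tree, dm) {
  nTip <- length(tree$tip.label)
  paths <- .edgePaths(tree)
  nEdge <- nrow(tree$edge)
  rootEdges <- which(tree$edge[, 1] == nTip + 1L)
  merged <- length(rootEdges) == 2L
  pairs <- utils::combn(nTip, 2)
  X <- matrix(0, ncol(pairs), nEdge)
  y <- numeric(ncol(pairs))
  dm <- as.matrix(dm)
  ord <- match(tree$tip.label, rownames(dm))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    e <- c(setdiff(paths[[i]], paths[[j]]), setdiff(paths[[j]], paths[[i]]))
    X[k, e] <- 1
    y[k] <- dm[ord[i], ord[j]]
  }
  if (merged) {
    X[, rootEdges[1]] <- X[, rootEdges[1]] + X[, rootEdges[2]]
    X <- X[, -rootEdges[2], drop = FALSE]
  }
  beta <- stats::lm.fit(X, y)$coefficients
  beta[is.na(beta)] <- 0
  beta <- pmax(beta, 0)
  bl <- numeric(nEdge)
  if (merged) {
    keep <- setdiff(seq_len(nEdge), rootEdges[2])
    bl[keep] <- beta
    tot <- tree$edge.length[rootEdges[1]] + tree$edge.length[rootEdges[2]]
    prop <- if (tot > 0) tree$edge.length[rootEdges[1]] / tot else 0.5
    both <- bl[rootEdges[1]]
    bl[rootEdges[1]] <- both * prop
    bl[rootEdges[2]] <- both * (1 - prop)
  } else bl <- beta
  bl
}

#' Branch length test for lineage rate acceleration
#'
#' For each taxon, the deviation \eqn{\delta_i = d_i - \bar d} of its
#' root-to-tip distance from the tree-wide mean; a taxon evolving faster
#' than average has \eqn{\delta > 0}. With an alignment supplied, the
#' standard error of each \eqn{\delta_i} comes from a nonparametric site
#' bootstrap: alignment columns are resampled, model-corrected pairwise
#' distances recomputed, branch lengths re-fitted by least squares on the
#' fixed topology, and the deviations re-read. The confidence probability
#' CP is \eqn{1 - p} from the two-sided normal tail of
#' \eqn{\delta/SE(\delta)}; taxa are flagged at the 5\% (CP >= 0.95) and
#' 1\% (CP >= 0.99) levels.
#'
#' @param tree rooted \code{phylo} with branch lengths (>= 3 taxa).
#' @param aln optional nucleotide alignment (\code{DNAStringSet}, named
#'   character vector, or character matrix) for the site bootstrap.
#' @param nBoot bootstrap replicates, default 1000 (a warning is issued
#'   below 50).
#' @param seed integer seed for the bootstrap.
#' @param se optional user-supplied per-taxon standard errors of delta
#'   (used when no alignment is available).
#' @param model distance model passed to \code{ape::dist.dna}, default
#'   \code{"TN93"}.
#' @return data.frame with columns \code{taxon}, \code{d}, \code{delta},
#'   \code{se}, \code{cp}, \code{sig5}, \code{sig1}. Without any SE
#'   source, \code{se}/\code{cp} are \code{NA} and no taxon is flagged.
#' @examples
#' tr <- makeClockTree(4, depth = 1, rateMultipliers = c(t4 = 2), seed = 1)
#' branchLengthTest(tr$tree)$delta  # -0.25 -0.25 -0.25 +0.75
#' @export
branchLengthTest <- function(tree, aln = NULL, nBoot = 1000L, seed = NULL,
                             se = NULL, model = "TN93") {
  d <- rootToTipDistances(tree)
  if (length(d) < 3) stop("the test needs at least 3 taxa")
  delta <- d - mean(d)
  seOut <- rep(NA_real_, length(d))
  if (!is.null(aln)) {
    if (nBoot < 50) warning("fewer than 50 bootstrap replicates: ",
                            "standard errors will be unstable")
    m <- .alnToCharMatrix(aln)
    m <- m[tree$tip.label, , drop = FALSE]
    nSites <- ncol(m)
    deltas <- .withSeed(seed, {
      vapply(seq_len(nBoot), function(b) {
        cols <- sample.int(nSites, nSites, replace = TRUE)
        dm <- ape::dist.dna(ape::as.DNAbin(m[, cols, drop = FALSE]),
                            model = model, pairwise.deletion = TRUE)
        if (any(!is.finite(dm))) return(rep(NA_real_, length(d)))
        bl <- .refitBranchLengths(tree, dm)
        tb <- tree
        tb$edge.length <- bl
        db <- rootToTipDistances(tb)
        db - mean(db)
      }, numeric(length(d)))
    })
    seOut <- apply(deltas, 1, stats::sd, na.rm = TRUE)
  } else if (!is.null(se)) {
    seOut <- if (!is.null(names(se))) se[names(d)] else se
  }
  z <- delta / seOut
  cp <- ifelse(is.na(z) | seOut == 0, NA_real_,
               1 - 2 * stats::pnorm(-abs(z)))
  data.frame(taxon = names(d), d = unname(d), delta = unname(delta),
             se = unname(seOut), cp = unname(cp),
             sig5 = !is.na(cp) & cp >= 0.95,
             sig1 = !is.na(cp) & cp >= 0.99,
             stringsAsFactors = FALSE)
}

.alnToCharMatrix <- function(aln) {
  if (methods::is(aln, "DNAStringSet"))
    aln <- stats::setNames(as.character(aln), names(aln))
  if (is.character(aln) && is.null(dim(aln))) {
    w <- unique(nchar(aln))
    if (length(w) != 1) stop("aligned sequences must have equal length")
    m <- do.call(rbind, strsplit(tolower(aln), ""))
    rownames(m) <- names(aln)
    m
  } else {
    rn <- rownames(aln)
    m <- tolower(aln)
    rownames(m) <- rn
    m
  }
}
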