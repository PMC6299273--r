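#' Canonicalize a circular signed gene order
#'
#' Rotates a circular order so the anchor gene comes first with positive
#' sign; if the anchor is on the minus strand the order is reflected
#' (reversed with all signs negated) first, which reads the same circular
#' genome from the other strand. Linear orders are only checked for the
#' anchor.
#'
#' @param order a \linkS4class{GeneOrder}.
#' @return canonicalized \code{GeneOrder} (idempotent).
#' @examples
#' o <- geneOrder(c("-A", "-C", "-B"), anchor = "A")
#' orderSymbols(canonicalizeOrder(o))  # +A +B +C
#' @export
canonicalizeOrder <- function(order) {
  a <- match(order@anchor, order@genes)
  if (is.na(a)) stop("anchor gene '", order@anchor, "' absent from order")
  if (!order@circular) return(order)
  g <- order@genes; s <- order@signs
  if (s[a] < 0) {
    g <- rev(g); s <- rev(-s)
    a <- match(order@anchor, g)
  }
  if (a > 1L) {
    rot <- c(a:length(g), seq_len(a - 1L))
    g <- g[rot]; s <- s[rot]
  }
  methods::initialize(order, genes = g, signs = s)
}

.checkSameGeneSet <- function(a, b) {
  d <- c(setdiff(a@genes, b@genes), setdiff(b@genes, a@genes))
  if (length(d))
    stop("gene sets differ between '", a@taxon, "' and '", b@taxon,
         "': ", paste(d, collapse = ", "))
}

## circular signed adjacency list of an order: rows (x, y) of signed genes
.signedAdjacencies <- function(order) {
  g <- order@genes; s <- order@signs
  n <- length(g)
  nxt <- c(2:n, 1L)
  if (!order@circular) nxt <- nxt[-n]
  cbind(x = paste0(ifelse(s < 0, "-", "+"), g)[seq_along(nxt)],
        y = paste0(ifelse(s[nxt] < 0, "-", "+"), g[nxt]))
}

.flipSym <- function(x) ifelse(startsWith(x, "-"), sub("^-", "+", x),
                               sub("^\\+", "-", x))

#' Breakpoint distance between two gene orders
#'
#' Counts adjacencies of the first (circular, signed) order that are absent
#' from the second: adjacency \eqn{(x, y)} is matched by \eqn{(x, y)} or by
#' its reading on the opposite strand, \eqn{(-y, -x)}. Identical orders
#' have 0 breakpoints; a reverse-complemented copy of the same circular
#' genome also has 0.
#'
#' @param a,b \linkS4class{GeneOrder}s over the same gene set.
#' @return integer breakpoint count (symmetric in the pair).
#' @export
breakpointCount <- function(a, b) {
  .checkSameGeneSet(a, b)
  adjA <- .signedAdjacencies(canonicalizeOrder(a))
  adjB <- .signedAdjacencies(canonicalizeOrder(b))
  keyB <- c(paste(adjB[, 1], adjB[, 2]),
            paste(.flipSym(adjB[, 2]), .flipSym(adjB[, 1])))
  sum(!(paste(adjA[, 1], adjA[, 2]) %in% keyB))
}

#' Common-interval count between two gene orders
#'
#' Counts gene subsets of size 2..n that appear as a contiguous block (any
#' internal arrangement, signs ignored) in both orders. Circular orders
#' are linearized at the shared anchor after canonicalization; the count
#' for identical orders of n genes is \eqn{n(n-1)/2}. Implemented with the
#' O(n^2) running min/max scan over windows of the first order.
#'
#' @inheritParams breakpointCount
#' @return integer count of common intervals.
#' @examples
#' a <- geneOrder(as.character(1:4), anchor = "1", circular = FALSE)
#' b <- geneOrder(c("1", "3", "2", "4"), anchor = "1", circular = FALSE)
#' commonIntervalsCount(a, b)  # 4
#' @export
commonIntervalsCount <- function(a, b) {
  .checkSameGeneSet(a, b)
  ga <- canonicalizeOrder(a)@genes
  gb <- canonicalizeOrder(b)@genes
  pos <- match(ga, gb)  # position in b of the gene at each position of a
  n <- length(pos)
  count <- 0L
  for (i in seq_len(n - 1L)) {
    mn <- mx <- pos[i]
    for (j in (i + 1L):n) {
      if (pos[j] < mn) mn <- pos[j]
      if (pos[j] > mx) mx <- pos[j]
      if (mx - mn == j - i) count <- count + 1L
    }
  }
  count
}

#' Pairwise gene-order distance matrices
#'
#' Full symmetric matrices of breakpoint and common-interval counts over a
#' list of gene orders, with an optional ranking against a designated
#' reference order (most similar first: fewest breakpoints, ties broken by
#' most common intervals).
#'
#' @param orders list of \linkS4class{GeneOrder}s over a common gene set.
#' @param reference taxon id of the reference order, or \code{NULL}.
#' @return list with matrices \code{breakpoints} and
#'   \code{common_intervals}, and (when a reference is named) a
#'   \code{ranking} data.frame.
#' @export
pairwiseOrderMatrix <- function(orders, reference = NULL) {
  taxa <- vapply(orders, function(o) o@taxon, character(1))
  if (anyDuplicated(taxa)) stop("duplicate taxon ids among orders")
  n <- length(orders)
  bp <- ci <- matrix(0L, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    bp[i, j] <- bp[j, i] <- breakpointCount(orders[[i]], orders[[j]])
    ci[i, j] <- ci[j, i] <- commonIntervalsCount(orders[[i]], orders[[j]])
  }
  nGenes <- length(orders[[1]]@genes)
  diag(ci) <- as.integer(nGenes * (nGenes - 1) / 2)
  out <- list(breakpoints = bp, common_intervals = ci)
  if (!is.null(reference)) {
    if (!reference %in% taxa) stop("reference taxon not among orders")
    others <- setdiff(taxa, reference)
    rk <- data.frame(taxon = others,
                     breakpoints = bp[reference, others],
                     common_intervals = ci[reference, others])
    rk <- rk[order(rk$breakpoints, -rk$common_intervals), ]
    rownames(rk) <- NULL
    out$ranking <- rk
  }
  out
}

#' Read gene orders from a plain-text file
#'
#' One taxon per line: a taxon id followed by tab- or space-separated
#' signed gene symbols (\code{+cox1 -trnM ...}; bare symbols are plus).
#'
#' @param path input file.
#' @param circular are the orders circular? Default \code{TRUE}.
#' @param anchor canonicalization anchor, default \code{"cox1"}.
#' @return named list of \linkS4class{GeneOrder}s.
#' @export
readGeneOrders <- function(path, circular = TRUE, anchor = "cox1") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- lapply(lines, function(ln) {
    tok <- strsplit(trimws(ln), "[\t ]+")[[1]]
    geneOrder(tok[-1], taxon = tok[1], circular = circular, anchor = anchor)
  })
  stats::setNames(out, vapply(out, function(o) o@taxon, character(1)))
}
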