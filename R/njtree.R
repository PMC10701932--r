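#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining: the pair minimizing the Q criterion is
#' joined iteratively, branch lengths follow the standard two-point
#' formula, the final three nodes are resolved by the three-point closed
#' form (so the result is unrooted with a trifurcating root, as usual).
#' Negative branch lengths are clamped to 0. Ties in Q are broken
#' deterministically in favour of the smallest (i, j) pair in the current
#' node order.
#'
#' @param d square symmetric numeric matrix with zero diagonal (n >= 3),
#'   or a `dist` object.
#' @param labels taxon labels; defaults to `rownames(d)`.
#' @return an `ape::phylo` tree.
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'   dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' njTree(d)
#' @export
njTree <- function(d, labels = NULL) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("d must be a square matrix", call. = FALSE)
  }
  n <- nrow(d)
  if (n < 3) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-9) {
    stop("distance matrix is asymmetric beyond tolerance 1e-9", call. = FALSE)
  }
  if (is.null(labels)) labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))

  fmt <- function(x) sprintf("%.10g", max(0, x))   # clamp negatives
  frag <- as.list(labels)
  D <- d
  while (nrow(D) > 3) {
    r <- nrow(D)
    R <- rowSums(D)
    best <- c(NA, NA); bestQ <- Inf
    for (i in seq_len(r - 1)) {
      for (j in seq(i + 1, r)) {
        q <- (r - 2) * D[i, j] - R[i] - R[j]
        if (q < bestQ - 1e-12) {
          bestQ <- q
          best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    newfrag <- paste0("(", frag[[i]], ":", fmt(li), ",",
                      frag[[j]], ":", fmt(lj), ")")
    keep <- setdiff(seq_len(r), c(i, j))
    dnew <- (D[i, keep] + D[j, keep] - D[i, j]) / 2
    D2 <- matrix(0, r - 1, r - 1)
    D2[seq_along(keep), seq_along(keep)] <- D[keep, keep, drop = FALSE]
    D2[r - 1, seq_along(keep)] <- dnew
    D2[seq_along(keep), r - 1] <- dnew
    D <- D2
    frag <- c(frag[keep], newfrag)
  }
  # resolve the last three nodes by the closed form
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- paste0("(", frag[[1]], ":", fmt(la), ",", frag[[2]], ":", fmt(lb),
                ",", frag[[3]], ":", fmt(lc), ");")
  ape::read.tree(text = nwk)
}

# connected components over a set of edges (union-find)
components_from_edges <- function(nNodes, edges) {
  parent <- seq_len(nNodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1]); b <- find(edges[k, 2])
      if (a != b) parent[b] <- a
    }
  }
  vapply(seq_len(nNodes), find, integer(1))
}

#' Group sequences by cutting long branches of their NJ tree
#'
#' Pairwise distances are p-distances derived from global-alignment percent
#' identity, `(100 - identity) / 100`. A neighbor-joining tree is built and
#' every branch longer than `cut` is removed; the connected leaf sets that
#' remain are the groups. The default cut of 0.03 mirrors the 97% sequence
#' identity convention used to color corresponding repeat units. Group
#' labels are integers in order of first appearance of their members.
#'
#' @param seqs named sequences (ignored when `identity` is given).
#' @param identity optional precomputed percent-identity matrix.
#' @param cut branch-length cut in p-distance units (default 0.03).
#' @param scoring an [alignScoring()] scheme used when aligning `seqs`.
#' @param distances optional function mapping an identity matrix to a
#'   distance matrix, exposed so that other distance models can be plugged
#'   in; the default is the p-distance above.
#' @return named integer vector of group labels.
#' @export
groupUnits <- function(seqs = NULL, identity = NULL, cut = 0.03,
                       scoring = alignScoring(),
                       distances = function(idm) (100 - idm) / 100) {
  if (is.null(identity)) {
    if (is.null(seqs)) stop("provide seqs or identity", call. = FALSE)
    if (length(seqs) == 1) return(setNames(1L, names(seqs)))
    identity <- identityMatrix(seqs, scoring, digits = Inf)
  }
  n <- nrow(identity)
  labs <- rownames(identity)
  if (n == 1) return(setNames(1L, labs))
  D <- distances(identity)
  diag(D) <- 0
  if (n == 2) {
    g <- if (D[1, 2] <= cut) c(1L, 1L) else c(1L, 2L)
    return(setNames(g, labs))
  }
  tree <- njTree(D, labels = labs)
  keep <- tree$edge[tree$edge.length <= cut, , drop = FALSE]
  nNodes <- n + tree$Nnode
  comp <- components_from_edges(nNodes, keep)
  leaf_comp <- comp[seq_len(n)]
  # renumber in order of first appearance, in input (identity row) order
  ord <- match(labs, tree$tip.label)
  grp <- leaf_comp[ord]
  setNames(as.integer(factor(grp, levels = unique(grp))), labs)
}
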