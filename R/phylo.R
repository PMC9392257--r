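#' Pairwise distance matrix from fitted pair trees
#'
#' Under the two-cell model, `t2 + t3` — the summed branch lengths from the
#' divergence point to each cell — measures the evolutionary distance
#' between the two cells. This assembles the symmetric matrix of those
#' distances. Every unordered pair must be present: a neighbour-restricted
#' pair set cannot produce a complete matrix.
#'
#' @param pair_fits named list of `cn_pair_fit`s keyed `"A|B"` covering all
#'   pairs of the cell set.
#' @return Symmetric numeric matrix with zero diagonal and cell-id
#'   dimnames.
#' @export
t2t3_matrix <- function(pair_fits) {
  ids <- sort(unique(unlist(lapply(pair_fits, `[[`, "cells"))))
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    key <- paste(ids[i], ids[j], sep = "|")
    pf <- pair_fits[[key]]
    if (is.null(pf))
      stop("missing pair fit for (", ids[i], ", ", ids[j],
           "): all pairs are required for a distance matrix")
    D[i, j] <- D[j, i] <- pf$tree$t2 + pf$tree$t3
  }
  D
}

#' Euclidean distance matrix between copy-number profiles
#'
#' @param cnps named list of [cn_profile]s on one grid.
#' @return Symmetric numeric matrix of Euclidean distances.
#' @export
euclidean_matrix <- function(cnps) {
  ids <- names(cnps)
  w <- cnps[[1L]]$windows
  for (p in cnps[-1L]) assert_same_grid(w, p$windows)
  X <- do.call(rbind, lapply(cnps, `[[`, "cn"))
  D <- as.matrix(stats::dist(X))
  dimnames(D) <- list(ids, ids)
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic agglomerative neighbor-joining (via [ape::nj]); negative branch
#' lengths occasionally produced on non-additive matrices are clamped to 0
#' with a warning.
#'
#' @param D symmetric distance matrix with dimnames, n >= 3.
#' @return An unrooted [ape::phylo] tree with branch lengths.
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D))
  if (nrow(D) < 3L) stop("neighbor-joining needs at least 3 taxa")
  tr <- ape::nj(stats::as.dist(D))
  if (any(tr$edge.length < 0)) {
    warning("negative branch lengths clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Robinson-Foulds distance between two trees
#'
#' Unweighted Robinson-Foulds distance: the size of the symmetric
#' difference of the sets of non-trivial bipartitions. Rooted inputs are
#' unrooted first; both trees must share the same leaf set.
#'
#' @param T1,T2 [ape::phylo] trees on the same leaves.
#' @return Non-negative integer.
#' @export
robinson_foulds <- function(T1, T2) {
  stopifnot(inherits(T1, "phylo"), inherits(T2, "phylo"))
  if (!setequal(T1$tip.label, T2$tip.label))
    stop("trees have different leaf sets")
  u1 <- ape::unroot(T1)
  u2 <- ape::unroot(T2)
  as.integer(phangorn::RF.dist(u1, u2, check.labels = TRUE))
}

#' Prune a tree to a subset of leaves
#'
#' Restricts a (true, simulated) tree to the sampled cell subset before
#' comparison with an inferred tree.
#'
#' @param tree an [ape::phylo].
#' @param keep character vector of leaf labels to keep.
#' @return The pruned [ape::phylo].
#' @export
prune_tree <- function(tree, keep) {
  ape::keep.tip(tree, keep)
}
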