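# Matrix representations of a phylogeny used downstream: patristic distances,
# Brownian covariance, Abouheif proximity, PCoA eigenbasis, node ages/sizes.

#' Patristic distance matrix
#'
#' Tip-to-tip path lengths (sum of branch lengths along the connecting path),
#' in the tree's tip order.
#'
#' @param tree A validated `phylo` object with >= 2 tips.
#' @return A symmetric zero-diagonal matrix with tip labels as dimnames.
#' @export
patristic_matrix <- function(tree) {
  validate_tree(tree)
  if (ape::Ntip(tree) < 2) stop_pvr("need >= 2 tips")
  d <- cophenetic(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Brownian-motion covariance matrix
#'
#' `V[i, j]` is the root-to-MRCA path length of tips i and j (their shared
#' evolutionary time under Brownian motion); the diagonal holds root-to-tip
#' depths.
#'
#' @inheritParams patristic_matrix
#' @return A symmetric positive semidefinite matrix in tip order.
#' @export
bm_covariance <- function(tree) {
  validate_tree(tree)
  if (ape::Ntip(tree) < 2) stop_pvr("need >= 2 tips")
  v <- ape::vcv.phylo(tree)
  v[tree$tip.label, tree$tip.label]
}

## Ancestor chain of every tip, from its parent up to the root.
tip_ancestor_paths <- function(tree) {
  n <- ape::Ntip(tree)
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- n + 1L
  lapply(seq_len(n), function(i) {
    path <- integer(0)
    node <- parent[i]
    while (node != 0L) {
      path <- c(path, node)
      node <- if (node == root) 0L else parent[node]
    }
    path
  })
}

#' Abouheif phylogenetic proximity matrix
#'
#' `A[i, j]` is the product, over the internal nodes on the path between tips
#' i and j (the MRCA included, plus every internal node strictly between the
#' MRCA and each tip), of 1 / (number of direct descendants of that node).
#' Polytomies contribute the actual daughter count (1/3 for a trichotomy).
#' This is the proximity underlying Abouheif's test for serial independence
#' of trait values among neighboring tips.
#'
#' @inheritParams patristic_matrix
#' @return A symmetric matrix with zero diagonal and entries in (0, 1].
#' @export
abouheif_proximity <- function(tree) {
  validate_tree(tree)
  n <- ape::Ntip(tree)
  if (n < 2) stop_pvr("need >= 2 tips")
  n_children <- tabulate(tree$edge[, 1], nbins = n + tree$Nnode)
  paths <- tip_ancestor_paths(tree)
  A <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    pi <- paths[[i]]
    for (j in seq(i + 1, n)) {
      pj <- paths[[j]]
      mrca <- pi[match(TRUE, pi %in% pj)]
      nodes <- c(pi[seq_len(match(mrca, pi))],             # up to and incl. MRCA
                 pj[seq_len(match(mrca, pj) - 1L)])        # strictly below MRCA
      A[i, j] <- A[j, i] <- prod(1 / n_children[nodes])
    }
  }
  A
}

#' Principal coordinate analysis of a distance matrix
#'
#' Gower double-centering `G = -1/2 J d^2 J` with `J = I - 11'/n`, followed by
#' an eigendecomposition. Axes with eigenvalue below `tol` times the largest
#' eigenvalue are discarded and counted (patristic matrices need not be
#' Euclidean-embeddable). Each retained axis is scaled so its squared norm
#' equals its eigenvalue, and flipped so its largest-magnitude entry is
#' positive, making outputs reproducible across linear-algebra backends.
#'
#' @param d A symmetric zero-diagonal distance matrix.
#' @param tol Relative eigenvalue tolerance (default 1e-10).
#' @return An object of class `phylo_pcoa`: list with `values` (positive
#'   eigenvalues, descending), `vectors` (tips x axes coordinate matrix),
#'   `tip_order`, `n_discarded`, and `trace` (of the centered matrix).
#' @export
phylo_pcoa <- function(d, tol = 1e-10) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop_pvr("distance matrix not symmetric")
  if (any(abs(diag(d)) > 1e-8)) stop_pvr("distance matrix diagonal not zero")
  n <- nrow(d)
  b <- -0.5 * d^2
  g <- b - outer(rowMeans(b), rep(1, n)) - outer(rep(1, n), colMeans(b)) + mean(b)
  g <- (g + t(g)) / 2
  eig <- eigen(g, symmetric = TRUE)
  cutoff <- tol * max(eig$values, 0)
  keep <- which(eig$values > cutoff)
  if (!length(keep)) stop_pvr("degenerate distances: no positive eigenvalues")
  values <- eig$values[keep]
  vectors <- eig$vectors[, keep, drop = FALSE]
  vectors <- sweep(vectors, 2, sqrt(values), `*`)
  for (k in seq_along(values)) {
    imax <- which.max(abs(vectors[, k]))
    if (vectors[imax, k] < 0) vectors[, k] <- -vectors[, k]
  }
  tip_order <- rownames(d) %||% as.character(seq_len(n))
  rownames(vectors) <- tip_order
  colnames(vectors) <- paste0("V", seq_along(values))
  structure(
    list(values = values, vectors = vectors, tip_order = tip_order,
         n_discarded = n - length(keep), trace = sum(diag(g))),
    class = "phylo_pcoa"
  )
}

#' @export
print.phylo_pcoa <- function(x, ...) {
  cat(sprintf("PCoA basis: %d axes (%d non-positive eigenvalues discarded)\n",
              length(x$values), x$n_discarded))
  cat(sprintf("  leading eigenvalues: %s\n",
              paste(signif(head(x$values, 5), 4), collapse = ", ")))
  invisible(x)
}

#' Node ages and descendant tip counts
#'
#' The age of a node is the maximum path length from the node to any of its
#' descendant tips (on an ultrametric tree all descendants agree); tips have
#' age 0. Tip counts give the number of descendant tips per node. The maximum
#' disagreement of root-to-tip depths is reported as the ultrametricity
#' deviation.
#'
#' @inheritParams patristic_matrix
#' @return A data frame with one row per node (tips first, then internals):
#'   `node`, `age`, `tip_count`, plus attribute `ultrametric_deviation`.
#' @export
node_ages_sizes <- function(tree) {
  validate_tree(tree)
  n <- ape::Ntip(tree)
  m <- n + tree$Nnode
  age <- numeric(m)
  count <- integer(m)
  count[seq_len(n)] <- 1L
  ## post-order over edges: children before parents
  eo <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1]; ch <- eo$edge[k, 2]; len <- eo$edge.length[k]
    age[p] <- max(age[p], age[ch] + len)
    count[p] <- count[p] + count[ch]
  }
  depth <- ape::node.depth.edgelength(tree)[seq_len(n)]
  out <- data.frame(node = seq_len(m), age = age, tip_count = count)
  attr(out, "ultrametric_deviation") <- diff(range(depth))
  out
}
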