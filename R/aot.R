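# Analysis-of-traits node statistics: recursive node means, divergence sizes,
# contribution indices to tree-wide trait variation, and permutation tests.

## Children of every internal node, as a list indexed by node number.
node_children <- function(tree) {
  n <- ape::Ntip(tree)
  ch <- vector("list", n + tree$Nnode)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]
    ch[[p]] <- c(ch[[p]], tree$edge[k, 2])
  }
  ch
}

#' Recursive (AOT-style) node means
#'
#' Tip means equal the tip values; an internal node's mean is the unweighted
#' arithmetic mean of its direct daughters' means, each daughter counting
#' once regardless of how many tips it spans. This recursive averaging is the
#' analysis-of-traits convention that removes sampling-imbalance bias. A
#' tip-count-weighted variant is available for sensitivity analysis.
#'
#' @param tree A validated `phylo` object.
#' @param x Trait vector aligned to `tree$tip.label` (names checked when
#'   present).
#' @param weighted Use tip-count-weighted daughter means instead of the
#'   unweighted convention.
#' @return Numeric vector of node means over all nodes (tips first, then
#'   internal nodes, in ape numbering).
#' @export
aot_node_means <- function(tree, x, weighted = FALSE) {
  n <- ape::Ntip(tree)
  x <- align_trait(tree, x)
  m <- n + tree$Nnode
  means <- numeric(m)
  means[seq_len(n)] <- x
  wts <- numeric(m)
  wts[seq_len(n)] <- 1
  eo <- ape::reorder.phylo(tree, "postorder")
  ch <- node_children(tree)
  for (node in unique(eo$edge[, 1])) {
    kids <- ch[[node]]
    if (weighted) {
      wk <- wts[kids]
      means[node] <- sum(means[kids] * wk) / sum(wk)
      wts[node] <- sum(wk)
    } else {
      means[node] <- mean(means[kids])
    }
  }
  means
}

align_trait <- function(tree, x) {
  if (!is.null(names(x))) {
    if (!all(tree$tip.label %in% names(x))) {
      stop_pvr("trait vector names do not cover all tips")
    }
    x <- x[tree$tip.label]
  }
  if (length(x) != ape::Ntip(tree)) stop_pvr("trait vector does not match tips")
  as.numeric(x)
}

## Precomputed traversal structures reused across permutations.
aot_engine <- function(tree) {
  n <- ape::Ntip(tree)
  eo <- ape::reorder.phylo(tree, "postorder")
  list(n = n,
       order_nodes = unique(eo$edge[, 1]), # children before parents
       children = node_children(tree),
       n_internal = tree$Nnode)
}

engine_means <- function(engine, x) {
  means <- c(x, numeric(engine$n_internal))
  for (node in engine$order_nodes) {
    means[node] <- mean(means[engine$children[[node]]])
  }
  means
}

engine_d <- function(engine, x) {
  means <- engine_means(engine, x)
  vapply(engine$n + seq_len(engine$n_internal), function(node) {
    dm <- means[engine$children[[node]]]
    if (length(dm) == 2) abs(dm[1] - dm[2]) else sd(dm)
  }, numeric(1))
}

#' Divergence sizes at internal nodes
#'
#' For a bifurcating node, `D` is the absolute difference of the two daughter
#' means; at a true polytomy, `D` is the sample standard deviation of the
#' daughter means.
#'
#' @inheritParams aot_node_means
#' @param means Optional precomputed [aot_node_means()] vector.
#' @return Named numeric vector of `D` over internal nodes (ape numbering).
#' @export
divergence_size <- function(tree, x, means = NULL) {
  means <- means %||% aot_node_means(tree, x)
  n <- ape::Ntip(tree)
  ch <- node_children(tree)
  internal <- n + seq_len(tree$Nnode)
  d <- vapply(internal, function(node) {
    dm <- means[ch[[node]]]
    if (length(dm) == 2) abs(dm[1] - dm[2]) else sd(dm)
  }, numeric(1))
  names(d) <- internal
  d
}

#' Node contribution index to tree-wide trait variation
#'
#' For node k with daughters d1..dm, the divergence sum of squares is
#' `SS_k = sum_j (mean(d_j) - mean(k))^2`. The node's score is `n_k * SS_k`
#' (tip-count weighting, the default) or `SS_k` alone, and the contribution
#' index CI is each score divided by the total over all internal nodes, so
#' the CIs sum to 1.
#'
#' @inheritParams aot_node_means
#' @param weighting `"tips"` (default) or `"none"`.
#' @return Named numeric vector of CI over internal nodes (ape numbering).
#' @export
contribution_index <- function(tree, x, weighting = c("tips", "none")) {
  weighting <- match.arg(weighting)
  x <- align_trait(tree, x)
  if (var(x) == 0) stop_pvr("no tree-wide variation: trait is constant")
  w <- node_scores(tree, x, weighting)
  w / sum(w)
}

node_scores <- function(tree, x, weighting) {
  means <- aot_node_means(tree, x)
  n <- ape::Ntip(tree)
  ch <- node_children(tree)
  sizes <- node_ages_sizes(tree)$tip_count
  internal <- n + seq_len(tree$Nnode)
  w <- vapply(internal, function(node) {
    ss <- sum((means[ch[[node]]] - means[node])^2)
    if (weighting == "tips") sizes[node] * ss else ss
  }, numeric(1))
  names(w) <- internal
  w
}

#' Permutation p-values for divergence sizes
#'
#' Shuffles tip values across all tips `n_perm` times and reports, per
#' internal node, `p = (#{D_perm >= D_obs} + 1) / (n_perm + 1)` (one-sided,
#' greater).
#'
#' @inheritParams aot_node_means
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed.
#' @param nodes Optional subset of internal node numbers.
#' @return Named numeric vector of p-values over the requested nodes.
#' @export
divergence_pvalue <- function(tree, x, n_perm = 999, seed = 1, nodes = NULL) {
  if (n_perm < 99) stop_pvr("n_perm must be >= 99")
  x <- align_trait(tree, x)
  engine <- aot_engine(tree)
  internal <- engine$n + seq_len(engine$n_internal)
  sel <- if (is.null(nodes)) seq_along(internal) else match(as.integer(nodes), internal)
  d_obs <- engine_d(engine, x)[sel]
  exceed <- integer(length(d_obs))
  set.seed(seed)
  for (i in seq_len(n_perm)) {
    d_perm <- engine_d(engine, sample(x))[sel]
    exceed <- exceed + (d_perm >= d_obs)
  }
  p <- (exceed + 1) / (n_perm + 1)
  names(p) <- as.character(internal[sel])
  p
}

#' Ranked node-contribution report
#'
#' Per-node contribution indices, divergence sizes, permutation p-values,
#' descendant tip counts, node ages, and daughter-clade tip summaries, for
#' all internal nodes with CI above `ci_floor`, ranked by CI descending.
#'
#' @inheritParams contribution_index
#' @inheritParams divergence_pvalue
#' @param ci_floor Report nodes with CI strictly greater than this
#'   (default 0.005; use 0 for all internal nodes).
#' @param max_label_tips Tips listed per daughter clade in the summary.
#' @return A data frame of class `aot_report` with columns `rank`, `node`,
#'   `ci`, `d`, `p`, `n`, `age`, `clades`.
#' @export
aot_report <- function(tree, x, n_perm = 999, seed = 1, ci_floor = 0.005,
                       weighting = c("tips", "none"), max_label_tips = 3) {
  weighting <- match.arg(weighting)
  x <- align_trait(tree, x)
  ci <- contribution_index(tree, x, weighting)
  d <- divergence_size(tree, x)
  p <- divergence_pvalue(tree, x, n_perm = n_perm, seed = seed)
  info <- node_ages_sizes(tree)
  n_tip <- ape::Ntip(tree)
  ch <- node_children(tree)

  keep <- which(ci > ci_floor)
  ord <- keep[order(ci[keep], decreasing = TRUE)]
  nodes <- as.integer(names(ci)[ord])

  clade_label <- function(node) {
    labs <- vapply(ch[[node]], function(k) {
      tips <- if (k <= n_tip) tree$tip.label[k] else {
        desc <- ape::extract.clade(tree, k)$tip.label
        extra <- length(desc) - max_label_tips
        paste0(paste(head(desc, max_label_tips), collapse = ","),
               if (extra > 0) sprintf(",+%d", extra))
      }
      tips
    }, character(1))
    paste(labs, collapse = " vs. ")
  }

  out <- data.frame(
    rank = seq_along(nodes),
    node = nodes,
    ci = as.numeric(ci[as.character(nodes)]),
    d = as.numeric(d[as.character(nodes)]),
    p = as.numeric(p[as.character(nodes)]),
    n = info$tip_count[nodes],
    age = info$age[nodes],
    clades = vapply(nodes, clade_label, character(1)),
    stringsAsFactors = FALSE
  )
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "weighting") <- weighting
  attr(out, "ci_floor") <- ci_floor
  class(out) <- c("aot_report", "data.frame")
  out
}

#' @export
print.aot_report <- function(x, ...) {
  cat(sprintf("Node contributions to tree-wide trait variation (CI > %g, %s weighting)\n",
              attr(x, "ci_floor"), attr(x, "weighting")))
  df <- data.frame(rank = x$rank, CI = signif(x$ci, 4), D = signif(x$d, 3),
                   p = x$p, n = x$n, age = round(x$age, 2),
                   clades = substr(x$clades, 1, 40))
  print(df, row.names = FALSE)
  invisible(x)
}
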