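test_that("recursive node means follow the unweighted daughter convention", {
  tr <- tree_text("((A:1,B:1):1,C:2);")
  m <- aot_node_means(tr, c(A = 1, B = 3, C = 10))
  n <- ape::Ntip(tr)
  ## internal nodes: root then (A,B)
  expect_equal(unname(m[n + 2]), 2)   # mean(A, B)
  expect_equal(unname(m[n + 1]), 6)   # mean(mean(AB), C), each daughter once

  expect_equal(unname(aot_node_means(tr, c(A = 7, B = 7, C = 7))),
               rep(7, 5)) # constant trait propagates

  ## oracle: independent recursive post-order computation on a bigger tree
  tr2 <- random_ultrametric(20, seed = 17)
  x <- setNames(rnorm(20), tr2$tip.label)
  oracle <- local({
    kids <- lapply(seq_len(20 + tr2$Nnode),
                   function(n) tr2$edge[tr2$edge[, 1] == n, 2])
    rec <- function(n) {
      if (n <= 20) return(x[[tr2$tip.label[n]]])
      mean(vapply(kids[[n]], rec, numeric(1)))
    }
    vapply(seq_len(20 + tr2$Nnode), rec, numeric(1))
  })
  expect_equal(unname(aot_node_means(tr2, x)), oracle, tolerance = 1e-12)
})

test_that("divergence size: absolute difference for pairs, SD for polytomies", {
  tr <- tree_text("((A:1,B:1):1,(C:1,D:1):1);")
  d <- divergence_size(tr, c(A = 2, B = 2, C = 10, D = 10))
  expect_equal(unname(d[1]), 8)           # root: |2 - 10|
  expect_equal(unname(d[2:3]), c(0, 0))

  t3 <- tree_text("(A:1,B:1,C:1);")
  expect_equal(unname(divergence_size(t3, c(A = 1, B = 2, C = 3))), 1) # sd
})

test_that("contribution index normalizes and matches brute force", {
  t2 <- tree_text("(A:1,B:1);")
  expect_equal(unname(contribution_index(t2, c(A = 0, B = 5))), 1)

  t4 <- tree_text("((A:1,B:1):1,(C:1,D:1):1);")
  x <- c(A = 0, B = 0, C = 1, D = 1)
  for (w in c("tips", "none")) {
    ci <- contribution_index(t4, x, weighting = w)
    expect_equal(unname(ci["5"]), 1)      # all variation at the root split
    expect_equal(unname(ci[c("6", "7")]), c(0, 0))
  }
  expect_error(contribution_index(t4, c(A = 1, B = 1, C = 1, D = 1)),
               "constant")

  ## brute-force oracle on an 8-tip tree, both weightings
  tr <- random_ultrametric(8, seed = 23)
  x <- setNames(rnorm(8), tr$tip.label)
  means <- aot_node_means(tr, x)
  sizes <- node_ages_sizes(tr)$tip_count
  internal <- 8 + seq_len(tr$Nnode)
  ss <- vapply(internal, function(nd) {
    kids <- tr$edge[tr$edge[, 1] == nd, 2]
    sum((means[kids] - means[nd])^2)
  }, numeric(1))
  expect_equal(unname(contribution_index(tr, x, "none")), ss / sum(ss),
               tolerance = 1e-12)
  wss <- sizes[internal] * ss
  expect_equal(unname(contribution_index(tr, x, "tips")), wss / sum(wss),
               tolerance = 1e-12)
  expect_equal(sum(contribution_index(tr, x)), 1, tolerance = 1e-12)
})

test_that("contribution index is invariant to affine trait transforms", {
  tr <- random_ultrametric(15, seed = 3)
  x <- setNames(rnorm(15), tr$tip.label)
  ci <- contribution_index(tr, x)
  expect_equal(contribution_index(tr, -2 * x + 7), ci, tolerance = 1e-10)
})

test_that("divergence p-values hit the floor for a dominant split", {
  tr <- simulate_tree(40, seed = 2, minor_clade_fraction = 0.5)
  x <- simulate_species_trait(tr, seed = 3, sigma2 = 1e-6,
                              clade_offsets = c(gymnosperm = 0, eudicot = 5))
  root <- ape::Ntip(tr) + 1L
  p <- divergence_pvalue(tr, x, n_perm = 999, seed = 7, nodes = root)
  expect_equal(unname(p), 0.001)
  p_all <- divergence_pvalue(tr, x, n_perm = 99, seed = 7)
  expect_true(all(p_all >= 1 / 100 & p_all <= 1))
})

test_that("aot report ranks the dominant divergence first", {
  tr <- simulate_tree(30, seed = 9, minor_clade_fraction = 0.3)
  x <- simulate_species_trait(tr, seed = 4,
                              clade_offsets = c(gymnosperm = -1, eudicot = 0))
  rep_all <- aot_report(tr, x, n_perm = 99, seed = 1, ci_floor = 0)
  expect_equal(nrow(rep_all), tr$Nnode) # one record per internal node
  expect_equal(rep_all$node[1], ape::Ntip(tr) + 1L) # root split dominates
  expect_equal(sum(rep_all$ci), 1, tolerance = 1e-8)
  expect_true(all(rep_all$n >= 2))
  expect_match(rep_all$clades[1], "vs\\.")

  rep_cut <- aot_report(tr, x, n_perm = 99, seed = 1, ci_floor = 0.005)
  expect_true(all(rep_cut$ci > 0.005))
  expect_lte(nrow(rep_cut), nrow(rep_all))
})

test_that("root CI grows to 1 along a clade-offset ladder", {
  tr <- simulate_tree(40, seed = 5, minor_clade_fraction = 0.5)
  base <- simulate_species_trait(tr, seed = 6, clade_offsets = c(gymnosperm = 0,
                                                                 eudicot = 0))
  root <- as.character(ape::Ntip(tr) + 1L)
  is_minor <- startsWith(tr$tip.label, "g")
  ci_root <- vapply(c(0.5, 1, 2, 4, 8), function(off) {
    x <- base + ifelse(is_minor, 0, off)
    unname(contribution_index(tr, x)[root])
  }, numeric(1))
  expect_true(all(diff(ci_root) > 0))
  expect_gt(ci_root[length(ci_root)], 0.99)
})
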