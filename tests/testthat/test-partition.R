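fake_pcoa <- function(values, n = 10, seed = 1) {
  set.seed(seed)
  v <- qr.Q(qr(matrix(rnorm(n * length(values)), n)))[, seq_along(values)]
  v <- sweep(v, 2, sqrt(values), `*`)
  rownames(v) <- paste0("t", seq_len(n))
  colnames(v) <- paste0("V", seq_along(values))
  structure(list(values = values, vectors = v, tip_order = rownames(v),
                 n_discarded = 0, trace = sum(values)),
            class = "phylo_pcoa")
}

test_that("eigenvector pool honors the cumulative-mass threshold", {
  b <- fake_pcoa(c(6, 3, 1))
  expect_equal(ncol(eigenvector_pool(b, 0.9)), 2)  # 9/10 of the mass
  expect_equal(ncol(eigenvector_pool(b, 1.0)), 3)  # all positive axes
  expect_equal(ncol(eigenvector_pool(b, n_axes = 1)), 1)
  ## oracle: independent cumulative-sum scan on a simulated tree
  tr <- random_ultrametric(50, seed = 13)
  p <- phylo_pcoa(patristic_matrix(tr))
  k <- ncol(eigenvector_pool(p, 0.95))
  expect_equal(k, which(cumsum(p$values) / sum(p$values) >= 0.95)[1])
})

test_that("candidate builder emits the right terms per subset", {
  d <- data.frame(matrix(rnorm(20 * 12), 20))
  names(d) <- c(default_climate_class(), default_soil_class())
  classes <- list(climate = default_climate_class(),
                  soil = default_soil_class(), quadratic = "map")
  axes <- matrix(rnorm(40), 20, dimnames = list(NULL, c("V1", "V2")))

  cc <- build_candidates(d, axes, classes, "C")
  expect_setequal(colnames(cc),
                  c("alpha", "map", "map^2", "mi", "mtcm", "mthm", "par"))
  ps <- build_candidates(d, axes, classes, "P")
  expect_equal(colnames(ps), c("V1", "V2")) # eigenvectors never squared
  cs <- build_candidates(d, axes, classes, c("C", "S"), interactions = TRUE)
  expect_equal(sum(grepl(":", colnames(cs))), 36) # 6 climate x 6 soil
  expect_false(any(grepl("V", colnames(cs))))
  pcs <- build_candidates(d, axes, classes, c("P", "C", "S"))
  expect_false(any(grepl(":", colnames(pcs)))) # plain variant: no products
})

test_that("forward AIC selects true predictors and resists noise", {
  ## exact match: single term, R2 = 1
  set.seed(2)
  X <- matrix(rnorm(100 * 3), 100, dimnames = list(NULL, c("a", "b", "c")))
  f <- forward_aic(X[, "b"], X)
  expect_equal(f$selected, "b")
  expect_equal(f$r2, 1, tolerance = 1e-12)

  ## one true signal among 10 decoys
  hits <- 0; false_sel <- 0
  for (s in 1:10) {
    set.seed(s)
    cand <- matrix(rnorm(200 * 11), 200,
                   dimnames = list(NULL, c("true", paste0("n", 1:10))))
    y <- cand[, "true"] + rnorm(200, 0, 0.1)
    f <- forward_aic(y, cand)
    hits <- hits + ("true" %in% f$selected)
    false_sel <- false_sel + length(setdiff(f$selected, "true"))
  }
  expect_equal(hits, 10)
  expect_lt(false_sel / (10 * 10), 0.3)

  ## all-noise: mostly intercept-only
  counts <- vapply(1:20, function(s) {
    set.seed(100 + s)
    cand <- matrix(rnorm(500 * 8), 500,
                   dimnames = list(NULL, paste0("n", 1:8)))
    length(forward_aic(rnorm(500), cand)$selected)
  }, numeric(1))
  expect_lt(mean(counts), 1.5)

  ## collinear duplicate is skipped, not double-selected
  cand <- cbind(a = X[, "a"], dup = X[, "a"], b = X[, "b"])
  expect_warning(f2 <- forward_aic(X[, "a"] + 0.5 * X[, "b"], cand),
                 "rank-deficient")
  expect_false(all(c("a", "dup") %in% f2$selected))
})

test_that("selected R2 never exceeds the full-candidate R2", {
  for (s in 1:5) {
    set.seed(s)
    cand <- matrix(rnorm(150 * 12), 150,
                   dimnames = list(NULL, paste0("v", 1:12)))
    y <- cand[, 1] * 0.5 + rnorm(150)
    f <- forward_aic(y, cand)
    expect_lte(f$r2, f$full_r2 + 1e-12)
  }
})

test_that("commonality matches constructed orthogonal and redundant designs", {
  ## orthogonal predictor blocks: no shared components
  set.seed(8)
  ## orthonormal columns, all orthogonal to the intercept too
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(120 * 6), 120))))[, -1]
  P <- Q[, 1:2]; C <- Q[, 3:4]; S <- Q[, 5:6]
  y <- P %*% c(1, 0.5) + C %*% c(0.8, 0) + S %*% c(0.5, 0.3) + rnorm(120, 0, 1)
  r2of <- function(X) summary(lm(y ~ X))$r.squared
  r2 <- c(P = r2of(P), C = r2of(C), S = r2of(S), PC = r2of(cbind(P, C)),
          PS = r2of(cbind(P, S)), CS = r2of(cbind(C, S)),
          PCS = r2of(cbind(P, C, S)))
  comp <- commonality(r2)
  expect_equal(unname(comp["U_P"]), unname(r2["P"]), tolerance = 1e-3)
  expect_lt(max(abs(comp[c("C_PC", "C_PS", "C_CS", "C_PCS")])), 1e-3)
  expect_equal(unname(sum(comp)), unname(r2["PCS"]), tolerance = 1e-12)

  ## duplicated block: all of C's contribution is shared with S
  r2dup <- r2
  r2dup["S"] <- r2["C"]; r2dup["CS"] <- r2["C"]
  r2dup["PS"] <- r2["PC"]; r2dup["PCS"] <- r2["PC"]
  cdup <- commonality(r2dup)
  expect_equal(unname(cdup["U_C"]), 0, tolerance = 1e-12)
  expect_equal(unname(cdup["U_S"]), 0, tolerance = 1e-12)
  expect_equal(unname(cdup["C_CS"] + cdup["C_PCS"]), unname(r2["C"]),
               tolerance = 1e-12)
})

test_that("intraspecific contribution handles edge and constructed cases", {
  ## one record per species: model R saturated, contribution exactly 0
  res <- rnorm(50)
  out <- intraspecific_contribution(res, paste0("sp", 1:50), r2_pcs = 0.6)
  expect_identical(out$value, 0)
  expect_identical(out$r2_r, 1)

  ## pure within-species noise: R2_R small, contribution ~ (1 - R2_PCS)
  set.seed(4)
  sp <- rep(paste0("sp", 1:100), each = 20)
  res <- rnorm(2000)
  res <- res - ave(res, sp) # exactly no between-species structure
  out <- intraspecific_contribution(res, sp, r2_pcs = 0.5)
  expect_lt(out$r2_r, 0.1)
  expect_lt(abs(out$value - 0.5), 0.1)
})

test_that("partition pipeline recovers structure on a small synthetic dataset", {
  ds <- small_dataset(seed = 21, n_species = 80, n_sites = 20)
  pp <- suppressWarnings(pvr_partition(ds))
  expect_equal(unname(sum(pp$components)), unname(pp$r2["PCS"]),
               tolerance = 1e-10)
  expect_true(all(pp$r2 >= 0 & pp$r2 <= 1))
  expect_equal(length(unique(vapply(pp$fits, `[[`, numeric(1), "n"))), 1)
  expect_equal(unname(pp$totals), unname(pp$r2[c("P", "C", "S")]))
  expect_true(pp$intraspecific >= 0 && pp$intraspecific <= 1)

  ## environment-free generation: climate and soil totals collapse
  null_totals <- vapply(1:4, function(s) {
    ds0 <- small_dataset(seed = 30 + s, n_species = 60, n_sites = 15,
                         betas = c(mtcm = 0), quad_betas = c(map = 0))
    p0 <- suppressWarnings(pvr_partition(ds0))
    max(p0$totals[c("C", "S")])
  }, numeric(1))
  expect_true(mean(null_totals < 0.05) >= 0.75)
})

test_that("interaction variant only augments the CS-containing models", {
  ds <- small_dataset(seed = 5, n_species = 50, n_sites = 12)
  plain <- suppressWarnings(pvr_partition(ds, variant = "plain"))
  inter <- suppressWarnings(pvr_partition(ds, variant = "interactions"))
  ## single-class totals are identical across variants by construction
  expect_equal(plain$totals, inter$totals, tolerance = 1e-10)
  expect_equal(plain$r2[c("PC", "PS")], inter$r2[c("PC", "PS")],
               tolerance = 1e-10)
})
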