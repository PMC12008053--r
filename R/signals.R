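# Phylogenetic signal statistics for a species-level trait vector: Moran's I,
# Abouheif's C_mean, Blomberg's K, and Pagel's lambda, each with a
# tip-permutation significance test.

#' Moran's I phylogenetic autocorrelation
#'
#' `I = (n / sum(w)) * (z' W z) / (z' z)` with `z = x - mean(x)`. The default
#' phylogenetic weights are the inverse patristic distances (`1/d[i, j]`,
#' zero diagonal), not row-standardized; set `row_standardize = TRUE` for the
#' row-normalized variant.
#'
#' @param x Numeric trait vector (one value per tip).
#' @param w Symmetric non-negative weight matrix with zero diagonal, in the
#'   same order as `x`.
#' @param row_standardize Divide each row of `w` by its sum before use.
#' @return The Moran's I statistic (scalar).
#' @export
moran_i <- function(x, w, row_standardize = FALSE) {
  x <- as.numeric(x)
  n <- length(x)
  if (nrow(w) != n || ncol(w) != n) stop_pvr("weight matrix does not match x")
  if (var(x) == 0) stop_pvr("degenerate trait: zero variance")
  if (row_standardize) w <- w / rowSums(w)
  s0 <- sum(w)
  if (s0 <= 0) stop_pvr("zero total weight")
  z <- x - mean(x)
  (n / s0) * as.numeric(t(z) %*% w %*% z) / sum(z^2)
}

#' Inverse-patristic-distance weights
#'
#' @param tree A validated `phylo` object.
#' @return `1/d` with zero diagonal, the default Moran's I weighting.
#' @export
inverse_distance_weights <- function(tree) {
  d <- patristic_matrix(tree)
  w <- 1 / d
  diag(w) <- 0
  w
}

#' Abouheif's C_mean
#'
#' The Moran-form autocorrelation statistic computed with the Abouheif
#' proximity matrix ([abouheif_proximity()]) as the weights; equivalent to
#' Abouheif's test for serial independence based on the sum of successive
#' squared trait differences between phylogenetically neighboring tips.
#'
#' @inheritParams moran_i
#' @param tree A validated `phylo` object (or pass a precomputed proximity
#'   via `proximity`).
#' @param proximity Optional precomputed Abouheif proximity matrix.
#' @return The C_mean statistic (scalar).
#' @export
abouheif_cmean <- function(x, tree = NULL, proximity = NULL) {
  A <- proximity %||% abouheif_proximity(tree)
  moran_i(x, A)
}

#' Blomberg's K
#'
#' The ratio of the observed mean squared error of tips around the
#' phylogenetically corrected mean (`MSE0`) to the phylogenetically corrected
#' mean squared error (`MSE`, computed through the inverse Brownian
#' covariance), standardized by its Brownian-motion expectation so that
#' K = 1 under Brownian evolution on the given tree:
#' `K = (MSE0 / MSE) / ((tr(V) - n / sum(V^-1)) / (n - 1))`.
#'
#' @param x Numeric trait vector (one value per tip).
#' @param V Brownian covariance matrix from [bm_covariance()], same order.
#' @return The K statistic (scalar).
#' @export
blomberg_k <- function(x, V) {
  x <- as.numeric(x)
  n <- length(x)
  if (var(x) == 0) stop_pvr("degenerate trait: zero variance")
  cache <- k_cache(V)
  k_from_cache(x, cache)
}

## Precompute the pieces of K that only depend on V, so permutation tests can
## reuse them across shuffles of x.
k_cache <- function(V) {
  V <- as.matrix(V)
  n <- nrow(V)
  ch <- tryCatch(chol(V), error = function(e) {
    stop_pvr("Brownian covariance is singular (duplicate tip depths?): ",
             conditionMessage(e))
  })
  Vinv <- chol2inv(ch)
  ones <- rep(1, n)
  s <- sum(Vinv)
  expected <- (sum(diag(V)) - n / s) / (n - 1)
  list(n = n, Vinv = Vinv, w1 = Vinv %*% ones / s, expected = expected)
}

k_from_cache <- function(x, cache) {
  a_hat <- sum(cache$w1 * x)
  r <- x - a_hat
  mse0 <- sum(r^2) / (cache$n - 1)
  mse <- as.numeric(t(r) %*% cache$Vinv %*% r) / (cache$n - 1)
  (mse0 / mse) / cache$expected
}

#' Pagel's lambda by maximum likelihood
#'
#' Multiplies the off-diagonal entries of the Brownian covariance by lambda
#' (diagonal unchanged) and maximizes the Gaussian log-likelihood, with the
#' ancestral mean and rate profiled out in closed form. Lambda is optimized on
#' `[0, lambda_max]` (`lambda_max = 1` on ultrametric trees) with a 21-point
#' grid scan followed by bounded Brent refinement, so local optima on flat
#' profiles are avoided.
#'
#' @inheritParams blomberg_k
#' @param lambda_max Upper bound of the search (default 1).
#' @param tol Convergence tolerance of the scalar optimizer.
#' @return A list with `lambda`, `loglik`, `sigma2`, `mu`, and the grid
#'   profile (`grid`, `grid_loglik`).
#' @export
pagel_lambda <- function(x, V, lambda_max = 1, tol = 1e-6) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4) stop_pvr("need >= 4 tips for lambda estimation")
  if (var(x) == 0) stop_pvr("degenerate trait: zero variance")
  V <- as.matrix(V)

  profile <- function(lambda) lambda_profile_loglik(x, V, lambda)
  grid <- seq(0, lambda_max, length.out = 21)
  gl <- vapply(grid, function(l) profile(l)$loglik, numeric(1))
  if (all(!is.finite(gl))) {
    stop_pvr("lambda profile not finite anywhere on the grid")
  }
  i0 <- which.max(gl)
  lo <- grid[max(1, i0 - 1)]
  hi <- grid[min(length(grid), i0 + 1)]
  opt <- optimize(function(l) profile(l)$loglik, interval = c(lo, hi),
                  maximum = TRUE, tol = tol)
  ## keep whichever of {grid best, refined} is better
  if (opt$objective >= gl[i0]) {
    lam <- opt$maximum; ll <- opt$objective
  } else {
    lam <- grid[i0]; ll <- gl[i0]
  }
  best <- profile(lam)
  structure(
    list(lambda = lam, loglik = ll, sigma2 = best$sigma2, mu = best$mu,
         grid = grid, grid_loglik = gl),
    class = "pagel_lambda"
  )
}

## Log-likelihood at a given lambda with mu and sigma2 profiled in closed form.
lambda_profile_loglik <- function(x, V, lambda) {
  n <- length(x)
  Vl <- V * lambda
  diag(Vl) <- diag(V)
  ch <- tryCatch(chol(Vl), error = function(e) NULL)
  if (is.null(ch)) return(list(loglik = -Inf, sigma2 = NA_real_, mu = NA_real_))
  logdet <- 2 * sum(log(diag(ch)))
  ones <- rep(1, n)
  z1 <- backsolve(ch, forwardsolve(t(ch), ones))
  zx <- backsolve(ch, forwardsolve(t(ch), x))
  mu <- sum(z1 * x) / sum(z1)
  r <- x - mu
  q <- as.numeric(t(r) %*% backsolve(ch, forwardsolve(t(ch), r)))
  sigma2 <- q / n
  if (sigma2 <= 0) return(list(loglik = -Inf, sigma2 = sigma2, mu = mu))
  ll <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  list(loglik = ll, sigma2 = sigma2, mu = mu)
}

#' @export
print.pagel_lambda <- function(x, ...) {
  cat(sprintf("Pagel's lambda: %.4f (log-likelihood %.3f)\n", x$lambda, x$loglik))
  invisible(x)
}

#' Tip-permutation test for a phylogenetic signal index
#'
#' Shuffles trait values across tips `n_perm` times and reports the one-sided
#' (greater) permutation p-value `p = (#{stat_perm >= stat_obs} + 1) /
#' (n_perm + 1)`. With the default 999 permutations the attainable floor is
#' p = 0.001.
#'
#' @param x Numeric trait vector aligned to the tree's tips.
#' @param tree A validated `phylo` object.
#' @param index One of `"moran"`, `"abouheif"`, `"K"`, `"lambda"`.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed for the shuffles.
#' @param row_standardize Passed to [moran_i()] for the Moran index.
#' @return An object of class `signal_result`: list with `index`, `value`,
#'   `p`, `n_perm`, `seed`.
#' @export
signal_test <- function(x, tree, index = c("moran", "abouheif", "K", "lambda"),
                        n_perm = 999, seed = 1, row_standardize = FALSE) {
  index <- match.arg(index)
  if (n_perm < 99) stop_pvr("n_perm must be >= 99")
  x <- as.numeric(x)
  n <- length(x)
  stat_fn <- switch(index,
    moran = {
      w <- inverse_distance_weights(tree)
      if (row_standardize) { w <- w / rowSums(w); }
      function(xx) moran_i(xx, w)
    },
    abouheif = {
      A <- abouheif_proximity(tree)
      function(xx) moran_i(xx, A)
    },
    K = {
      cache <- k_cache(bm_covariance(tree))
      function(xx) k_from_cache(xx, cache)
    },
    lambda = {
      V <- bm_covariance(tree)
      function(xx) pagel_lambda(xx, V)$lambda
    }
  )
  obs <- stat_fn(x)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) stat_fn(sample(x)), numeric(1))
  p <- (sum(perm >= obs) + 1) / (n_perm + 1)
  structure(
    list(index = index, value = obs, p = p, n_perm = n_perm, seed = seed),
    class = "signal_result"
  )
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("%-10s %8.4f  (p = %.3g, %d permutations)\n",
              x$index, x$value, x$p, x$n_perm))
  invisible(x)
}

#' All four phylogenetic signal indices with permutation tests
#'
#' Computes Moran's I (inverse-patristic-distance weights), Abouheif's
#' C_mean, Blomberg's K, and Pagel's lambda for the species-level trait of a
#' matched dataset, each with a tip-permutation p-value.
#'
#' @param dataset A `matched_dataset`, or alternatively supply `x` and `tree`.
#' @param x Optional species-level trait vector (overrides the dataset's).
#' @param tree Optional tree (required with `x`).
#' @param indices Which indices to compute.
#' @param n_perm Permutations per index.
#' @param seed Global seed; each index gets a deterministic sub-seed.
#' @param aggregate Aggregation from records to species (`"mean"`/`"median"`).
#' @return A data frame of class `phylo_signal` with columns `index`,
#'   `value`, `p`, `n_perm`, `seed`.
#' @export
phylo_signal <- function(dataset = NULL, x = NULL, tree = NULL,
                         indices = c("moran", "abouheif", "K", "lambda"),
                         n_perm = 999, seed = 1, aggregate = "mean") {
  if (is.null(x)) {
    stopifnot(inherits(dataset, "matched_dataset"))
    tree <- dataset$tree
    x <- species_trait(dataset, fun = aggregate)
  }
  rows <- lapply(seq_along(indices), function(i) {
    r <- signal_test(x, tree, index = indices[i], n_perm = n_perm,
                     seed = stage_seed(seed, i))
    data.frame(index = r$index, value = r$value, p = r$p,
               n_perm = r$n_perm, seed = r$seed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("phylo_signal", "data.frame")
  out
}

#' @export
print.phylo_signal <- function(x, ...) {
  cat("Phylogenetic signals\n")
  labels <- c(moran = "Moran's I", abouheif = "Abouheif's C_mean",
              K = "Blomberg's K", lambda = "Pagel's lambda")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-18s %8.4f   p = %.3g\n",
                labels[[x$index[i]]] %||% x$index[i], x$value[i], x$p[i]))
  }
  invisible(x)
}
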