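# Phylogenetic eigenvector regression partition: seven OLS models over the
# predictor classes {P, C, S}, forward-AIC parsimony, commonality analysis of
# R2, and the residual-based intraspecific contribution.

#' Leading eigenvector pool
#'
#' Smallest leading set of positive-eigenvalue PCoA axes whose eigenvalues
#' sum to at least `cum_threshold` of the total positive eigenvalue mass.
#'
#' @param basis A `phylo_pcoa` object.
#' @param cum_threshold Cumulative eigenvalue fraction in (0, 1]. The
#'   default 1 keeps every positive axis: forward-AIC selection, not
#'   eigenvalue mass, is the parsimony guard, because Brownian trait
#'   variance loads shallow axes that carry little distance mass.
#' @param n_axes Optional fixed axis count overriding the threshold.
#' @return The tips x axes coordinate matrix restricted to the pool.
#' @export
eigenvector_pool <- function(basis, cum_threshold = 1, n_axes = NULL) {
  stopifnot(inherits(basis, "phylo_pcoa"))
  if (!is.null(n_axes)) {
    k <- min(n_axes, length(basis$values))
  } else {
    if (cum_threshold <= 0 || cum_threshold > 1) stop_pvr("threshold must be in (0, 1]")
    cs <- cumsum(basis$values) / sum(basis$values)
    k <- match(TRUE, cs >= cum_threshold - 1e-12)
  }
  basis$vectors[, seq_len(k), drop = FALSE]
}

#' Candidate design matrix for one class subset
#'
#' Builds the named candidate columns for a subset of the classes P
#' (phylogenetic eigenvectors), C (climate), and S (soil): linear terms for
#' all subset members, squared terms (of centered variables) only for
#' variables flagged quadratic, and, in the interaction variant, all
#' climate x soil products of centered variables when the subset contains
#' both C and S. Eigenvectors are coordinates, not gradients: they are never
#' squared and never enter interactions. Columns are in canonical order --
#' eigenvectors by eigenvalue rank, then variables alphabetically (each
#' followed by its square), then interactions -- which also fixes the
#' deterministic tie-break of the forward selection.
#'
#' @param data Record-level data frame containing the class variables.
#' @param axes Record-level eigenvector matrix (species axes broadcast to
#'   records), used when `"P"` is in `subset`.
#' @param classes List with character vectors `climate` and `soil` and
#'   optional `quadratic` (variable names flagged quadratic).
#' @param subset Character subset of `c("P", "C", "S")`.
#' @param interactions Add climate x soil product terms (interaction
#'   variant).
#' @return A numeric matrix of candidate columns.
#' @export
build_candidates <- function(data, axes, classes, subset,
                             interactions = FALSE) {
  stopifnot(length(subset) >= 1, all(subset %in% c("P", "C", "S")))
  quad <- classes$quadratic %||% character(0)
  cols <- list()
  if ("P" %in% subset) {
    for (k in seq_len(ncol(axes))) cols[[colnames(axes)[k]]] <- axes[, k]
  }
  add_vars <- function(vars) {
    for (v in sort(vars)) {
      cols[[v]] <<- data[[v]]
      if (v %in% quad) {
        ctr <- data[[v]] - mean(data[[v]], na.rm = TRUE)
        cols[[paste0(v, "^2")]] <<- ctr^2
      }
    }
  }
  if ("C" %in% subset) add_vars(classes$climate)
  if ("S" %in% subset) add_vars(classes$soil)
  if (interactions && all(c("C", "S") %in% subset)) {
    for (cv in sort(classes$climate)) {
      cc <- data[[cv]] - mean(data[[cv]], na.rm = TRUE)
      for (sv in sort(classes$soil)) {
        sc <- data[[sv]] - mean(data[[sv]], na.rm = TRUE)
        cols[[paste0(cv, ":", sv)]] <- cc * sc
      }
    }
  }
  do.call(cbind, cols)
}

## Gaussian OLS AIC from a residual sum of squares (same convention as
## stats::AIC on an lm fit: parameters = coefficients + sigma).
ols_aic <- function(rss, n, n_coef) {
  n * (log(2 * pi) + log(rss / n) + 1) + 2 * (n_coef + 1)
}

#' Forward stepwise selection by AIC for ordinary least squares
#'
#' Starts from the intercept-only model; at each step adds the candidate with
#' the largest AIC decrease, stopping when no addition lowers AIC. Ties break
#' toward the earlier column in canonical order, so results are
#' bit-reproducible. Candidates whose addition leaves the design
#' rank-deficient are skipped with a warning.
#'
#' @param y Response vector.
#' @param candidates Numeric matrix of candidate columns (named).
#' @param subset Label of the class subset (stored with the fit).
#' @return An object of class `pvr_fit`: list with `subset`, `selected`
#'   (column names in selection order), `r2`, `aic`, `n`, `coefficients`,
#'   `residuals`, `full_r2` (R2 of the all-candidates fit).
#' @export
forward_aic <- function(y, candidates, subset = "") {
  n <- length(y)
  candidates <- as.matrix(candidates)
  if (nrow(candidates) != n) {
    stop_pvr("candidate matrix does not match response length")
  }
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) stop_pvr("degenerate response: zero variance")
  m <- ncol(candidates)

  ## Incremental Gram-Schmidt: keep the response residual r and the
  ## candidates residualized against the current design. For a fixed number
  ## of added terms, AIC is monotone in RSS, so the best addition is the
  ## candidate maximizing the RSS drop (c'r)^2 / (c'c); ties (within 1e-10)
  ## break toward the earlier column in canonical order.
  r <- y - mean(y)
  Cres <- sweep(candidates, 2, colMeans(candidates))
  norm0 <- colSums(Cres^2)
  alive <- norm0 > 1e-12 * max(norm0, 1)
  rss <- tss
  aic <- ols_aic(rss, n, 1)
  selected <- integer(0)
  any_skipped <- any(!alive)

  while (any(alive)) {
    nrm <- colSums(Cres^2)
    newly_dead <- alive & nrm <= 1e-10 * pmax(norm0, 1e-300)
    if (any(newly_dead)) { any_skipped <- TRUE; alive[newly_dead] <- FALSE }
    if (!any(alive)) break
    drop <- rep(-Inf, m)
    idx <- which(alive)
    drop[idx] <- (crossprod(Cres[, idx, drop = FALSE], r)^2)[, 1] / nrm[idx]
    j <- which(drop >= max(drop) - 1e-10)[1]
    rss_j <- rss - drop[j]
    aic_j <- ols_aic(max(rss_j, 1e-300), n, length(selected) + 2)
    if (aic_j >= aic - 1e-10) break
    q <- Cres[, j] / sqrt(nrm[j])
    r <- r - q * sum(q * r)
    alive[j] <- FALSE
    Cres[, alive] <- Cres[, alive, drop = FALSE] -
      q %*% crossprod(q, Cres[, alive, drop = FALSE])
    selected <- c(selected, j)
    rss <- rss_j
    aic <- aic_j
  }

  if (any_skipped) {
    warning("candidate term(s) skipped: addition would leave the design rank-deficient")
  }
  selected <- colnames(candidates)[selected]
  X <- cbind(`(Intercept)` = rep(1, n),
             candidates[, selected, drop = FALSE])
  final <- lm.fit(X, y)
  rss <- sum(final$residuals^2)
  aic <- ols_aic(rss, n, ncol(X))
  full_fit <- lm.fit(cbind(`(Intercept)` = rep(1, n), candidates), y)
  structure(
    list(subset = subset, selected = selected,
         r2 = 1 - rss / tss,
         aic = aic, n = n,
         coefficients = setNames(final$coefficients, colnames(X)),
         residuals = final$residuals,
         full_r2 = 1 - sum(full_fit$residuals^2) / tss),
    class = "pvr_fit"
  )
}

#' Commonality decomposition of the seven model R2 values
#'
#' Decomposes the full model's R2 into unique components of each class,
#' pairwise shared components, and the three-way shared component, from the
#' R2 of all seven class-subset models. Negative shared components are
#' legitimate (suppression) and reported as-is. The seven components always
#' sum to `R2_PCS` exactly.
#'
#' @param r2 Named numeric vector with entries `P`, `C`, `S`, `PC`, `PS`,
#'   `CS`, `PCS`.
#' @return A named numeric vector with components `U_P`, `U_C`, `U_S`,
#'   `C_PC`, `C_PS`, `C_CS`, `C_PCS`.
#' @export
commonality <- function(r2) {
  need <- c("P", "C", "S", "PC", "PS", "CS", "PCS")
  if (!all(need %in% names(r2))) {
    stop_pvr("r2 must carry entries ", paste(need, collapse = ", "))
  }
  r2 <- r2[need]
  c_pcs <- r2["P"] + r2["C"] + r2["S"] - r2["PC"] - r2["PS"] - r2["CS"] + r2["PCS"]
  out <- c(
    U_P = unname(r2["PCS"] - r2["CS"]),
    U_C = unname(r2["PCS"] - r2["PS"]),
    U_S = unname(r2["PCS"] - r2["PC"]),
    C_PC = unname(r2["P"] + r2["C"] - r2["PC"] - c_pcs),
    C_PS = unname(r2["P"] + r2["S"] - r2["PS"] - c_pcs),
    C_CS = unname(r2["C"] + r2["S"] - r2["CS"] - c_pcs),
    C_PCS = unname(c_pcs)
  )
  out
}

#' Intraspecific contribution from PCS residuals
#'
#' Model R regresses the residuals of the full (PCS) model on species
#' indicator variables; the intraspecific contribution is
#' `(1 - R2_PCS) * (1 - R2_R)`, the share of total variance that neither the
#' three predictor classes nor species identity can explain -- i.e.
#' within-species variation. With one record per species, model R is
#' saturated (`R2_R = 1`) and the contribution is exactly 0.
#'
#' @param residuals Residuals of the PCS model, one per record.
#' @param species Species label per record.
#' @param r2_pcs R2 of the PCS model.
#' @return A list with `value` (the contribution) and `r2_r`.
#' @export
intraspecific_contribution <- function(residuals, species, r2_pcs) {
  species <- as.character(species)
  tss <- sum((residuals - mean(residuals))^2)
  within <- residuals - ave(residuals, species)
  rss <- sum(within^2)
  r2_r <- if (tss <= 0) 1 else 1 - rss / tss
  list(value = unname((1 - r2_pcs) * (1 - r2_r)), r2_r = unname(r2_r))
}

#' Phylogenetic eigenvector regression variance partition
#'
#' The package's central fitting function. Represents phylogeny by the
#' leading principal-coordinate axes of the patristic distance matrix,
#' broadcasts them from species to records, and fits the seven OLS models
#' over the class subsets {P, C, S, PC, PS, CS, PCS}, each pruned to its
#' most parsimonious version by forward AIC selection. The seven R2 values
#' are decomposed by commonality analysis into unique and shared components;
#' the residuals of the full model yield the intraspecific contribution.
#'
#' Records are the unit of analysis. All seven models use the identical
#' record subset (listwise deletion on the union of the class variables), so
#' their AIC and R2 values are comparable.
#'
#' @param dataset A `matched_dataset` (see [harmonize()] or
#'   [simulate_sla_dataset()]).
#' @param classes Optional list with `climate` and `soil` variable names and
#'   a `quadratic` flag vector; defaults to the six climate and six soil
#'   variables of the standard roster with no quadratic flags.
#' @param variant `"plain"` or `"interactions"` (adds all climate x soil
#'   product terms to the CS-containing subsets).
#' @param quad_screen If `TRUE` and `classes$quadratic` is absent, flag each
#'   class variable quadratic when the mixed-model screen
#'   ([env_screen()]) prefers the quadratic candidate by AIC.
#' @param eigvec_threshold Cumulative eigenvalue mass of the eigenvector
#'   pool (default 1: all positive axes, see [eigenvector_pool()]).
#' @param n_axes Optional fixed eigenvector count overriding the threshold.
#' @param response Record-level response column (default `"log_sla"`).
#' @return An object of class `pvr_partition`; see [print.pvr_partition()].
#'   Key elements: `fits` (seven `pvr_fit`s), `r2` (named, seven entries),
#'   `components` (commonality), `totals` (class totals = single-class R2),
#'   `intraspecific`, `r2_r`, `unexplained` (1 - R2_PCS), `n`, `n_axes`.
#' @export
pvr_partition <- function(dataset, classes = NULL,
                          variant = c("plain", "interactions"),
                          quad_screen = FALSE,
                          eigvec_threshold = 1, n_axes = NULL,
                          response = "log_sla") {
  stopifnot(inherits(dataset, "matched_dataset"))
  variant <- match.arg(variant)
  classes <- classes %||% list(climate = default_climate_class(),
                               soil = default_soil_class())
  if (length(intersect(classes$climate, classes$soil))) {
    stop_pvr("climate and soil classes must be disjoint")
  }

  records <- dataset$records
  vars <- c(classes$climate, classes$soil)
  keep <- complete.cases(records[, c(response, "species", vars)])
  records <- records[keep, , drop = FALSE]
  y <- records[[response]]

  if (quad_screen && is.null(classes$quadratic)) {
    classes$quadratic <- Filter(function(v) {
      env_screen(records, v, response = response)$degree == 2
    }, vars)
  }

  basis <- phylo_pcoa(patristic_matrix(dataset$tree))
  axes_sp <- eigenvector_pool(basis, cum_threshold = eigvec_threshold,
                              n_axes = n_axes)
  axes <- axes_sp[records$species, , drop = FALSE]

  subsets <- list(P = "P", C = "C", S = "S", PC = c("P", "C"),
                  PS = c("P", "S"), CS = c("C", "S"), PCS = c("P", "C", "S"))
  interactions <- variant == "interactions"
  fits <- lapply(names(subsets), function(nm) {
    cand <- build_candidates(records, axes, classes, subsets[[nm]],
                             interactions = interactions)
    forward_aic(y, cand, subset = nm)
  })
  names(fits) <- names(subsets)
  stopifnot(length(unique(vapply(fits, `[[`, numeric(1), "n"))) == 1)

  r2 <- vapply(fits, `[[`, numeric(1), "r2")
  comp <- commonality(r2)
  intra <- intraspecific_contribution(fits$PCS$residuals, records$species,
                                      r2_pcs = r2["PCS"])
  structure(
    list(fits = fits, r2 = r2, components = comp,
         totals = c(P = unname(r2["P"]), C = unname(r2["C"]), S = unname(r2["S"])),
         intraspecific = intra$value, r2_r = intra$r2_r,
         unexplained = unname(1 - r2["PCS"]),
         variant = variant, classes = classes,
         n = length(y), n_axes = ncol(axes_sp),
         eigvec_threshold = if (is.null(n_axes)) eigvec_threshold else NA_real_),
    class = "pvr_partition"
  )
}

#' @export
print.pvr_partition <- function(x, ...) {
  cat(sprintf("PVR variance partition (%s variant; %d records, %d eigenvectors)\n",
              x$variant, x$n, x$n_axes))
  cat("  Relative contributions (% of total variance):\n")
  cat(sprintf("    phylogenetic relatedness (total) %6.2f\n", 100 * x$totals["P"]))
  cat(sprintf("    intraspecific variation          %6.2f\n", 100 * x$intraspecific))
  cat(sprintf("    climatic conditions (total)      %6.2f\n", 100 * x$totals["C"]))
  cat(sprintf("    soil properties (total)          %6.2f\n", 100 * x$totals["S"]))
  cat(sprintf("    three-way joint (C_PCS)          %6.2f\n",
              100 * x$components["C_PCS"]))
  invisible(x)
}

#' @export
summary.pvr_partition <- function(object, ...) {
  x <- object
  cat(sprintf("PVR variance partition, %s variant\n", x$variant))
  cat(sprintf("  %d records, %d eigenvectors (threshold %s), quadratic: %s\n",
              x$n, x$n_axes,
              ifelse(is.na(x$eigvec_threshold), "fixed count",
                     format(x$eigvec_threshold)),
              if (length(x$classes$quadratic %||% character(0)))
                paste(x$classes$quadratic, collapse = ", ") else "none"))
  cat("  Model R2 (forward-AIC parsimonious fits):\n")
  for (nm in names(x$r2)) {
    cat(sprintf("    %-4s R2 = %.4f  (%d terms)\n", nm, x$r2[[nm]],
                length(x$fits[[nm]]$selected)))
  }
  cat("  Commonality components (% of total variance):\n")
  for (nm in names(x$components)) {
    cat(sprintf("    %-6s %7.2f\n", nm, 100 * x$components[[nm]]))
  }
  cat(sprintf("  Intraspecific contribution: %.2f%%  (R2_R = %.4f)\n",
              100 * x$intraspecific, x$r2_r))
  cat(sprintf("  Unexplained by PCS: %.2f%%\n", 100 * x$unexplained))
  invisible(x)
}

#' @export
coef.pvr_partition <- function(object, model = "PCS", ...) {
  object$fits[[model]]$coefficients
}
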