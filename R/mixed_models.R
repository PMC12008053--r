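# Nested random-intercept variance decomposition and single-predictor
# mixed-model environment screens (linear vs quadratic by AIC), via lme4.

#' Nested random-effects variance decomposition
#'
#' Fits a random-intercept model with one variance component per nesting
#' level (outermost to innermost, e.g. site then species-within-site) plus
#' the residual, by REML, and reports each component as a fraction of their
#' sum. On balanced designs the REML estimates coincide with the classical
#' ANOVA method-of-moments estimators.
#'
#' @param data A data frame of records (or a `matched_dataset`).
#' @param nesting Character vector of grouping columns, outermost first,
#'   e.g. `c("site_id", "species")` for the spatial decomposition.
#' @param response Response column (default `"log_sla"`).
#' @param label Optional label stored with the result.
#' @return An object of class `variance_components`: a data frame with
#'   columns `level`, `variance`, `fraction` (residual last, fractions sum
#'   to 1).
#' @export
variance_decomposition <- function(data, nesting, response = "log_sla",
                                   label = NULL) {
  if (inherits(data, "matched_dataset")) data <- data$records
  if (!length(nesting)) stop_pvr("nesting must name at least one grouping factor")
  absent <- setdiff(c(response, nesting), names(data))
  if (length(absent)) stop_pvr("column(s) not in data: ", paste(absent, collapse = ", "))
  data <- data[complete.cases(data[, c(response, nesting)]), , drop = FALSE]

  ## nested grouping labels: level k is the interaction of factors 1..k
  terms <- character(length(nesting))
  for (k in seq_along(nesting)) {
    col <- paste0(".grp", k)
    data[[col]] <- interaction(data[, nesting[seq_len(k)], drop = FALSE],
                               drop = TRUE)
    if (nlevels(data[[col]]) < 2) {
      stop_pvr("grouping level '", nesting[k], "' has fewer than 2 groups")
    }
    terms[k] <- paste0("(1 | ", col, ")")
  }
  singleton <- vapply(seq_along(nesting), function(k) {
    all(table(data[[paste0(".grp", k)]]) == 1L)
  }, logical(1))
  if (any(singleton)) {
    warning("all-singleton group level(s): ",
            paste(nesting[singleton], collapse = ", "),
            "; their variance is not separable from the residual")
  }

  fml <- as.formula(paste(response, "~ 1 +", paste(terms, collapse = " + ")))
  fit <- lme4::lmer(fml, data = data, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vars <- setNames(vc$vcov, vc$grp)
  comp <- vapply(seq_along(nesting), function(k) {
    unname(vars[paste0(".grp", k)])
  }, numeric(1))
  comp[is.na(comp)] <- 0
  resid_var <- unname(vars["Residual"])
  level_names <- vapply(seq_along(nesting), function(k) {
    if (k == 1) nesting[1] else paste0(nesting[k], ":", nesting[k - 1])
  }, character(1))
  out <- data.frame(
    level = c(rev(level_names), "residual"),
    variance = c(rev(comp), resid_var),
    stringsAsFactors = FALSE
  )
  out$fraction <- out$variance / sum(out$variance)
  attr(out, "label") <- label
  attr(out, "method") <- "REML (lme4)"
  attr(out, "n") <- nrow(data)
  class(out) <- c("variance_components", "data.frame")
  out
}

#' @export
print.variance_components <- function(x, ...) {
  lab <- attr(x, "label")
  cat("Variance decomposition", if (!is.null(lab)) paste0(" [", lab, "]"),
      " (", attr(x, "method"), ", n = ", attr(x, "n"), ")\n", sep = "")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-24s %10.6f  (%5.2f%%)\n",
                x$level[i], x$variance[i], 100 * x$fraction[i]))
  }
  invisible(x)
}

## Fit y ~ poly(env) + (1|species) at a given degree. The predictor is
## centered and scaled before squaring, which limits collinearity and keeps
## the fixed-effect design well conditioned; both constants are kept with
## the result. ML is used when the fit feeds an AIC comparison or a
## likelihood-ratio test, REML for reported coefficients.
fit_env_lmm <- function(data, response, env_var, species, degree, REML,
                        extra_fixed = NULL) {
  ctr <- mean(data[[env_var]])
  scl <- sd(data[[env_var]])
  if (!is.finite(scl) || scl <= 0) scl <- 1
  data$.env_c <- (data[[env_var]] - ctr) / scl
  fixed <- ".env_c"
  if (degree == 2) fixed <- c(fixed, "I(.env_c^2)")
  if (!is.null(extra_fixed)) fixed <- c(fixed, extra_fixed)
  fml <- as.formula(paste(response, "~", paste(fixed, collapse = " + "),
                          "+ (1 |", species, ")"))
  fit <- lme4::lmer(fml, data = data, REML = REML,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  list(fit = fit, center = ctr, scale = scl, data = data)
}

## Nakagawa-Schielzeth marginal R2: variance of the fixed-effect predictions
## over the sum of fixed, random-intercept, and residual variances.
marginal_r2 <- function(fit) {
  var_f <- var(as.numeric(lme4::getME(fit, "X") %*% lme4::fixef(fit)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_f / (var_f + sum(vc$vcov))
}

#' Single-predictor mixed-model environment screen
#'
#' Regresses the response on one environment variable with a species random
#' intercept, fitting linear and quadratic candidates (centered predictor).
#' The candidates are compared by AIC on ML fits (they differ in fixed
#' effects); the winner is refit by REML for the reported coefficients and
#' Nakagawa-Schielzeth marginal R2.
#'
#' @param data A data frame of records (or a `matched_dataset`).
#' @param env_var Name of the environment column.
#' @param response Response column (default `"log_sla"`).
#' @param species Species grouping column.
#' @return An object of class `env_screen`: list with `variable`, `degree`,
#'   `aic` (named, linear/quadratic), `coefficients` (on the standardized
#'   predictor scale), `center`, `scale`, `r2_marginal`, `n`.
#' @export
env_screen <- function(data, env_var, response = "log_sla", species = "species") {
  if (inherits(data, "matched_dataset")) data <- data$records
  absent <- setdiff(c(response, env_var, species), names(data))
  if (length(absent)) stop_pvr("column(s) not in data: ", paste(absent, collapse = ", "))
  data <- data[complete.cases(data[, c(response, env_var, species)]), , drop = FALSE]
  if (length(unique(data[[env_var]])) < 3) {
    stop_pvr("'", env_var, "' has fewer than 3 distinct values")
  }

  m1 <- fit_env_lmm(data, response, env_var, species, degree = 1, REML = FALSE)
  m2 <- tryCatch(
    fit_env_lmm(data, response, env_var, species, degree = 2, REML = FALSE),
    error = function(e) NULL
  )
  aic1 <- AIC(m1$fit)
  aic2 <- if (is.null(m2)) NA_real_ else AIC(m2$fit)
  singular2 <- !is.null(m2) && lme4::isSingular(m2$fit, tol = 1e-5)
  degree <- if (!is.null(m2) && !singular2 && aic2 < aic1) 2L else 1L
  if (!is.null(m2) && singular2 && aic2 < aic1) {
    warning("quadratic fit for '", env_var, "' is singular; keeping degree 1")
  }

  refit <- fit_env_lmm(data, response, env_var, species, degree = degree,
                       REML = TRUE)
  structure(
    list(variable = env_var, degree = degree,
         aic = c(linear = aic1, quadratic = aic2),
         coefficients = lme4::fixef(refit$fit), center = refit$center,
         scale = refit$scale,
         r2_marginal = marginal_r2(refit$fit), n = nrow(data)),
    class = "env_screen"
  )
}

#' @export
print.env_screen <- function(x, ...) {
  cat(sprintf("Screen %-20s degree %d  AIC(1)=%.1f AIC(2)=%.1f  marginal R2=%.3f (n=%d)\n",
              x$variable, x$degree, x$aic["linear"], x$aic["quadratic"],
              x$r2_marginal, x$n))
  invisible(x)
}

#' Group-by-environment interaction test
#'
#' Likelihood-ratio test (ML fits) of whether the response-environment
#' relationship differs between two groups (e.g. angiosperms vs gymnosperms),
#' at the AIC-chosen polynomial degree, with a species random intercept in
#' both models. The null model carries the group main effect; the alternative
#' adds group x environment interaction terms.
#'
#' @inheritParams env_screen
#' @param group Name of a two-level grouping column.
#' @param min_group_size Minimum records per group (default 10).
#' @return A list with `p` (LRT p-value), `degree`, `statistic`, `df`, `n`.
#' @export
group_interaction_test <- function(data, env_var, group, response = "log_sla",
                                   species = "species", min_group_size = 10) {
  if (inherits(data, "matched_dataset")) data <- data$records
  absent <- setdiff(c(response, env_var, group, species), names(data))
  if (length(absent)) stop_pvr("column(s) not in data: ", paste(absent, collapse = ", "))
  data <- data[complete.cases(data[, c(response, env_var, group, species)]), , drop = FALSE]
  data[[group]] <- factor(data[[group]])
  data[[group]] <- droplevels(data[[group]])
  if (nlevels(data[[group]]) != 2) {
    stop_pvr("group factor must have exactly 2 levels, has ",
             nlevels(data[[group]]))
  }
  if (any(table(data[[group]]) < min_group_size)) {
    stop_pvr("both groups need >= ", min_group_size, " records")
  }

  degree <- env_screen(data, env_var, response = response, species = species)$degree
  ctr <- mean(data[[env_var]])
  scl <- sd(data[[env_var]]); if (!is.finite(scl) || scl <= 0) scl <- 1
  data$.env_c <- (data[[env_var]] - ctr) / scl
  poly_terms <- if (degree == 2) c(".env_c", "I(.env_c^2)") else ".env_c"
  base <- paste(response, "~", paste(poly_terms, collapse = " + "), "+", group,
                "+ (1 |", species, ")")
  full <- paste(base, "+", paste(paste0(group, ":", poly_terms), collapse = " + "))
  ctl <- lme4::lmerControl(check.conv.singular = "ignore")
  m0 <- lme4::lmer(as.formula(base), data = data, REML = FALSE, control = ctl)
  m1 <- lme4::lmer(as.formula(full), data = data, REML = FALSE, control = ctl)
  lrt <- anova(m0, m1)
  list(p = lrt$`Pr(>Chisq)`[2], degree = degree,
       statistic = lrt$Chisq[2], df = lrt$Df[2], n = nrow(data))
}
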