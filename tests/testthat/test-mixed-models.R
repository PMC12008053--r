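balanced_oneway <- function(seed = 1, n_groups = 10, n_rep = 10,
                            sd_group = 2, sd_resid = 1) {
  set.seed(seed)
  g <- factor(rep(seq_len(n_groups), each = n_rep))
  y <- rep(rnorm(n_groups, 0, sd_group), each = n_rep) +
    rnorm(n_groups * n_rep, 0, sd_resid)
  data.frame(y = y, species = paste0("sp", g), site_id = "S1")
}

## ANOVA method-of-moments closed form for the balanced one-way design.
anova_oneway_fractions <- function(d, n_rep) {
  ybar <- tapply(d$y, d$species, mean)
  msb <- n_rep * var(ybar)
  msw <- sum((d$y - ave(d$y, d$species))^2) / (nrow(d) - length(ybar))
  va <- max((msb - msw) / n_rep, 0)
  c(group = va, resid = msw) / (va + msw)
}

test_that("REML fractions equal balanced-design ANOVA closed forms", {
  d <- balanced_oneway(seed = 4)
  vc <- variance_decomposition(d, nesting = "species", response = "y")
  oracle <- anova_oneway_fractions(d, n_rep = 10)
  expect_equal(vc$fraction[vc$level == "species"], unname(oracle["group"]),
               tolerance = 1e-6)
  expect_equal(vc$fraction[vc$level == "residual"], unname(oracle["resid"]),
               tolerance = 1e-6)
  expect_equal(sum(vc$fraction), 1, tolerance = 1e-8)
})

test_that("within-group-constant data put all variance on the group level", {
  d <- data.frame(y = rep(c(1, 5, 9), each = 4),
                  species = rep(c("a", "b", "c"), each = 4))
  ## zero residual variance: lme4 legitimately warns near the boundary
  vc <- suppressWarnings(
    variance_decomposition(d, nesting = "species", response = "y"))
  expect_gt(vc$fraction[vc$level == "species"], 0.999)
  expect_lt(vc$fraction[vc$level == "residual"], 1e-3)
})

test_that("variance fractions are location- and scale-invariant", {
  d <- balanced_oneway(seed = 9, n_groups = 8, n_rep = 6)
  vc0 <- variance_decomposition(d, nesting = "species", response = "y")
  d$y <- 3 * d$y + 100
  vc1 <- variance_decomposition(d, nesting = "species", response = "y")
  expect_equal(vc1$fraction, vc0$fraction, tolerance = 1e-6)
})

test_that("two-level spatial nesting decomposes site and species components", {
  set.seed(5)
  n_site <- 12; n_sp <- 8; n_rep <- 3
  d <- expand.grid(site_id = paste0("S", seq_len(n_site)),
                   species = paste0("sp", seq_len(n_sp)),
                   rep = seq_len(n_rep))
  site_eff <- rnorm(n_site, 0, 1.5)
  spsite_eff <- rnorm(n_site * n_sp, 0, 1)
  d$y <- site_eff[as.integer(factor(d$site_id))] +
    spsite_eff[as.integer(interaction(d$site_id, d$species))] +
    rnorm(nrow(d), 0, 0.5)
  vc <- variance_decomposition(d, nesting = c("site_id", "species"),
                               response = "y")
  expect_equal(nrow(vc), 3)
  expect_equal(sum(vc$fraction), 1, tolerance = 1e-8)
  ## generating shares 1.5^2 : 1 : 0.25 -> ~0.55 / 0.31 / 0.08
  expect_gt(vc$fraction[vc$level == "site_id"], 0.3)
  expect_gt(vc$fraction[vc$level == "species:site_id"], 0.15)
})

test_that("env screen recovers degree and explained fraction", {
  make_screen_data <- function(seed, quadratic = FALSE) {
    set.seed(seed)
    n_sp <- 40; n_rec <- 6
    sp <- rep(paste0("sp", seq_len(n_sp)), each = n_rec)
    env <- runif(n_sp * n_rec, -2, 2)
    sp_eff <- rnorm(n_sp, 0, 0.7)[rep(seq_len(n_sp), each = n_rec)]
    y <- if (quadratic) 1 - env^2 + sp_eff else env + sp_eff
    data.frame(species = sp, env = env, y = y + rnorm(length(y), 0, 0.3))
  }

  deg1 <- vapply(1:20, function(s) {
    env_screen(make_screen_data(s), "env", response = "y")$degree
  }, integer(1))
  expect_true(mean(deg1 == 1) >= 0.7) # AIC prefers a spurious square ~16% of the time

  d <- make_screen_data(3, quadratic = TRUE)
  scr <- env_screen(d, "env", response = "y")
  expect_equal(scr$degree, 2L)
  expect_true(scr$r2_marginal > 0 && scr$r2_marginal < 1)
  expect_lt(scr$aic[["quadratic"]], scr$aic[["linear"]])

  ## marginal R2 tracks the generating fixed-effect fraction (linear case)
  r2s <- vapply(1:10, function(s) {
    env_screen(make_screen_data(s), "env", response = "y")$r2_marginal
  }, numeric(1))
  ## var(env)~4/3 vs species 0.49 and resid 0.09 -> ~0.70
  expect_lt(abs(mean(r2s) - 4 / 3 / (4 / 3 + 0.49 + 0.09)), 0.05)
})

test_that("group interaction test detects opposite slopes and guards input", {
  set.seed(11)
  n_sp <- 30; n_rec <- 8
  sp <- rep(paste0("sp", seq_len(n_sp)), each = n_rec)
  grp <- rep(rep(c("g1", "g2"), each = n_sp / 2), each = n_rec)
  env <- runif(n_sp * n_rec, -1, 1)
  slope <- ifelse(grp == "g1", 1, -1)
  y <- slope * env + rnorm(n_sp, 0, 0.4)[rep(seq_len(n_sp), each = n_rec)] +
    rnorm(length(env), 0, 0.3)
  d <- data.frame(species = sp, group = grp, env = env, y = y)
  res <- group_interaction_test(d, "env", "group", response = "y")
  expect_lt(res$p, 0.01)

  d1 <- d[d$group == "g1", ]
  expect_error(group_interaction_test(d1, "env", "group", response = "y"),
               "2 levels")
})
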