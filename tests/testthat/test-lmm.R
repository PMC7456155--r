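# Mixed-model wrapper, R2, VIF, interaction screening, model comparison
# and subgroup fits.

make_crossed_table <- function(n = 400, beta = c(x1 = 2, x2 = -1),
                               sd_site = 3, sd_sp = 1.5, sd_e = 2,
                               seed = 1) {
  set.seed(seed)
  site <- sample(sprintf("S%02d", 1:12), n, replace = TRUE)
  sp <- sample(sprintf("P%02d", 1:6), n, replace = TRUE)
  x1 <- rnorm(n); x2 <- rnorm(n)
  b <- rnorm(12, 0, sd_site); a <- rnorm(6, 0, sd_sp)
  y <- 100 + beta[["x1"]] * x1 + beta[["x2"]] * x2 +
    b[match(site, sprintf("S%02d", 1:12))] +
    a[match(sp, sprintf("P%02d", 1:6))] + rnorm(n, 0, sd_e)
  data.frame(onset_doy = y, x1 = x1, x2 = x2,
             species = sp, site_id = site)
}

test_that("exact linear data is recovered with zero variance components", {
  tab <- make_crossed_table(300, sd_site = 0, sd_sp = 0, sd_e = 0)
  tab$onset_doy <- 100 + 2 * tab$x1
  spec <- model_spec(c("x1"))
  fit <- suppressWarnings(fit_lmm(tab, spec))
  expect_equal(fit$coefficients$estimate[1], 100, tolerance = 1e-6)
  expect_equal(fit$coefficients$estimate[2], 2, tolerance = 1e-6)
  expect_lt(fit$sd_resid, 1e-4)
  expect_true(fit$singular)
})

test_that("crossed random intercepts and slopes are recovered", {
  tab <- make_crossed_table(2000, seed = 42)
  fit <- fit_lmm(tab, model_spec(c("x1", "x2")))
  expect_equal(fit$coefficients$estimate[2], 2, tolerance = 0.15 / 2)
  expect_equal(fit$coefficients$estimate[3], -1, tolerance = 0.15)
  expect_equal(fit$sd_resid, 2, tolerance = 0.15 / 2)
  expect_gt(fit$sd_site, 1)
  expect_equal(fit$n_obs, 2000)
  # normal-approximation p-values present and tiny for strong effects
  expect_lt(fit$coefficients$p_value[2], 1e-10)
})

test_that("zero-site/species data matches OLS to 1e-4 relative error", {
  tab <- make_crossed_table(800, sd_site = 0, sd_sp = 0, sd_e = 2, seed = 3)
  fit <- fit_lmm(tab, model_spec(c("x1", "x2")))
  ols <- coef(lm(onset_doy ~ x1 + x2, tab))
  expect_equal(fit$coefficients$estimate, unname(ols),
               tolerance = 1e-4)
})

test_that("constant fixed term is dropped with a warning", {
  tab <- make_crossed_table(200, seed = 5)
  tab$flat <- 7
  expect_warning(fit <- fit_lmm(tab, model_spec(c("x1", "flat"))),
                 "rank-deficient")
  expect_equal(fit$dropped, "flat")
  expect_false("flat" %in% fit$coefficients$term)
})

test_that("argument errors are classed", {
  tab <- make_crossed_table(100)
  expect_error(fit_lmm(tab, model_spec("nope")),
               class = "woodonset_arg_error")
  tab$site_id <- "only_one"
  expect_error(fit_lmm(tab, model_spec("x1")),
               class = "woodonset_arg_error")
})

test_that("r2_nakagawa matches an independent formula evaluation", {
  tab <- make_crossed_table(600, seed = 7)
  fit <- fit_lmm(tab, model_spec(c("x1", "x2")))
  r2 <- r2_nakagawa(fit)
  # independent evaluation from the model matrix and VarCorr
  mod <- fit$model
  var_f <- var(as.vector(model.matrix(mod) %*% lme4::fixef(mod)))
  vc <- lme4::VarCorr(mod)
  var_r <- sum(vapply(vc, function(v) v[1, 1], numeric(1)))
  var_e <- attr(vc, "sc")^2
  denom <- var_f + var_r + var_e
  expect_equal(unname(r2[["r2_marginal"]]), var_f / denom, tolerance = 1e-10)
  expect_equal(unname(r2[["r2_conditional"]]), (var_f + var_r) / denom,
               tolerance = 1e-10)
  expect_gte(r2[["r2_conditional"]], r2[["r2_marginal"]])
})

test_that("r2 degenerate cases collapse as documented", {
  tab <- make_crossed_table(300, beta = c(x1 = 0, x2 = 0),
                            sd_site = 0, sd_sp = 0, sd_e = 2, seed = 8)
  fit <- fit_lmm(tab, model_spec(c("x1", "x2")))
  r2 <- r2_nakagawa(fit)
  expect_lt(r2[["r2_marginal"]], 0.02)
  tab2 <- make_crossed_table(300, sd_site = 0, sd_sp = 0, sd_e = 0, seed = 9)
  # zero-noise data trips lme4's scale heuristics; the fit itself is exact
  fit2 <- suppressWarnings(fit_lmm(tab2, model_spec(c("x1", "x2"))))
  r22 <- r2_nakagawa(fit2)
  expect_gt(r22[["r2_marginal"]], 0.99)
  expect_gt(r22[["r2_conditional"]], 0.99)
})

test_that("VIF matches an independent OLS implementation", {
  set.seed(11)
  n <- 10000
  tab <- data.frame(a = rnorm(n), b = rnorm(n))
  v <- compute_vif(tab, c("a", "b"))
  expect_true(all(abs(v - 1) < 0.05))

  tab$c <- tab$a
  expect_equal(unname(compute_vif(tab, c("a", "c"))[1]), Inf)

  tab$d <- tab$a + rnorm(n, 0, 0.014)  # correlation ~ 0.9999
  v2 <- compute_vif(tab, c("a", "d", "b"))
  r2 <- summary(lm(a ~ d + b, tab))$r.squared
  expect_equal(unname(v2[["a"]]), 1 / (1 - r2), tolerance = 1e-6)
  expect_error(compute_vif(tab, "a"), class = "woodonset_arg_error")
})

test_that("interaction screening keeps orthogonal products, drops collinear", {
  # balanced +/-1 factors: product is orthogonal -> retained
  g <- expand.grid(x1 = c(-1, 1), x2 = c(-1, 1))
  tab <- g[rep(1:4, 50), ]
  tab$onset_doy <- rnorm(200)
  tab$species <- rep(c("A", "B"), 100)
  tab$site_id <- rep(c("s1", "s2", "s3", "s4"), 50)
  res <- screen_interactions(tab, model_spec(c("x1", "x2")))
  expect_true(res$log$retained[1])
  expect_true("x1_x_x2" %in% res$spec$fixed)

  # raw collinear predictors: product excluded at threshold 5
  set.seed(2)
  tab2 <- data.frame(u = runif(300, 10, 20), v = runif(300, 5, 9))
  tab2$onset_doy <- rnorm(300)
  tab2$species <- "A"; tab2$site_id <- "s"
  res2 <- screen_interactions(tab2, model_spec(c("u", "v")))
  expect_false(res2$log$retained[1])
  expect_identical(res2$spec$fixed, c("u", "v"))

  # infinite threshold retains everything
  res3 <- screen_interactions(tab2, model_spec(c("u", "v")), threshold = Inf)
  expect_true(all(res3$log$retained))
})

test_that("compare_models ranks by AIC with ML refits across structures", {
  tab <- make_crossed_table(500, seed = 13)
  f_full <- fit_lmm(tab, model_spec(c("x1", "x2")))
  f_x1 <- fit_lmm(tab, model_spec("x1"))
  rk <- compare_models(list(full = f_full, x1_only = f_x1))
  expect_identical(rk$model[1], "full")
  expect_identical(attr(rk, "criteria"), "ML")
  expect_equal(rk$delta_aic[1], 0)

  # same model twice: delta AIC 0
  rk2 <- compare_models(list(a = f_full, b = f_full))
  expect_equal(rk2$delta_aic, c(0, 0))

  # mismatched row sets are rejected
  f_sub <- fit_lmm(tab[1:400, ], model_spec(c("x1", "x2")))
  expect_error(compare_models(list(a = f_full, b = f_sub)),
               class = "woodonset_arg_error")
})

test_that("a pure-noise extra term costs little AIC and BIC prefers smaller", {
  bic_smaller <- 0L
  for (s in 1:20) {
    tab <- make_crossed_table(400, seed = 100 + s)
    set.seed(1000 + s)
    tab$noise <- rnorm(nrow(tab))
    f2 <- fit_lmm(tab, model_spec(c("x1", "x2")))
    f3 <- fit_lmm(tab, model_spec(c("x1", "x2", "noise")))
    expect_lt(abs(f3$aic_ml - f2$aic_ml), 4)
    if (f2$bic_ml < f3$bic_ml) bic_smaller <- bic_smaller + 1L
  }
  expect_gte(bic_smaller, 15L)
})

test_that("homogeneous subgroups give coefficients with overlapping CIs", {
  # both biomes share the generating parameters, so per-term 95% CIs from
  # independent subgroup fits should overlap
  d <- cached_small()$drivers
  d <- d[d$biome %in% c("boreal", "temperate"), ]
  fits <- suppressWarnings(fit_subgroups(d, onset_model(2), "biome"))
  if (length(fits) == 2L) {
    c1 <- fits[[1]]$coefficients; c2 <- fits[[2]]$coefficients
    for (tm in intersect(c1$term, c2$term)) {
      a <- c1[c1$term == tm, ]; b <- c2[c2$term == tm, ]
      lo <- pmax(a$estimate - 1.96 * a$se, b$estimate - 1.96 * b$se)
      hi <- pmin(a$estimate + 1.96 * a$se, b$estimate + 1.96 * b$se)
      expect_lt(lo, hi, label = paste("CI overlap for", tm))
    }
  }
})

test_that("subgroup fits respect the size floor and flag missing columns", {
  tab <- make_crossed_table(500, seed = 17)
  tab$biome <- rep(c("boreal", "temperate"), length.out = nrow(tab))
  tiny <- tab[1:5, ]; tiny$biome <- "subtropical"
  tab <- rbind(tab, tiny)
  expect_warning(fits <- fit_subgroups(tab, model_spec(c("x1", "x2")),
                                       "biome"),
                 "skipped")
  expect_setequal(names(fits), c("boreal", "temperate"))
  expect_error(fit_subgroups(tab, model_spec(c("x1", "x2")), "absent"),
               class = "woodonset_arg_error")
})
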