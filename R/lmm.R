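#' Specify an onset mixed model
#'
#' Describes a linear mixed model for onset day-of-year: a global intercept,
#' fixed slopes for the listed predictor columns, and independent (crossed)
#' random intercepts for each grouping factor. The canonical models are
#' model 1 (photoperiod + forcing + chilling + scPDSI) and model 2
#' (MAT + forcing + chilling + scPDSI), both with species and site
#' intercepts.
#'
#' @param fixed Character vector of fixed-effect predictor columns.
#' @param response Response column (default `"onset_doy"`).
#' @param random Character vector of grouping-factor columns (default
#'   species and site).
#' @param method `"REML"` (default) or `"ML"`.
#' @return A `model_spec` list.
#' @export
model_spec <- function(fixed, response = "onset_doy",
                       random = c("species", "site_id"),
                       method = c("REML", "ML")) {
  method <- match.arg(method)
  if (length(fixed) == 0L) stop_arg("at least one fixed term is required")
  if (length(random) == 0L) stop_arg("at least one random factor is required")
  structure(list(response = response, fixed = fixed, random = random,
                 method = method),
            class = "model_spec")
}

#' Canonical model specifications
#'
#' `onset_model(1)` is the photoperiod model, `onset_model(2)` the MAT
#' model; both include forcing, chilling and scPDSI plus crossed species
#' and site intercepts.
#'
#' @param model 1 or 2.
#' @param method Estimation method passed to [model_spec()].
#' @return A [model_spec()].
#' @export
onset_model <- function(model = 2, method = "REML") {
  first <- switch(as.character(model), "1" = "photoperiod", "2" = "mat",
                  stop_arg("model must be 1 or 2"))
  model_spec(c(first, "forcing", "chilling", "scpdsi"), method = method)
}

spec_formula <- function(spec) {
  fixed <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
  ran <- paste(sprintf("(1 | %s)", spec$random), collapse = " + ")
  stats::as.formula(paste(spec$response, "~", fixed, "+", ran))
}

#' Fit a crossed random-intercept mixed model
#'
#' REML (or ML) fit of the model described by `spec` via `lme4::lmer`.
#' Constant or linearly dependent fixed columns are dropped with a warning
#' before fitting (names recorded in the result); a variance component
#' estimated at zero flags the fit as singular but is not an error;
#' non-convergence after one re-initialisation is a fit error.
#'
#' @param table Driver table (no missing values in the model columns).
#' @param spec A [model_spec()].
#' @return An `onset_fit` object: coefficient table with SEs and normal-
#'   approximation p-values, random-effect SDs, marginal/conditional
#'   R-squared, REML and ML AIC/BIC, log-likelihood, and the underlying
#'   `lmerMod` in `$model`.
#' @export
fit_lmm <- function(table, spec) {
  stopifnot(inherits(spec, "model_spec"))
  cols <- c(spec$response, spec$fixed, spec$random)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols)) {
    stop_arg("table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyNA(table[cols])) stop_arg("model columns contain missing values")
  for (f in spec$random) {
    if (length(unique(table[[f]])) < 2L) {
      stop_arg("random factor ", f, " has fewer than 2 levels")
    }
  }

  # rank screen on the fixed design: drop constant / dependent columns
  fixed <- spec$fixed
  X <- cbind(`(Intercept)` = 1, as.matrix(table[fixed]))
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    keep_idx <- qrx$pivot[seq_len(qrx$rank)]
    dropped <- setdiff(colnames(X), colnames(X)[keep_idx])
    dropped <- setdiff(dropped, "(Intercept)")
    warning("dropping rank-deficient fixed term(s): ",
            paste(dropped, collapse = ", "))
    fixed <- setdiff(fixed, dropped)
    if (length(fixed) == 0L) stop_fit("no estimable fixed terms remain")
    spec$fixed <- fixed
  } else {
    dropped <- character(0)
  }

  form <- spec_formula(spec)
  reml <- spec$method == "REML"
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            check.scaleX = "ignore",
                            optCtrl = list(xtol_abs = 1e-8, ftol_abs = 1e-8))
  fit <- suppressMessages(lme4::lmer(form, data = table, REML = reml,
                                     control = ctrl))
  conv <- fit@optinfo$conv$opt
  if (!is.null(conv) && conv != 0) {
    # bounded restart: one re-initialisation of the relative covariance
    # factor (theta = 0.5 puts each variance component at a quarter of the
    # residual variance)
    fit2 <- try(suppressMessages(lme4::lmer(
      form, data = table, REML = reml, control = ctrl,
      start = list(theta = rep(0.5, length(fit@theta))))), silent = TRUE)
    if (inherits(fit2, "try-error") ||
        (!is.null(fit2@optinfo$conv$opt) && fit2@optinfo$conv$opt != 0)) {
      stop_fit("mixed-model fit did not converge: optimizer code ", conv)
    }
    fit <- fit2
  }

  res <- structure(list(model = fit, spec = spec, dropped = dropped),
                   class = "onset_fit")
  res <- finalize_fit(res, table)
  res
}

finalize_fit <- function(res, table) {
  fit <- res$model
  spec <- res$spec
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  coefs <- data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se), z = unname(z), p_value = unname(p))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sd_of <- function(grp) {
    i <- vc$grp == grp & is.na(vc$var2)
    if (any(i)) vc$sdcor[i][1] else NA_real_
  }
  sd_random <- vapply(spec$random, sd_of, numeric(1))
  sd_resid <- vc$sdcor[vc$grp == "Residual"]

  r2 <- r2_components(fit, spec)
  ml <- if (lme4::isREML(fit)) suppressMessages(lme4::refitML(fit)) else fit

  res$coefficients <- coefs
  res$sd_random <- sd_random
  res$sd_site <- if ("site_id" %in% spec$random) sd_random[["site_id"]] else NA_real_
  res$sd_species <- if ("species" %in% spec$random) sd_random[["species"]] else NA_real_
  res$sd_resid <- sd_resid
  res$r2_marginal <- r2$r2m
  res$r2_conditional <- r2$r2c
  res$var_fixed <- r2$var_fixed
  res$aic <- stats::AIC(fit)
  res$bic <- stats::BIC(fit)
  res$aic_ml <- stats::AIC(ml)
  res$bic_ml <- stats::BIC(ml)
  res$loglik <- as.numeric(stats::logLik(fit))
  res$n_obs <- stats::nobs(fit)
  res$method <- spec$method
  res$singular <- lme4::isSingular(fit, tol = 1e-5)
  res$rows_key <- rows_fingerprint(table, spec)
  res
}

rows_fingerprint <- function(table, spec) {
  # identifies the fitted row set so model comparisons can insist on it
  paste0(nrow(table), ":",
         format(sum(as.numeric(table[[spec$response]])), digits = 15))
}

r2_components <- function(fit, spec) {
  X <- lme4::getME(fit, "X")
  var_fixed <- stats::var(as.vector(X %*% lme4::fixef(fit)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_ran <- sum(vc$vcov[vc$grp != "Residual" & is.na(vc$var2)])
  var_res <- vc$vcov[vc$grp == "Residual"]
  denom <- var_fixed + var_ran + var_res
  list(r2m = var_fixed / denom, r2c = (var_fixed + var_ran) / denom,
       var_fixed = var_fixed, var_random = var_ran, var_resid = var_res,
       denom = denom)
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance-components R-squared for Gaussian mixed models:
#' `R2m = var_f / (var_f + sum(var_random) + var_resid)` and
#' `R2c = (var_f + sum(var_random)) / (same denominator)`, where `var_f` is
#' the sample variance of the fixed-effect linear predictor over the fitted
#' rows.
#'
#' @param fit An `onset_fit` (or `lmerMod`).
#' @return Named numeric vector `c(r2_marginal=, r2_conditional=)`.
#' @export
r2_nakagawa <- function(fit) {
  mod <- if (inherits(fit, "onset_fit")) fit$model else fit
  spec <- if (inherits(fit, "onset_fit")) fit$spec else NULL
  r2 <- r2_components(mod, spec)
  c(r2_marginal = r2$r2m, r2_conditional = r2$r2c)
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R2_k)` where `R2_k` is from the OLS regression of term
#' `k` on the remaining terms (with intercept). Perfect collinearity is
#' reported as `Inf`, not an error.
#'
#' @param table data.frame holding the terms.
#' @param terms Character vector (length >= 2) of numeric columns.
#' @return Named numeric vector of VIFs (all >= 1, possibly `Inf`).
#' @export
compute_vif <- function(table, terms) {
  if (length(terms) < 2L) stop_arg("need at least 2 terms for VIF")
  X <- as.matrix(table[terms])
  if (!is.numeric(X)) stop_arg("VIF terms must be numeric")
  vapply(seq_along(terms), function(k) {
    y <- X[, k]
    others <- X[, -k, drop = FALSE]
    fit <- stats::lm.fit(cbind(1, others), y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) -> v
  names(v) <- terms
  v
}

#' Screen pairwise interactions by collinearity
#'
#' Considers every pairwise product of the specification's main effects; a product is
#' retained only if adding its column leaves all VIFs of the augmented
#' design at or below `threshold`. Products of raw (uncentred) predictors
#' are used, matching the convention under which interactions among these
#' climate drivers are strongly collinear with their main effects.
#'
#' @param table Driver table.
#' @param spec A [model_spec()] with main effects only.
#' @param threshold VIF threshold (default 5).
#' @return List with `spec` (augmented or unchanged), `table` (with product
#'   columns appended for retained interactions), and `log` (data.frame of
#'   candidate, max VIF, retained flag).
#' @export
screen_interactions <- function(table, spec, threshold = 5) {
  stopifnot(inherits(spec, "model_spec"))
  mains <- spec$fixed
  pairs <- utils::combn(mains, 2, simplify = FALSE)
  log <- data.frame(term = character(0), max_vif = numeric(0),
                    retained = logical(0))
  for (pr in pairs) {
    nm <- paste(pr, collapse = "_x_")
    cand <- table
    cand[[nm]] <- table[[pr[1]]] * table[[pr[2]]]
    v <- compute_vif(cand, c(mains, nm))
    ok <- all(v <= threshold)
    log <- rbind(log, data.frame(term = nm, max_vif = max(v), retained = ok))
    if (ok) {
      table[[nm]] <- cand[[nm]]
      spec$fixed <- c(spec$fixed, nm)
    }
  }
  list(spec = spec, table = table, log = log)
}

#' Compare fitted models by information criteria
#'
#' Ranks fits by AIC with BIC as tie-break and reports delta-AIC. All fits
#' must be on the identical row set. Whenever the fixed-effect structures
#' differ, ML criteria are used (REML likelihoods are not comparable across
#' fixed structures); otherwise the fits' own criteria are used.
#'
#' @param fits Named list of `onset_fit` objects.
#' @return data.frame ranking with columns `model`, `aic`, `bic`,
#'   `delta_aic`, ordered best first.
#' @export
compare_models <- function(fits) {
  if (length(fits) < 2L) stop_arg("need at least two fits to compare")
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  keys <- vapply(fits, function(f) f$rows_key, character(1))
  if (length(unique(keys)) != 1L) {
    stop_arg("fits were not obtained on identical row sets")
  }
  structures <- vapply(fits, function(f)
    paste(sort(f$spec$fixed), collapse = "+"), character(1))
  use_ml <- length(unique(structures)) > 1L
  aic <- vapply(fits, function(f) if (use_ml) f$aic_ml else f$aic, numeric(1))
  bic <- vapply(fits, function(f) if (use_ml) f$bic_ml else f$bic, numeric(1))
  ord <- order(aic, bic)
  out <- data.frame(model = names(fits)[ord], aic = aic[ord], bic = bic[ord],
                    delta_aic = aic[ord] - min(aic))
  attr(out, "criteria") <- if (use_ml) "ML" else "REML"
  rownames(out) <- NULL
  out
}

#' Fit the model separately within subgroups
#'
#' Independent fits of the same spec within each level of a grouping column
#' (biome or successional type). Groups smaller than
#' `10 * length(spec$fixed)` rows are skipped with a warning (small
#' subgroups give unreliable fits).
#'
#' @param table Driver table containing `grouping`.
#' @param spec A [model_spec()].
#' @param grouping Column name, e.g. `"biome"` or `"successional"`.
#' @return Named list of `onset_fit`, one per retained group.
#' @export
fit_subgroups <- function(table, spec, grouping) {
  if (!grouping %in% names(table)) {
    stop_arg("grouping column not in table: ", grouping)
  }
  floor_n <- 10L * length(spec$fixed)
  out <- list()
  for (g in sort(unique(as.character(table[[grouping]])))) {
    sub <- table[table[[grouping]] == g, , drop = FALSE]
    if (nrow(sub) < floor_n) {
      warning(sprintf("subgroup %s skipped: %d rows < floor %d",
                      g, nrow(sub), floor_n))
      next
    }
    out[[g]] <- fit_lmm(sub, spec)
  }
  if (length(out) == 0L) stop_data("no subgroup meets the size floor")
  out
}

#' @export
print.onset_fit <- function(x, ...) {
  cat(sprintf("Crossed random-intercept LMM (%s), n = %d%s\n", x$method,
              x$n_obs, if (isTRUE(x$singular)) " [singular]" else ""))
  cat("Fixed effects:\n")
  cf <- x$coefficients
  stars <- cut(cf$p_value, c(-Inf, 0.001, 0.01, 0.05, Inf),
               labels = c("***", "**", "*", ""))
  for (i in seq_len(nrow(cf))) {
    cat(sprintf("  %-14s %9.3f (%.3f)%s\n", cf$term[i], cf$estimate[i],
                cf$se[i], stars[i]))
  }
  cat("Random-effect SDs:\n")
  for (nm in names(x$sd_random)) {
    cat(sprintf("  %-14s %9.3f\n", nm, x$sd_random[[nm]]))
  }
  cat(sprintf("  %-14s %9.3f\n", "residual", x$sd_resid))
  cat(sprintf("R2 marginal %.3f, conditional %.3f; AIC %.1f, BIC %.1f\n",
              x$r2_marginal, x$r2_conditional, x$aic, x$bic))
  invisible(x)
}
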