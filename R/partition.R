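#' Partition explained variance among predictors and random factors
#'
#' Decomposes the variance of onset day-of-year into per-predictor fixed
#' shares, per-factor random shares and a residual share. Two fixed-share
#' variants are computed from refits over all subsets of the fixed terms
#' (random structure held fixed):
#'
#' * `unique`: R2m(full) minus R2m(model without the term), clamped at 0
#'   (clamps are logged in `$clamped`);
#' * `averaged`: the term's sequential R2m increment averaged over all
#'   orderings of entry (LMG). Averaged shares sum to the full model's
#'   marginal R2 by construction, so fixed + random + residual shares sum
#'   to 1 — this is the variant to read as an additive accounting.
#'
#' @param table Driver table.
#' @param spec A [model_spec()] for the full model.
#' @return A `partition_result` list: `fixed` (data.frame term/unique/
#'   averaged), `random` (named shares), `residual`, `r2_marginal`,
#'   `clamped`, `failed` (reduced models that failed to converge, if any).
#' @export
partition_variance <- function(table, spec) {
  stopifnot(inherits(spec, "model_spec"))
  terms <- spec$fixed
  k <- length(terms)
  if (k > 6L) stop_arg("variance partition supports at most 6 fixed terms")

  full <- fit_lmm(table, spec)
  denom_full <- full$var_fixed +
    sum(vapply(full$sd_random, function(s) s^2, numeric(1))) + full$sd_resid^2

  # R2m for every subset of terms (empty subset has R2m = 0 identically)
  subsets <- lapply(0:k, function(m) utils::combn(terms, m, simplify = FALSE))
  subsets <- unlist(subsets, recursive = FALSE)
  key <- function(s) {
    if (length(s) == 0L) "<none>" else paste(sort(s), collapse = "+")
  }
  r2m <- stats::setNames(numeric(length(subsets)),
                         vapply(subsets, key, character(1)))
  failed <- character(0)
  for (s in subsets) {
    if (length(s) == 0L) { r2m[key(s)] <- 0; next }
    if (length(s) == k) { r2m[key(s)] <- full$r2_marginal; next }
    sub_spec <- spec; sub_spec$fixed <- s
    f <- tryCatch(fit_lmm(table, sub_spec), woodonset_fit_error = function(e) NULL)
    if (is.null(f)) {
      failed <- c(failed, key(s)); r2m[key(s)] <- NA_real_
    } else r2m[key(s)] <- f$r2_marginal
  }

  # averaged (LMG): weight of each subset increment over orderings
  averaged <- stats::setNames(numeric(k), terms)
  for (tm in terms) {
    others <- setdiff(terms, tm)
    incr <- 0
    for (m in 0:length(others)) {
      combos <- utils::combn(others, m, simplify = FALSE)
      w <- factorial(m) * factorial(k - m - 1) / factorial(k)
      for (s in combos) {
        incr <- incr + w * (r2m[key(c(s, tm))] - r2m[key(s)])
      }
    }
    averaged[tm] <- incr
  }
  unique_share <- vapply(terms, function(tm) {
    full$r2_marginal - r2m[key(setdiff(terms, tm))]
  }, numeric(1))
  clamped <- names(unique_share)[!is.na(unique_share) & unique_share < 0]
  unique_share <- pmax(unique_share, 0)

  random_share <- vapply(full$sd_random, function(s) s^2 / denom_full,
                         numeric(1))
  residual_share <- full$sd_resid^2 / denom_full

  structure(list(
    fixed = data.frame(term = terms, unique = unname(unique_share),
                       averaged = unname(averaged)),
    random = random_share,
    residual = residual_share,
    r2_marginal = full$r2_marginal,
    r2_conditional = full$r2_conditional,
    clamped = clamped,
    failed = failed,
    fit = full
  ), class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat("Variance partition (shares of total onset variance)\n")
  cat("Fixed terms (unique | orderings-averaged):\n")
  for (i in seq_len(nrow(x$fixed))) {
    cat(sprintf("  %-14s %6.3f | %6.3f\n", x$fixed$term[i],
                x$fixed$unique[i], x$fixed$averaged[i]))
  }
  for (nm in names(x$random)) {
    cat(sprintf("  random %-7s %6.3f\n", nm, x$random[[nm]]))
  }
  cat(sprintf("  residual       %6.3f\n", x$residual))
  cat(sprintf("  (averaged fixed shares sum to R2m = %.3f)\n", x$r2_marginal))
  invisible(x)
}

#' Collinearity between photoperiod and mean annual temperature
#'
#' Ordinary least-squares R-squared of `y` on `x` (by default MAT on
#' photoperiod), quantifying how much of the site-year MAT variance the
#' photoperiod at onset explains.
#'
#' @param table Driver table.
#' @param x,y Column names (defaults `"photoperiod"`, `"mat"`).
#' @return R-squared in `[0, 1]`.
#' @export
regress_collinearity <- function(table, x = "photoperiod", y = "mat") {
  if (!all(c(x, y) %in% names(table))) stop_arg("columns absent: ", x, ", ", y)
  xv <- table[[x]]; yv <- table[[y]]
  if (length(xv) < 3L) stop_arg("need at least 3 rows")
  if (stats::var(xv) == 0) stop_arg("predictor has zero variance")
  fit <- stats::lm.fit(cbind(1, xv), yv)
  1 - sum(fit$residuals^2) / sum((yv - mean(yv))^2)
}

#' Compare chilling-window definitions
#'
#' Rebuilds the chilling predictor under each candidate window, refits the
#' full model and the model without chilling on the same rows (the
#' intersection of rows valid under every window), and reports each
#' window's unique chilling share and ML AIC. The window maximising the
#' chilling share is flagged.
#'
#' @param drivers Driver table built under any window (its chilling column
#'   is replaced per window).
#' @param climates Named list of [climate_series()] per site.
#' @param spec A [model_spec()] that includes `"chilling"`.
#' @param windows List of [chilling_window()] objects; default the
#'   canonical four: `[-5,5]`, `[0,5]`, `[-5,0]`, `[-10,0]`.
#' @return data.frame with one row per window: `window`, `chilling_share`,
#'   `aic`, `constant` (all-zero / constant chilling flag), `best`.
#' @export
compare_chilling_thresholds <- function(drivers, climates, spec,
                                        windows = default_chilling_windows()) {
  if (length(windows) < 2L) stop_arg("need at least 2 windows")
  if (!"chilling" %in% spec$fixed) stop_arg("spec must include chilling")
  labels <- vapply(windows, function(w)
    sprintf("[%g,%g]", w$t_low, w$t_high), character(1))

  # chilling columns per window on the common row set, computed per
  # site-year from the daily grids (one climate extraction per group)
  cols <- matrix(NA_real_, nrow(drivers), length(windows))
  grp <- split(seq_len(nrow(drivers)),
               paste(drivers$site_id, drivers$year))
  for (j in seq_along(windows)) {
    w <- windows[[j]]
    for (idx in grp) {
      sid <- as.character(drivers$site_id[idx[1]])
      yr <- drivers$year[idx[1]]
      g <- tryCatch(driver_grids(climates[[sid]], 0, yr, window = w),
                    error = function(e) NULL)
      if (is.null(g)) next
      cols[idx, j] <- g$chilling[drivers$onset_doy[idx]]
    }
  }
  keep <- stats::complete.cases(cols)
  drivers <- drivers[keep, , drop = FALSE]
  cols <- cols[keep, , drop = FALSE]

  red_spec <- spec; red_spec$fixed <- setdiff(spec$fixed, "chilling")
  out <- data.frame(window = labels, chilling_share = NA_real_,
                    aic = NA_real_, constant = FALSE, best = FALSE)
  red <- tryCatch(fit_lmm(drivers, red_spec), error = function(e) NULL)
  for (j in seq_along(windows)) {
    tab <- drivers
    tab$chilling <- cols[, j]
    if (stats::var(tab$chilling) == 0) {
      out$constant[j] <- TRUE
      next
    }
    res <- tryCatch({
      full <- fit_lmm(tab, spec)
      list(share = full$r2_marginal -
             (if (is.null(red)) NA_real_ else red$r2_marginal),
           aic = full$aic_ml)
    }, error = function(e) NULL)
    if (is.null(res)) next
    out$chilling_share[j] <- max(0, res$share)
    out$aic[j] <- res$aic
  }
  if (any(!is.na(out$chilling_share))) {
    out$best[which.max(out$chilling_share)] <- TRUE
  }
  out
}

#' The four canonical chilling windows
#'
#' @return List of [chilling_window()]: `[-5,5]`, `[0,5]`, `[-5,0]`,
#'   `[-10,0]` degrees C.
#' @export
default_chilling_windows <- function() {
  list(chilling_window(-5, 5), chilling_window(0, 5),
       chilling_window(-5, 0), chilling_window(-10, 0))
}
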