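#' Fit a random-intercept mixed model of waiting time
#'
#' Maximum-likelihood fit (default; REML optional for reporting) of
#' `waiting_time ~ drivers + background + (1 | level4)`. Predictors are
#' z-standardized within the fitting subset by default so coefficients are
#' comparable across terms and models. A rank-deficient fixed-effect design
#' fails with the collinear columns named.
#'
#' @param table A [assemble_table()] result (or compatible tibble).
#' @param drivers Character vector of driver columns to include.
#' @param background Character vector of background variables forced into
#'   the model (default: year of first detection and neighborhood mean
#'   waiting time).
#' @param response Response column (default `"waiting_time"`).
#' @param group Random-intercept grouping column (default `"level4"`).
#' @param standardize Z-standardize predictors within the fitting subset
#'   (default `TRUE`).
#' @param REML Use REML instead of ML (default `FALSE`; ML is required for
#'   AIC comparison across fixed-effect structures).
#' @return An object of class `wt_lmm`.
#' @export
fit_lmm <- function(table, drivers,
                    background = c("detection_year", "neighborhood_wait"),
                    response = "waiting_time", group = "level4",
                    standardize = TRUE, REML = FALSE) {
  preds <- c(drivers, background)
  missing_cols <- setdiff(c(response, preds, group), names(table))
  if (length(missing_cols) > 0)
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  if (length(unique(table[[group]])) < 2)
    abort("random-intercept grouping needs >= 2 levels")

  dat <- as.data.frame(table[, c(response, preds, group)])
  if (standardize) {
    for (p in preds) {
      s <- sd(dat[[p]])
      dat[[p]] <- if (s > 0) (dat[[p]] - mean(dat[[p]])) / s
                  else dat[[p]] - mean(dat[[p]])
    }
  }
  X <- model.matrix(as.formula(paste("~", paste(preds, collapse = " + "))),
                    dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("singular fixed-effect design; collinear columns: ",
                 paste(aliased, collapse = ", ")))
  }

  fml <- as.formula(paste(response, "~", paste(preds, collapse = " + "),
                          "+ (1 |", group, ")"))
  model <- lme4::lmer(fml, data = dat, REML = REML)
  vc <- as.data.frame(lme4::VarCorr(model))
  sig2_group <- vc$vcov[vc$grp == group]
  sig2_resid <- vc$vcov[vc$grp == "Residual"]
  fixed_pred <- as.vector(X %*% lme4::fixef(model))
  structure(list(
    model = model, data = dat, drivers = drivers, background = background,
    response = response, group = group, standardize = standardize,
    REML = REML,
    sigma2_fixed = var(fixed_pred),
    sigma2_group = sig2_group, sigma2_resid = sig2_resid,
    X = X
  ), class = "wt_lmm")
}

#' @export
print.wt_lmm <- function(x, ...) {
  cat("Mixed model:", x$response, "~",
      paste(c(x$drivers, x$background), collapse = " + "),
      "+ (1 |", x$group, ")\n")
  cat(sprintf("  n = %d, AIC = %.1f, logLik = %.1f (%s)\n",
              nrow(x$data), AIC(x$model), as.numeric(logLik(x$model)),
              if (x$REML) "REML" else "ML"))
  r2 <- r2_nakagawa(x)
  cat(sprintf("  R2 marginal = %.3f, conditional = %.3f\n",
              r2$r2_marginal, r2$r2_conditional))
  invisible(x)
}

#' @rdname fit_lmm
#' @param x A `wt_lmm` object.
#' @param ... Unused.
#' @export
tidy.wt_lmm <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    statistic = sm[, "t value"]
  )
}

#' @rdname fit_lmm
#' @export
glance.wt_lmm <- function(x, ...) {
  r2 <- r2_nakagawa(x)
  tibble::tibble(
    nobs = nrow(x$data),
    logLik = as.numeric(logLik(x$model)),
    AIC = AIC(x$model),
    sigma2_fixed = x$sigma2_fixed,
    sigma2_group = x$sigma2_group,
    sigma2_resid = x$sigma2_resid,
    r2_marginal = r2$r2_marginal,
    r2_conditional = r2$r2_conditional,
    r2_marginal_drivers = r2_marginal_drivers(x)
  )
}

#' Exhaustive AIC subset selection over the candidate drivers
#'
#' Enumerates all `2^k` subsets of the candidate drivers, fits each with
#' the background variables forced in and the random intercept retained,
#' and returns the minimum-AIC fit. Ties are broken by fewer parameters,
#' then lexicographic term order. Subsets whose fit fails are recorded and
#' skipped, never silently dropped.
#'
#' @inheritParams fit_lmm
#' @param drivers Candidate driver set (at most 15).
#' @return An object of class `wt_dredge`: `best` (the winning `wt_lmm`),
#'   `models` (one row per subset: terms, k, df, logLik, AIC, delta_AIC),
#'   and `failures`.
#' @export
all_subsets_aic <- function(table, drivers,
                            background = c("detection_year",
                                           "neighborhood_wait"),
                            response = "waiting_time", group = "level4",
                            standardize = TRUE) {
  k <- length(drivers)
  if (k > 15) abort("at most 15 candidate drivers (2^k enumeration)")
  masks <- 0:(2^k - 1)
  rows <- vector("list", length(masks))
  failures <- list()
  for (m in masks) {
    subset <- drivers[bitwAnd(m, bitwShiftL(1, seq_len(k) - 1)) > 0]
    fit <- tryCatch(
      fit_lmm(table, subset, background, response, group, standardize,
              REML = FALSE),
      error = function(e) e)
    if (inherits(fit, "error")) {
      failures[[length(failures) + 1]] <- tibble::tibble(
        mask = m, terms = paste(subset, collapse = "+"),
        message = conditionMessage(fit))
      next
    }
    rows[[m + 1]] <- tibble::tibble(
      mask = m,
      terms = paste(subset, collapse = "+"),
      k = length(subset),
      df = attr(logLik(fit$model), "df"),
      logLik = as.numeric(logLik(fit$model)),
      AIC = AIC(fit$model)
    )
  }
  models <- dplyr::bind_rows(rows)
  if (nrow(models) == 0) abort("every candidate subset failed to fit")
  models <- dplyr::arrange(models, .data$AIC, .data$df, .data$terms)
  models$delta_AIC <- models$AIC - models$AIC[1]
  best_terms <- if (models$terms[1] == "") character(0)
                else strsplit(models$terms[1], "+", fixed = TRUE)[[1]]
  best <- fit_lmm(table, best_terms, background, response, group,
                  standardize, REML = FALSE)
  structure(list(best = best, models = models,
                 failures = dplyr::bind_rows(failures)),
            class = "wt_dredge")
}

#' @export
print.wt_dredge <- function(x, ...) {
  cat("All-subsets AIC selection:", nrow(x$models), "models fitted",
      if (nrow(x$failures) > 0) paste0("(", nrow(x$failures), " failed)"),
      "\n")
  cat("Best model terms:", x$models$terms[1], "\n")
  print(x$best)
  invisible(x)
}

#' @export
tidy.wt_dredge <- function(x, ...) x$models

#' @export
glance.wt_dredge <- function(x, ...) glance(x$best)

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing predictor
#' `j` on the remaining predictors (with intercept). Perfect collinearity
#' yields `Inf`.
#'
#' @param x A `wt_lmm` fit, or a numeric matrix / data frame of
#'   predictors (columns).
#' @return A named numeric vector of VIFs.
#' @export
vif <- function(x) {
  if (inherits(x, "wt_lmm")) {
    M <- x$X[, setdiff(colnames(x$X), "(Intercept)"), drop = FALSE]
  } else {
    M <- as.matrix(x)
  }
  if (ncol(M) < 2) abort("need at least 2 predictors for VIF")
  if (nrow(M) <= ncol(M)) abort("need more observations than predictors")
  vapply(seq_len(ncol(M)), function(j) {
    r2 <- summary(lm(M[, j] ~ M[, -j, drop = FALSE]))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> setNames(colnames(M))
}

#' Marginal and conditional R-squared from variance components
#'
#' `R2_marginal = s2_f / (s2_f + s2_a + s2_e)` and
#' `R2_conditional = (s2_f + s2_a) / (s2_f + s2_a + s2_e)`, with `s2_f`
#' the variance of the fixed-effects linear predictor, `s2_a` the
#' random-intercept variance and `s2_e` the residual variance.
#'
#' @param sigma2_fixed,sigma2_group,sigma2_resid The three components.
#' @return A tibble `r2_marginal`, `r2_conditional`.
#' @export
r2_components <- function(sigma2_fixed, sigma2_group, sigma2_resid) {
  tot <- sigma2_fixed + sigma2_group + sigma2_resid
  if (tot <= 0) abort("all variance components are zero: R2 undefined")
  tibble::tibble(r2_marginal = sigma2_fixed / tot,
                 r2_conditional = (sigma2_fixed + sigma2_group) / tot)
}

#' @rdname r2_components
#' @param fit A `wt_lmm` object.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "wt_lmm"))
  r2_components(fit$sigma2_fixed, fit$sigma2_group, fit$sigma2_resid)
}

#' Driver-only marginal R-squared
#'
#' The variance of the fixed-effects linear predictor restricted to the
#' driver terms (coefficients taken from the full fit), divided by the
#' total variance `s2_f + s2_a + s2_e` — the share of variance explained
#' by the environmental and anthropogenic drivers alone, excluding the
#' background variables. Exact under predictor orthogonality, an
#' approximation otherwise.
#'
#' @param fit A `wt_lmm` object.
#' @param drivers Driver terms to credit (default: the fit's drivers).
#' @return A single numeric value.
#' @export
r2_marginal_drivers <- function(fit, drivers = fit$drivers) {
  stopifnot(inherits(fit, "wt_lmm"))
  tot <- fit$sigma2_fixed + fit$sigma2_group + fit$sigma2_resid
  if (length(drivers) == 0) return(0)
  cols <- intersect(drivers, colnames(fit$X))
  if (length(cols) == 0) return(0)
  b <- lme4::fixef(fit$model)[cols]
  lp <- as.vector(fit$X[, cols, drop = FALSE] %*% b)
  var(lp) / tot
}
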