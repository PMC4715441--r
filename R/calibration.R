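## Allometric calibration: log10 body mass (g) regressed on log10 convex
## hull volume (mm^3) over extant specimens, by OLS and by phylogenetic GLS
## under a Brownian-motion covariance. The fitted model object carries every
## statistic needed later for prediction intervals (n, mean_x, Sxx, MSE), so
## fossil predictions are reproducible without refitting.

VALID_TAGS <- c("eviscerated", "intact", "combined")
VALID_VARIANTS <- c("with_feet", "minus_feet")

#' Assemble a specimen calibration dataset
#'
#' Validates the specimen table used to calibrate the mass-volume
#' regression: one row per extant specimen with its measured body mass and
#' whole-skeleton convex hull volumes with and without the foot segments.
#' Preparation records whether the carcass was intact or eviscerated
#' (internal organs removed), which determines the calibration subset.
#'
#' @param specimens data.frame with columns `species`, `mass_g`,
#'   `preparation` (`"intact"` or `"eviscerated"`), `ch_vol_mm3`,
#'   `ch_vol_minus_feet_mm3`, optionally `common_name`.
#' @param subset_tag one of `"eviscerated"`, `"intact"`, `"combined"`.
#' @param predictor_variant which volume column feeds the regression:
#'   `"with_feet"` or `"minus_feet"`.
#' @return object of class `calibration_dataset` (a validated data.frame
#'   with `subset_tag` and `predictor_variant` attributes).
#' @export
calibration_dataset <- function(specimens, subset_tag = "combined",
                                predictor_variant = "minus_feet") {
  subset_tag <- match.arg(subset_tag, VALID_TAGS)
  predictor_variant <- match.arg(predictor_variant, VALID_VARIANTS)
  need <- c("species", "mass_g", "preparation", "ch_vol_mm3", "ch_vol_minus_feet_mm3")
  missing_cols <- setdiff(need, names(specimens))
  if (length(missing_cols) > 0L) {
    chm_error("schema", sprintf("specimen table lacks columns: %s",
                                paste(missing_cols, collapse = ", ")))
  }
  specimens$species <- trimws(specimens$species)
  if (anyDuplicated(specimens$species)) {
    chm_error("schema", "species names must be unique")
  }
  if (!all(specimens$preparation %in% c("intact", "eviscerated"))) {
    chm_error("schema", "preparation must be 'intact' or 'eviscerated'")
  }
  if (any(specimens$mass_g <= 0) || any(specimens$ch_vol_minus_feet_mm3 <= 0)) {
    chm_error("nonpositive_value", "masses and hull volumes must be positive")
  }
  if (any(specimens$ch_vol_minus_feet_mm3 > specimens$ch_vol_mm3)) {
    chm_error("schema", "minus-feet volume exceeds with-feet volume for some specimen")
  }
  structure(as.data.frame(specimens), class = c("calibration_dataset", "data.frame"),
            subset_tag = subset_tag, predictor_variant = predictor_variant)
}

#' Read a specimen calibration table from CSV
#'
#' @param path CSV path with the [calibration_dataset()] schema.
#' @inheritParams calibration_dataset
#' @return a `calibration_dataset`.
#' @export
read_specimens <- function(path, subset_tag = "combined",
                           predictor_variant = "minus_feet") {
  calibration_dataset(utils::read.csv(path, stringsAsFactors = FALSE),
                      subset_tag = subset_tag, predictor_variant = predictor_variant)
}

#' Subset a calibration dataset by carcass preparation
#'
#' @param data a `calibration_dataset`.
#' @param tag `"eviscerated"`, `"intact"` or `"combined"` (all specimens).
#' @return a `calibration_dataset` carrying the new subset tag.
#' @export
subset_by_preparation <- function(data, tag) {
  if (!is.character(tag) || length(tag) != 1L || !tag %in% VALID_TAGS) {
    chm_error("unknown_tag", sprintf(
      "unknown preparation tag '%s' (expected one of %s)",
      paste(tag, collapse = "/"), paste(VALID_TAGS, collapse = ", ")))
  }
  keep <- if (tag == "combined") rep(TRUE, nrow(data)) else data$preparation == tag
  out <- data[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(data), subset_tag = tag,
            predictor_variant = attr(data, "predictor_variant"))
}

## log10 predictor under the dataset's (or an overriding) variant.
predictor_log10 <- function(data, variant = NULL) {
  variant <- variant %||% attr(data, "predictor_variant") %||% "minus_feet"
  col <- if (variant == "minus_feet") "ch_vol_minus_feet_mm3" else "ch_vol_mm3"
  log10(data[[col]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_calibration_model <- function(a, b, n, mean_x, Sxx, SSE, r2, se_a, se_b,
                                  aic, covariance, subset_tag, predictor_variant,
                                  level = 0.95) {
  MSE <- if (n > 2) SSE / (n - 2) else 0
  tq <- if (SSE > 0) stats::qt(1 - (1 - level) / 2, n - 2) else 0
  m <- structure(list(
    a = a, b = b, n = n, mean_x = mean_x, Sxx = Sxx,
    SSE = SSE, MSE = MSE, r2 = r2,
    se_a = se_a, se_b = se_b,
    ci_a = c(a - tq * se_a, a + tq * se_a),
    ci_b = c(b - tq * se_b, b + tq * se_b),
    ci_level = level,
    aic = aic, covariance = covariance,
    subset_tag = subset_tag, predictor_variant = predictor_variant
  ), class = "calibration_model")
  m
}

#' Fit the log-log mass-volume calibration by ordinary least squares
#'
#' Regresses log10 body mass (g) on log10 convex hull volume (mm^3). OLS is
#' the appropriate type-I regression when the purpose is prediction of mass
#' from volume. The residual mean square is SSE/(n-2); the AIC uses the full
#' Gaussian log-likelihood at the maximum-likelihood variance with k = 3
#' parameters (intercept, slope, variance). A perfect fit (SSE = 0) yields
#' MSE = 0, zero-width intervals and AIC = -Inf.
#'
#' @param data a [calibration_dataset()].
#' @param predictor_variant optional override of the dataset's volume variant.
#' @return object of class `calibration_model` with fields `a`, `b`, `n`,
#'   `mean_x`, `Sxx`, `SSE`, `MSE`, `r2`, `se_a`, `se_b`, `ci_a`, `ci_b`,
#'   `aic`, `covariance` (`"iid"`), `subset_tag`, `predictor_variant`.
#' @export
fit_loglog_ols <- function(data, predictor_variant = NULL) {
  n <- nrow(data)
  if (n < 3L) {
    chm_error("insufficient_data", sprintf("need at least 3 specimens, got %d", n))
  }
  variant <- predictor_variant %||% attr(data, "predictor_variant") %||% "minus_feet"
  if (any(data$mass_g <= 0)) chm_error("nonpositive_value", "masses must be positive")
  x <- predictor_log10(data, variant)
  y <- log10(data$mass_g)
  fit <- stats::lm(y ~ x)
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  SSE <- sum(stats::resid(fit)^2)
  Syy <- sum((y - mean(y))^2)
  ## snap numerically-zero residuals to the exact perfect-fit path
  if (SSE < 1e-12 * max(1, Syy)) SSE <- 0
  Sxx <- sum((x - mean(x))^2)
  if (Sxx <= 0) chm_error("insufficient_data", "predictor has zero spread")
  r2 <- 1 - SSE / Syy
  MSE <- SSE / (n - 2)
  se_b <- sqrt(MSE / Sxx)
  se_a <- sqrt(MSE * (1 / n + mean(x)^2 / Sxx))
  aic <- gaussian_aic(SSE, n, log_det_C = 0)
  new_calibration_model(a, b, n, mean(x), Sxx, SSE, r2, se_a, se_b, aic,
                        covariance = "iid", subset_tag = attr(data, "subset_tag"),
                        predictor_variant = variant)
}

## AIC with the full Gaussian log-likelihood, ML variance (SSE/n), k = 3.
## log_det_C accounts for a non-identity residual correlation.
gaussian_aic <- function(SSE, n, log_det_C = 0) {
  if (SSE <= 0) return(-Inf)
  s2 <- SSE / n
  ll <- -0.5 * (n * log(2 * pi * s2) + log_det_C + n)
  -2 * ll + 2 * 3
}

#' Expected Brownian-motion covariance of tip values on a phylogeny
#'
#' Entry (i, j) is the shared root-to-MRCA path length of tips i and j;
#' the diagonal holds root-to-tip distances. Trees without branch lengths
#' get unit lengths on every edge. Computed with [ape::vcv.phylo()] and
#' reordered to `species`.
#'
#' @param tree an [ape::phylo] rooted tree with unique tip labels.
#' @param species character vector ordering the rows/columns; every name
#'   must be a tip of the tree (exact match after trimming).
#' @return symmetric positive semi-definite covariance matrix.
#' @export
brownian_covariance <- function(tree, species = tree$tip.label) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  species <- trimws(species)
  miss <- setdiff(species, trimws(tree$tip.label))
  if (length(miss) > 0L) {
    chm_error("missing_tip", sprintf("species absent from tree: %s",
                                     paste(miss, collapse = ", ")))
  }
  C <- ape::vcv.phylo(tree)
  rownames(C) <- colnames(C) <- trimws(rownames(C))
  C[species, species, drop = FALSE]
}

#' Read a rooted phylogeny from a Newick file
#'
#' Polytomies are allowed; absent branch lengths default to 1 on every edge,
#' matching the unit-branch-length convention of the calibration.
#'
#' @param path Newick file path.
#' @return an [ape::phylo] tree.
#' @export
read_phylogeny <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) chm_error("io", sprintf("could not parse Newick file %s", path))
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  tree
}

#' Fit the calibration by phylogenetic generalized least squares
#'
#' GLS with residual covariance proportional to the Brownian-motion
#' expectation on the supplied tree, estimating
#' beta = (X' C^-1 X)^-1 X' C^-1 y. The residual variance is profiled by
#' maximum likelihood for the AIC; MSE remains the unbiased SSE_gls/(n-2)
#' with SSE_gls = r' C^-1 r. r2 is the GLS analogue
#' 1 - SSE_gls / Syy_gls with Syy_gls taken about the GLS-weighted mean.
#' With an identity covariance (star tree, unit branches) the fit reproduces
#' OLS exactly.
#'
#' @param data a [calibration_dataset()].
#' @param tree an [ape::phylo] tree covering all dataset species as tips.
#' @param predictor_variant optional override of the dataset's volume variant.
#' @return a `calibration_model` with `covariance = "brownian"`.
#' @export
fit_pgls <- function(data, tree, predictor_variant = NULL) {
  n <- nrow(data)
  if (n < 3L) {
    chm_error("insufficient_data", sprintf("need at least 3 specimens, got %d", n))
  }
  variant <- predictor_variant %||% attr(data, "predictor_variant") %||% "minus_feet"
  x <- predictor_log10(data, variant)
  y <- log10(data$mass_g)
  C <- brownian_covariance(tree, data$species)
  L <- tryCatch(chol(C), error = function(e) {
    chm_error("singular_covariance", "Brownian covariance matrix is not positive definite")
  })
  Ci <- chol2inv(L)
  X <- cbind(1, x)
  XtCi <- crossprod(X, Ci)
  A <- XtCi %*% X
  beta <- tryCatch(solve(A, XtCi %*% y), error = function(e) {
    chm_error("singular_covariance", "normal equations are singular")
  })
  r <- y - X %*% beta
  SSE <- drop(crossprod(r, Ci %*% r))
  one <- rep(1, n)
  mu <- drop(crossprod(one, Ci %*% y)) / drop(crossprod(one, Ci %*% one))
  Syy <- drop(crossprod(y - mu, Ci %*% (y - mu)))
  if (SSE < 1e-12 * max(1, Syy)) SSE <- 0
  r2 <- 1 - SSE / Syy
  MSE <- SSE / (n - 2)
  covb <- MSE * solve(A)
  aic <- gaussian_aic(SSE, n, log_det_C = 2 * sum(log(diag(L))))
  new_calibration_model(
    a = beta[1], b = beta[2], n = n, mean_x = mean(x),
    Sxx = sum((x - mean(x))^2), SSE = SSE, r2 = r2,
    se_a = sqrt(covb[1, 1]), se_b = sqrt(covb[2, 2]), aic = aic,
    covariance = "brownian", subset_tag = attr(data, "subset_tag"),
    predictor_variant = variant)
}

#' Confidence intervals for the calibration coefficients
#'
#' Student-t intervals `b +/- t(1-alpha/2, n-2) * SE(b)` (and likewise for
#' the intercept), recomputed at any level from the stored standard errors.
#'
#' @param model a `calibration_model`.
#' @param level confidence level in (0, 1); default 0.95.
#' @return list with elements `a` and `b`, each a length-2 interval.
#' @export
coefficient_ci <- function(model, level = 0.95) {
  stopifnot(inherits(model, "calibration_model"), level > 0, level < 1)
  tq <- if (model$SSE > 0) stats::qt(1 - (1 - level) / 2, model$n - 2) else 0
  list(a = c(model$a - tq * model$se_a, model$a + tq * model$se_a),
       b = c(model$b - tq * model$se_b, model$b + tq * model$se_b))
}

#' Akaike information criterion of a fitted calibration model
#'
#' @param model a `calibration_model`.
#' @return the AIC stored at fit time (full Gaussian likelihood, ML
#'   variance, k = 3); `-Inf` for a perfect fit.
#' @export
model_aic <- function(model) {
  stopifnot(inherits(model, "calibration_model"))
  model$aic
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "log10(mass g) = %.4f + %.4f * log10(volume mm^3)   [%s, %s, %s]\n",
    x$a, x$b, x$subset_tag %||% "?", x$predictor_variant %||% "?", x$covariance))
  cat(sprintf("  n = %d, r2 = %.4f, MSE = %.6f, AIC = %.2f\n", x$n, x$r2, x$MSE, x$aic))
  cat(sprintf("  95%% CI a: [%.3f, %.3f]  b: [%.3f, %.3f]\n",
              x$ci_a[1], x$ci_a[2], x$ci_b[1], x$ci_b[2]))
  invisible(x)
}

#' Serialize a calibration model to JSON
#'
#' All fields needed to reproduce predictions (including `n`, `mean_x`,
#' `Sxx`, `MSE`) are written at full precision, so a reloaded model yields
#' bit-identical predictions without refitting.
#'
#' @param model a `calibration_model`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  m <- unclass(model)
  if (!is.finite(m$aic)) m$aic <- NULL # JSON has no -Inf; absent means perfect fit
  ## 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Load a calibration model from JSON
#'
#' @param path JSON path written by [write_model_json()].
#' @return a `calibration_model`.
#' @export
read_model_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("a", "b", "n", "mean_x", "Sxx", "MSE") %in% names(m))) {
    chm_error("schema", sprintf("%s is not a serialized calibration model", path))
  }
  if (is.null(m$aic)) m$aic <- -Inf # JSON cannot carry -Inf; absent means perfect fit
  structure(m, class = "calibration_model")
}
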