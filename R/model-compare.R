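#' Poisson regression alternatives to the home-range model
#'
#' Fits the empirical abundance models used as benchmarks for the
#' mechanistic model, all with a log link and Poisson errors:
#' `"habitat_value"` regresses abundance on site-mean habitat value
#' (coefficients q0, q1); `"shrub_shade"` on site-level shrub cover and
#' shade (r0-r2); `"all_habitat"` on all four habitat resources (r0-r4,
#' with r3 = DWD and r4 = substrate); `"constant"` is the null model, a
#' single mean abundance k. Fitting uses iteratively reweighted least
#' squares via [stats::glm()].
#'
#' @param kind model family, see above.
#' @param covariates data frame (or vector for `"habitat_value"`) of
#'   per-site covariates in the order shrub, shade (, dwd, substrate);
#'   ignored for `"constant"`.
#' @param y observed per-site abundances.
#' @return A `poisson_regression`: list with `kind`, `coefficients`
#'   (named per family; for `"constant"` the response-scale mean `k`),
#'   `loglik`, `k_params`, `fitted`, and `converged`.
#' @export
fit_poisson_regression <- function(kind = c("habitat_value", "shrub_shade",
                                            "all_habitat", "constant"),
                                   covariates = NULL, y) {
  kind <- match.arg(kind)
  if (any(y < 0)) stop("abundances must be non-negative")
  coef_names <- switch(kind,
                       habitat_value = c("q0", "q1"),
                       shrub_shade = c("r0", "r1", "r2"),
                       all_habitat = c("r0", "r1", "r2", "r3", "r4"),
                       constant = "k")
  if (kind == "constant") {
    fit <- glm(y ~ 1, family = poisson())
    coefs <- c(k = unname(exp(coef(fit))))
  } else {
    covariates <- as.data.frame(covariates)
    if (ncol(covariates) != length(coef_names) - 1)
      stop(sprintf("`%s` expects %d covariate column(s)", kind,
                   length(coef_names) - 1))
    if (nrow(covariates) != length(y)) stop("covariate/abundance length mismatch")
    if (length(y) <= length(coef_names))
      stop("more coefficients than sites")
    df <- cbind(y = y, covariates)
    fit <- glm(y ~ ., family = poisson(), data = df)
    coefs <- stats::setNames(coef(fit), coef_names)
  }
  if (!fit$converged) warning("IRLS did not converge (possible separation)")
  structure(list(kind = kind, coefficients = coefs,
                 loglik = as.numeric(logLik(fit)),
                 k_params = length(coef_names),
                 fitted = as.numeric(fitted(fit)),
                 converged = fit$converged),
            class = "poisson_regression")
}

#' @export
print.poisson_regression <- function(x, ...) {
  cat(sprintf("<poisson_regression '%s'> logLik %.2f\n  ", x$kind, x$loglik))
  cat(paste(sprintf("%s = %.4g", names(x$coefficients), x$coefficients),
            collapse = ", "), "\n")
  invisible(x)
}

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 LL + 2k + 2k(k + 1) / (n - k - 1)`; requires `n > k + 1`.
#'
#' @param loglik model log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size.
#' @return Numeric AICc.
#' @examples
#' aicc(-87.95, 3, 31)
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: need n > k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Variance explained by model predictions
#'
#' The default is the squared Pearson correlation between observed and
#' predicted abundances, applied identically to every model family (the
#' mechanistic model's integer predictions included). Degenerate constant
#' predictions score 0 by convention. `method = "deviance"` instead
#' returns `1 - D(model) / D(null)` on the Poisson deviance.
#'
#' @param observed observed counts.
#' @param predicted model predictions.
#' @param method `"pearson"` (default) or `"deviance"`.
#' @return Numeric in \[0, 1\] (deviance-based values can be negative for
#'   models worse than the null).
#' @export
pseudo_r2 <- function(observed, predicted, method = c("pearson", "deviance")) {
  method <- match.arg(method)
  if (length(observed) < 3) stop("need at least 3 observations")
  if (var(observed) == 0) {
    warning("observed abundances have zero variance; R2 undefined")
    return(NA_real_)
  }
  if (method == "pearson") {
    if (var(predicted) == 0) return(0)
    return(cor(observed, predicted)^2)
  }
  dev <- function(y, mu) {
    mu <- pmax(mu, 1e-9)
    2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  }
  1 - dev(observed, predicted) / dev(observed, mean(observed))
}

#' Rank abundance models by AICc
#'
#' Builds the model-comparison table: for each candidate model
#' (characterised by its log-likelihood, parameter count, and per-site
#' predictions) it computes AICc, the difference from the best model, and
#' the variance explained, sorted by increasing AICc. The mechanistic
#' home-range model enters with its integer predicted abundances and
#' k = 3.
#'
#' @param fits list of candidates, each a list with `name`, `loglik`, `k`
#'   and `predictions` (predictions may be `NULL`, yielding `NA` R2).
#' @param y observed abundances.
#' @param n sample size for the AICc correction (default `length(y)`).
#' @param r2_method passed to [pseudo_r2()].
#' @return A data frame (class `model_comparison`) sorted by AICc with
#'   columns `model`, `k`, `loglik`, `aicc`, `delta_aicc`, `r2`.
#' @export
comparison_table <- function(fits, y, n = length(y),
                             r2_method = c("pearson", "deviance")) {
  r2_method <- match.arg(r2_method)
  tab <- data.frame(
    model = vapply(fits, `[[`, character(1), "name"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    r2 = vapply(fits, function(f) {
      if (is.null(f$predictions)) NA_real_
      else pseudo_r2(y, f$predictions, r2_method)
    }, numeric(1)))
  tab$aicc <- mapply(aicc, tab$loglik, tab$k, MoreArgs = list(n = n))
  tab <- tab[order(tab$aicc), c("model", "k", "loglik", "aicc", "r2")]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  tab <- tab[, c("model", "k", "loglik", "aicc", "delta_aicc", "r2")]
  rownames(tab) <- NULL
  attr(tab, "r2_method") <- r2_method
  class(tab) <- c("model_comparison", "data.frame")
  tab
}

#' @export
print.model_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("Model comparison (AICc; R2 = %s)\n", attr(x, "r2_method")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
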