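#' Compact regression/correlation result
#'
#' Shared result container for the single-variant eQTL fit, the risk-allele
#' burden regression and the effect-size concordance test: the OLS slope and
#' intercept, the Pearson correlation coefficient, the two-sided p-value from
#' the t distribution with n - 2 degrees of freedom, and the number of
#' observations. Both slope and r are always reported because published
#' "regression coefficients" are sometimes correlation coefficients.
#'
#' @param slope,intercept OLS coefficients of `response ~ predictor`.
#' @param pearson_r Pearson correlation in `[-1, 1]`.
#' @param p_value Two-sided p-value.
#' @param n Observations used.
#' @param predictor,response Axis labels for printing.
#' @return An object of class `regression_result`.
#' @export
regression_result <- function(slope, intercept, pearson_r, p_value, n,
                              predictor = "x", response = "y") {
  structure(
    list(slope = unname(slope), intercept = unname(intercept),
         pearson_r = unname(pearson_r), p_value = unname(p_value),
         n = n, predictor = predictor, response = response),
    class = "regression_result"
  )
}

fit_ols <- function(x, y, weights = NULL, predictor = "x", response = "y") {
  fit <- if (is.null(weights)) stats::lm(y ~ x) else stats::lm(y ~ x, weights = weights)
  coefs <- summary(fit)$coefficients
  r <- if (is.null(weights)) {
    stats::cor(x, y)
  } else {
    stats::cov.wt(cbind(x, y), wt = weights / sum(weights), cor = TRUE)$cor[1L, 2L]
  }
  regression_result(
    slope = coefs["x", "Estimate"],
    intercept = coefs["(Intercept)", "Estimate"],
    pearson_r = r,
    p_value = coefs["x", "Pr(>|t|)"],
    n = length(x), predictor = predictor, response = response
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("Regression of %s on %s (n = %d)\n", x$response, x$predictor, x$n))
  cat(sprintf("  slope     = %.4g (intercept %.4g)\n", x$slope, x$intercept))
  cat(sprintf("  Pearson r = %.4g\n", x$pearson_r))
  cat(sprintf("  p-value   = %.4g (two-sided, t with n-2 df)\n", x$p_value))
  invisible(x)
}
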