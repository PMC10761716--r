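#' Siegel repeated-medians robust linear trend
#'
#' Fits the repeated-medians line of Siegel (1982): for every point `i`,
#' take the median over `j != i` of the pairwise slopes
#' `(y_j - y_i) / (x_j - x_i)`; the slope estimate is the median of these
#' per-point medians and the intercept the median of `y_i - slope * x_i`.
#' The estimator has a 50% breakdown point, so up to half the points may be
#' gross outliers without moving the fit.
#'
#' Trend significance is assessed with the two-sided Mann-Kendall test
#' (Kendall's tau of `y` against `x` via [stats::cor.test()]), the standard
#' companion test for median-based trend slopes; a signed-rank test on the
#' per-point median slopes is not used because those slopes are strongly
#' mutually correlated, which grossly inflates its type-I error.
#'
#' @param x predictor (e.g. calendar years); at least 3 distinct values,
#'   duplicates not allowed.
#' @param y response, same length as `x`.
#' @param alpha significance level for the trend gate (default 0.05).
#' @param test if `FALSE`, skip the significance test (`p_value = NA`).
#' @return An object of class `siegel`: list with `slope`, `intercept`,
#'   `point_slopes` (the per-point medians), `p_value`, `significant`,
#'   `alpha`, `n`, `x`, `y`, `fitted.values`, `residuals`, `call`.
#' @examples
#' fit <- siegel(2001:2020, 3 + 0.2 * (1:20) + rnorm(20, 0, 0.1))
#' coef(fit)
#' summary(fit)
#' @export
siegel <- function(x, y, alpha = 0.05, test = TRUE) {
  n <- length(x)
  stopifnot(length(y) == n)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]; n <- length(x)
  if (n < 3) stop("siegel requires at least 3 finite observations")
  if (anyDuplicated(x)) stop("duplicate x values are not allowed")
  m <- vapply(seq_len(n), function(i)
    stats::median((y[-i] - y[i]) / (x[-i] - x[i])), numeric(1))
  slope <- stats::median(m)
  intercept <- stats::median(y - slope * x)
  p <- NA_real_
  if (test) {
    p <- if (stats::var(y) == 0) 1
    else suppressWarnings(
      stats::cor.test(x, y, method = "kendall", exact = NULL)$p.value)
    if (!is.finite(p)) p <- 1
  }
  fitted <- intercept + slope * x
  structure(list(slope = slope, intercept = intercept, point_slopes = m,
                 p_value = p,
                 significant = isTRUE(is.finite(p) && p < alpha),
                 alpha = alpha, n = n, x = x, y = y,
                 fitted.values = fitted, residuals = y - fitted,
                 call = match.call()),
            class = "siegel")
}

#' @export
print.siegel <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat("Siegel repeated-medians regression\n")
  cat(sprintf("  n = %d   slope = %s   intercept = %s\n", x$n,
              format(x$slope, digits = digits),
              format(x$intercept, digits = digits)))
  if (is.finite(x$p_value))
    cat(sprintf("  Mann-Kendall p = %s (%ssignificant at alpha = %g)\n",
                format.pval(x$p_value, digits = digits),
                if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' @export
coef.siegel <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.siegel <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x
  else if (is.list(newdata)) newdata$x else newdata
  object$intercept + object$slope * x
}

#' @export
residuals.siegel <- function(object, ...) object$residuals

#' @export
fitted.siegel <- function(object, ...) object$fitted.values

#' @export
summary.siegel <- function(object, ...) {
  structure(list(fit = object,
                 resid_summary = summary(object$residuals),
                 mad = stats::mad(object$residuals)),
            class = "summary.siegel")
}

#' @export
print.summary.siegel <- function(x, ...) {
  print(x$fit)
  cat("  residuals:\n")
  print(x$resid_summary)
  cat(sprintf("  residual MAD: %g\n", x$mad))
  invisible(x)
}

#' Simulate responses from a fitted Siegel trend
#'
#' Draws `nsim` response vectors `intercept + slope * x + e`, with `e`
#' resampled residuals, for parametric-bootstrap style checks.
#'
#' @param object a [siegel()] fit.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param ... ignored.
#' @return Data frame with `nsim` columns of simulated responses.
#' @export
simulate.siegel <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- replicate(nsim, object$fitted.values +
                     sample(object$residuals, object$n, replace = TRUE))
  as.data.frame(out)
}

#' Significance-gated trend slope
#'
#' Convenience wrapper returning the pieces the rate engine needs: the
#' repeated-medians slope and intercept, the Mann-Kendall p-value, and the
#' gated slope (`slope` if significant at `alpha`, else exactly 0).
#'
#' @param x,y series as in [siegel()].
#' @param alpha significance level.
#' @return List `(slope, intercept, p_value, significant, gated_slope,
#'   n_years)`.
#' @export
slope_significance <- function(x, y, alpha = 0.05) {
  fit <- siegel(x, y, alpha = alpha)
  list(slope = fit$slope, intercept = fit$intercept, p_value = fit$p_value,
       significant = fit$significant,
       gated_slope = if (fit$significant) fit$slope else 0,
       n_years = fit$n)
}
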