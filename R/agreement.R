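# ------------------------------------------------------------------------
# Scalar agreement statistics between two measurement methods (e.g.
# image-derived vs ex vivo blood, organ T values vs protein levels).
# ------------------------------------------------------------------------

#' Ordinary least-squares fit with confidence interval and R-squared
#'
#' OLS of `y` on `x` with intercept: slope, intercept, R-squared, the
#' two-sided p-value for slope != 0, and the parametric 95% CI on the
#' slope via the t(n - 2) distribution.
#'
#' @param x,y numeric vectors of equal length >= 3; `x` must have nonzero
#'   variance.
#' @return An object of class `regression_fit` with fields `slope`,
#'   `intercept`, `r_squared`, `p_value`, `ci95_slope` (length 2) and `n`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("at least 3 paired observations required")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  if (stats::var(x) <= 0) stop("'x' has zero variance")
  fit <- stats::lm(y ~ x)
  # summary.lm warns on an exact fit; exact fits are a legitimate ideal
  # limit here (noiseless phantoms), so the warning is silenced
  sm <- suppressWarnings(summary(fit))
  co <- stats::coef(sm)
  p_slope <- if (nrow(co) < 2L || is.nan(co["x", "t value"])) NA_real_
             else co["x", "Pr(>|t|)"]
  ci <- if (all(is.finite(co[, "Std. Error"])) && co["x", "Std. Error"] > 0)
    as.numeric(suppressWarnings(stats::confint(fit, "x", level = 0.95))) else
    rep(co["x", "Estimate"], 2L)
  structure(
    list(slope = unname(co["x", "Estimate"]),
         intercept = unname(co["(Intercept)", "Estimate"]),
         r_squared = sm$r.squared, p_value = unname(p_slope),
         ci95_slope = ci, n = length(x)),
    class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "<regression_fit> slope %.4g [95%% CI %.4g, %.4g], intercept %.4g, R^2 = %.4g, p = %.3g, n = %d\n",
    x$slope, x$ci95_slope[1], x$ci95_slope[2], x$intercept, x$r_squared,
    x$p_value, x$n))
  invisible(x)
}

#' Bland-Altman agreement statistics
#'
#' Differences are taken as `reference - test`, so a positive bias means
#' the test method underestimates the reference (e.g. PET segmentation
#' underestimating gamma-counter blood levels). Limits of agreement are
#' `bias +/- 1.96 * SD(differences)` (sample SD).
#'
#' @param reference,test numeric vectors of equal length >= 2.
#' @return An object of class `bland_altman` with `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`, plus `mean_pair` and `diff` for plotting.
#' @export
bland_altman <- function(reference, test) {
  if (length(reference) != length(test))
    stop("'reference' and 'test' must have equal length")
  if (length(reference) < 2L) stop("at least 2 pairs required")
  if (any(!is.finite(reference)) || any(!is.finite(test)))
    stop("inputs must be finite")
  d <- reference - test
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(
    list(bias = bias, sd_diff = sd_diff,
         loa_low = bias - 1.96 * sd_diff, loa_high = bias + 1.96 * sd_diff,
         n = length(d), mean_pair = (reference + test) / 2, diff = d),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> bias %.4g (SD %.4g), limits of agreement [%.4g, %.4g], n = %d\n",
    x$bias, x$sd_diff, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y numeric vectors of equal length >= 3, both with nonzero
#'   variance.
#' @return List with `r`, `r_squared` and `p` (two-sided, via the
#'   t(n - 2) transform of r).
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("at least 3 paired observations required")
  if (stats::var(x) <= 0 || stats::var(y) <= 0)
    stop("both inputs need nonzero variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  list(r = r, r_squared = r^2, p = ct$p.value)
}
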