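#' @title Bivariate log-log scaling machinery
#' @description Standardized major axis (SMA) regression with analytic
#' confidence intervals and slope tests, ordinary least squares for
#' near-zero slopes, and LOWESS-based curvature diagnostics. All fits here
#' operate on already log-transformed variables; exponents are base-invariant
#' but intercepts are natural-log values throughout the package.
#' @name scaling_regression
NULL

check_bivariate <- function(x, y, min_n = 3L, allow_constant_y = FALSE) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < min_n) stop(sprintf("need at least %d complete observations, got %d", min_n, n), call. = FALSE)
  if (stats::sd(x) == 0 || (!allow_constant_y && stats::sd(y) == 0)) {
    stop("degenerate input: zero variance in 'x' or 'y'", call. = FALSE)
  }
  list(x = x, y = y, n = n)
}

#' Standardized major axis (SMA) regression
#'
#' Fits the line minimising the sum of triangle areas between points and the
#' line (the product of vertical and horizontal residuals), the standard
#' estimator for allometric scaling where both variables carry error. The
#' slope is `sign(r) * sd(y)/sd(x)`; the confidence interval uses the
#' classical formula `alpha * (sqrt(B + 1) +/- sqrt(B))` with
#' `B = (1 - r^2) * qf(conf, 1, n - 2) / (n - 2)`.
#'
#' @param x,y Numeric vectors of equal length, already on the log scale.
#'   Non-finite pairs are dropped listwise.
#' @param conf_level Confidence level for the slope interval (default 0.95).
#' @return An object of class `"sma_fit"`: list with `alpha` (scaling
#'   exponent), `beta_log` (intercept, natural-log units), `alpha_ci`
#'   (lower/upper), `r2`, `n`, `conf_level`.
#' @seealso [sma_slope_test()], [ols_fit()]
#' @examples
#' set.seed(1)
#' x <- rnorm(50); y <- x + rnorm(50, sd = 0.3)
#' sma_fit(x, y)
#' @export
sma_fit <- function(x, y, conf_level = 0.95) {
  d <- check_bivariate(x, y)
  stopifnot(conf_level > 0, conf_level < 1)
  r <- stats::cor(d$x, d$y)
  if (!is.finite(r)) stop("correlation undefined", call. = FALSE)
  alpha <- sign2(r) * stats::sd(d$y) / stats::sd(d$x)
  beta_log <- mean(d$y) - alpha * mean(d$x)
  B <- (1 - r^2) * stats::qf(conf_level, 1, d$n - 2) / (d$n - 2)
  ci <- alpha * c(sqrt(B + 1) - sqrt(B), sqrt(B + 1) + sqrt(B))
  if (alpha < 0) ci <- rev(ci)
  structure(list(alpha = alpha, beta_log = beta_log,
                 alpha_ci = c(lower = ci[1], upper = ci[2]),
                 r2 = r^2, n = d$n, conf_level = conf_level),
            class = "sma_fit")
}

# sign() returns 0 at r = 0; an SMA slope keeps the magnitude sd(y)/sd(x),
# so treat r = 0 as positive by convention.
sign2 <- function(r) if (r < 0) -1 else 1

#' @export
print.sma_fit <- function(x, ...) {
  cat(sprintf("SMA fit (n = %d): alpha = %.4f [%.4f, %.4f] (%.0f%% CI), ln beta = %.4f, r^2 = %.4f\n",
              x$n, x$alpha, x$alpha_ci[1], x$alpha_ci[2],
              100 * x$conf_level, x$beta_log, x$r2))
  invisible(x)
}

#' Test an SMA slope against a hypothesised value
#'
#' Two-sided test of H0: SMA slope equals `hypothesized_slope`, based on the
#' correlation between the residual axis `y - b0*x` and the fitted axis
#' `y + b0*x`, which is zero exactly when the sample SMA slope equals `b0`.
#' The p-value uses the t distribution with `n - 2` degrees of freedom.
#'
#' @param fit An [sma_fit()] object (used for bookkeeping checks).
#' @param x,y The data the fit was computed from.
#' @param hypothesized_slope Positive slope under the null (e.g. 1 for
#'   isometry).
#' @return Two-sided p-value.
#' @export
sma_slope_test <- function(fit, x, y, hypothesized_slope = 1) {
  stopifnot(inherits(fit, "sma_fit"), hypothesized_slope > 0)
  d <- check_bivariate(x, y)
  if (d$n != fit$n) stop("'x','y' do not match the fitted data (different n)", call. = FALSE)
  b0 <- hypothesized_slope
  res <- d$y - b0 * d$x
  fitax <- d$y + b0 * d$x
  if (stats::sd(res) == 0 || stats::sd(fitax) == 0) return(1)
  r <- stats::cor(res, fitax)
  if (abs(r) >= 1) return(0)
  tval <- r * sqrt((d$n - 2) / (1 - r^2))
  2 * stats::pt(abs(tval), df = d$n - 2, lower.tail = FALSE)
}

#' Ordinary least squares fit
#'
#' Plain OLS of `y` on `x` with a t-based confidence interval and p-value for
#' the slope. Used where the expected slope is small and close to zero (the
#' water-content versus dry-mass relationship), where SMA is inappropriate.
#'
#' @inheritParams sma_fit
#' @return An object of class `"ols_fit"`: list with `slope`, `intercept`,
#'   `slope_ci`, `r2`, `p_value`, `n`, `conf_level`.
#' @export
ols_fit <- function(x, y, conf_level = 0.95) {
  d <- check_bivariate(x, y, allow_constant_y = TRUE)
  if (stats::sd(d$y) == 0) {
    # a constant response is a legitimate zero-slope fit, not degenerate
    return(structure(list(slope = 0, intercept = mean(d$y),
                          slope_ci = c(lower = 0, upper = 0),
                          r2 = 0, p_value = 1, n = d$n,
                          conf_level = conf_level),
                     class = "ols_fit"))
  }
  fit <- stats::lm(d$y ~ d$x)
  # an exact fit triggers a harmless precision warning in summary.lm
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2])
  ci <- suppressWarnings(stats::confint(fit, level = conf_level))[2, ]
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 slope_ci = c(lower = unname(ci[1]), upper = unname(ci[2])),
                 r2 = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = d$n, conf_level = conf_level),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit (n = %d): slope = %.4f [%.4f, %.4f], r^2 = %.4f, P = %.3g\n",
              x$n, x$slope, x$slope_ci[1], x$slope_ci[2], x$r2, x$p_value))
  invisible(x)
}

#' LOWESS smoothing curve
#'
#' Locally weighted (tricube) linear smoother with robustifying iterations,
#' evaluated on the sorted unique abscissae. Used to reveal curvature in
#' log-log trait relationships that a straight scaling line would miss.
#'
#' @param x,y Numeric vectors (log scale), at least 10 complete pairs.
#' @param frac Smoothing span: fraction of points used per local fit.
#' @param iterations Number of robustifying reweighting iterations.
#' @return An object of class `"smooth_curve"`: list with `x_grid` (strictly
#'   increasing), `y_smooth`, `frac`.
#' @export
lowess_curve <- function(x, y, frac = 2 / 3, iterations = 3L) {
  d <- check_bivariate(x, y, min_n = 10L, allow_constant_y = TRUE)
  stopifnot(frac > 0, frac <= 1)
  sm <- stats::lowess(d$x, d$y, f = frac, iter = iterations, delta = 0)
  grid <- !duplicated(sm$x)
  structure(list(x_grid = sm$x[grid], y_smooth = sm$y[grid], frac = frac),
            class = "smooth_curve")
}

#' Curvature index of a bivariate scaling relationship
#'
#' Root-mean-square vertical deviation between the LOWESS curve and the SMA
#' line over the x grid, scaled by `sd(y)`. Zero for an exactly linear
#' relationship; larger values indicate systematic curvature on log-log axes,
#' the diagnostic used to rank candidate whole-leaf predictors.
#'
#' @inheritParams lowess_curve
#' @return Non-negative scalar.
#' @export
curvature_index <- function(x, y, frac = 2 / 3) {
  d <- check_bivariate(x, y, min_n = 10L)
  sm <- lowess_curve(d$x, d$y, frac = frac)
  fit <- sma_fit(d$x, d$y)
  line <- fit$beta_log + fit$alpha * sm$x_grid
  sqrt(mean((sm$y_smooth - line)^2)) / stats::sd(d$y)
}
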