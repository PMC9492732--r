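#' @title Non-linear estimation of the saturation model
#' @description
#' Least-squares estimation of the log-scale rate model. The model is
#' conditionally linear: for a fixed half-saturation constant `K1`, the
#' predictors `1`, `lwc/(K1 + lwc)` and (in the joint form) `-1/(kT)` enter
#' linearly with coefficients `ln g`, `k1` and `E`. The fitter therefore
#' profiles the residual sum of squares over `K1` (coarse log-spaced scan
#' plus golden-section refinement) and solves the inner linear problem
#' exactly — a separable (variable-projection) least-squares scheme that has
#' no starting-value sensitivity and is fast enough for dense bootstrap
#' resampling.
#' @name model_fitting
NULL

#' Inverse thermal energy 1/(kT)
#'
#' Convenience transform used when the activation energy is estimated as a
#' regression coefficient: the model term `-E/(kT)` is linear in `-1/(kT)`,
#' so `1/(kT)` is treated as a single predictor.
#'
#' @param temperature_k Absolute temperature(s) in Kelvin; positive.
#' @param boltzmann_k Boltzmann constant (eV K^-1).
#' @return `1 / (boltzmann_k * temperature_k)`, in eV^-1.
#' @export
inverse_kt <- function(temperature_k, boltzmann_k = boltzmann_ev) {
  if (any(temperature_k <= 0, na.rm = TRUE)) {
    stop("'temperature_k' must be positive Kelvin temperatures", call. = FALSE)
  }
  1 / (boltzmann_k * temperature_k)
}

# Inner exact solve for fixed K1. Returns list(coef, rss).
# Design: [1, lwc/(K1+lwc)] plus optionally [-inv_kt].
.solve_linear <- function(u, ln_y, inv_kt = NULL) {
  X <- if (is.null(inv_kt)) cbind(1, u) else cbind(1, u, -inv_kt)
  fit <- .lm.fit(X, ln_y)
  list(coef = fit$coefficients, rss = sum(fit$residuals^2))
}

.profile_rss <- function(K1, lwc, ln_y, inv_kt = NULL) {
  .solve_linear(lwc / (K1 + lwc), ln_y, inv_kt)$rss
}

# Profiled least squares over K1; shared engine of the two fitters.
.fit_profiled <- function(lwc, ln_y, inv_kt = NULL, k1_grid = NULL) {
  n <- length(ln_y)
  if (is.null(k1_grid)) {
    pos <- lwc[lwc > 0]
    lo <- max(min(pos) / 20, 1e-6)
    hi <- max(pos) * 100
    k1_grid <- exp(seq(log(lo), log(hi), length.out = 25L))
  }
  rss_grid <- vapply(k1_grid, .profile_rss, numeric(1),
                     lwc = lwc, ln_y = ln_y, inv_kt = inv_kt)
  i <- which.min(rss_grid)
  lower <- k1_grid[max(i - 1L, 1L)]
  upper <- k1_grid[min(i + 1L, length(k1_grid))]
  boundary <- FALSE
  if (lower < upper) {
    opt <- stats::optimize(.profile_rss, interval = c(lower, upper),
                           lwc = lwc, ln_y = ln_y, inv_kt = inv_kt,
                           tol = 1e-10)
    K1 <- opt$minimum
    rss <- opt$objective
    # keep the grid point if refinement did not improve (flat profile)
    if (rss_grid[i] < rss) { K1 <- k1_grid[i]; rss <- rss_grid[i] }
  } else {
    K1 <- k1_grid[i]; rss <- rss_grid[i]
  }
  if (i == 1L || K1 <= min(k1_grid) * (1 + 1e-8)) boundary <- TRUE
  sol <- .solve_linear(lwc / (K1 + lwc), ln_y, inv_kt)
  list(K1 = K1, coef = sol$coef, rss = rss, boundary = boundary,
       grid = k1_grid, n = n)
}

# Gaussian AIC on the log scale with the constant kept, so that the
# saturation and linear models are compared on identical footing.
.gaussian_aic <- function(rss, n, n_curve_params) {
  n * log(rss / n) + 2 * (n_curve_params + 1) + n * (log(2 * pi) + 1)
}

.new_saturation_fit <- function(pf, params, inv_kt_used) {
  n_curve <- if (inv_kt_used) 4L else 3L
  structure(list(params = params,
                 residual_ss = pf$rss,
                 n = pf$n,
                 aic = .gaussian_aic(max(pf$rss, .Machine$double.xmin), pf$n, n_curve),
                 converged = TRUE,
                 k1_boundary = pf$boundary,
                 init_used = list(k1_grid = pf$grid)),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("Saturation model fit (n = %d)%s\n", x$n,
              if (isTRUE(x$k1_boundary)) " [K1 at search boundary]" else ""))
  print(x$params)
  cat(sprintf("  residual SS (ln scale): %.6g   AIC: %.2f\n",
              x$residual_ss, x$aic))
  invisible(x)
}

check_fit_inputs <- function(lwc, ln_y, min_n = 10L) {
  stopifnot(is.numeric(lwc), is.numeric(ln_y))
  if (length(lwc) != length(ln_y)) stop("input vectors must have equal length", call. = FALSE)
  keep <- is.finite(lwc) & is.finite(ln_y)
  if (sum(keep) < min_n) {
    stop(sprintf("need at least %d complete observations", min_n), call. = FALSE)
  }
  if (any(lwc[keep] < 0)) stop("'lwc' must be non-negative", call. = FALSE)
  keep
}

#' Fit the temperature-corrected saturation model
#'
#' Estimates `(ln g, k1, K1)` in `ln(y_cor) = ln(g) + k1*lwc/(K1 + lwc)` by
#' least squares on the natural-log scale, where `ln_y_cor` is a
#' temperature-corrected log trait (log of [temperature_correct()] output),
#' or any log trait when no temperature correction is wanted.
#'
#' @param lwc Leaf water content (g g^-1, dry-mass basis), non-negative.
#' @param ln_y_cor Natural-log temperature-corrected trait values.
#' @param init Optional list with element `k1_grid`: candidate `K1` values for
#'   the profile scan. Defaults to 25 log-spaced values spanning the
#'   observed LWC range.
#' @return An object of class `"saturation_fit"`: `params` (a
#'   [model_params()] with `E = 0`), `residual_ss`, `n`, `aic`, `converged`,
#'   `k1_boundary` (TRUE when `K1` ran into the search boundary, i.e. is
#'   weakly identified), `init_used`.
#' @export
fit_saturation_model <- function(lwc, ln_y_cor, init = NULL) {
  keep <- check_fit_inputs(lwc, ln_y_cor)
  lwc <- lwc[keep]; ln_y <- ln_y_cor[keep]
  if (stats::sd(lwc) == 0) {
    stop("'lwc' has no variation: K1 and k1 are unidentifiable", call. = FALSE)
  }
  pf <- .fit_profiled(lwc, ln_y, inv_kt = NULL, k1_grid = init$k1_grid)
  params <- model_params(g = exp(pf$coef[1]), k1 = pf$coef[2], K1 = pf$K1, E = 0)
  .new_saturation_fit(pf, params, inv_kt_used = FALSE)
}

#' Fit the joint saturation-times-Arrhenius model
#'
#' Estimates `(ln g, k1, K1, E)` in
#' `ln(y) = ln(g) + k1*lwc/(K1 + lwc) - E/(kT)`, treating `1/(kT)` as a
#' single predictor so that `E` is its (negated) regression coefficient.
#'
#' @inheritParams fit_saturation_model
#' @param inv_kt Inverse thermal energy `1/(k*T)` per record (eV^-1); see
#'   [inverse_kt()]. Must vary across records for `E` to be identifiable.
#' @param ln_y Natural-log uncorrected trait values.
#' @return A `"saturation_fit"` whose `params$E` is the estimated activation
#'   energy (eV).
#' @export
fit_full_model <- function(lwc, inv_kt, ln_y, init = NULL) {
  stopifnot(is.numeric(inv_kt), length(inv_kt) == length(ln_y))
  keep <- check_fit_inputs(lwc, ln_y) & is.finite(inv_kt)
  lwc <- lwc[keep]; ln_y <- ln_y[keep]; inv_kt <- inv_kt[keep]
  if (stats::sd(lwc) == 0) {
    stop("'lwc' has no variation: K1 and k1 are unidentifiable", call. = FALSE)
  }
  if (stats::sd(inv_kt) == 0) {
    stop("no temperature variation across records: E is unidentifiable", call. = FALSE)
  }
  pf <- .fit_profiled(lwc, ln_y, inv_kt = inv_kt, k1_grid = init$k1_grid)
  params <- model_params(g = exp(pf$coef[1]), k1 = pf$coef[2], K1 = pf$K1,
                         E = pf$coef[3])
  .new_saturation_fit(pf, params, inv_kt_used = TRUE)
}

#' Non-parametric bootstrap for the saturation model fits
#'
#' Case-resampling bootstrap: records are resampled with replacement
#' `n_boot` times, the model is refit on each resample, and percentile
#' confidence intervals are formed for each parameter. Resamples whose refit
#' fails (degenerate design after resampling) are dropped and counted.
#'
#' @param lwc,ln_y Data vectors as in [fit_saturation_model()].
#' @param covariates Optional list with element `inv_kt`; when present the
#'   joint model of [fit_full_model()] is refit, otherwise the
#'   temperature-corrected form.
#' @param n_boot Number of resamples (default 1000).
#' @param seed Integer seed; required. Identical seeds give identical
#'   summaries.
#' @param conf_level Confidence level of the percentile intervals.
#' @return An object of class `"bootstrap_summary"`: `n_boot`, `seed`,
#'   `param_cis` (matrix, rows = parameters g/k1/K1[/E]), `param_draws_summary`
#'   (mean and sd of draws), `n_failed`, `reliable` (FALSE when more than half
#'   of the refits failed), `base_fit`.
#' @export
bootstrap_fit <- function(lwc, ln_y, covariates = NULL, n_boot = 1000L,
                          seed, conf_level = 0.95) {
  if (missing(seed)) stop("'seed' is required for bootstrap resampling", call. = FALSE)
  inv_kt <- covariates$inv_kt
  base <- if (is.null(inv_kt)) {
    fit_saturation_model(lwc, ln_y)
  } else {
    fit_full_model(lwc, inv_kt, ln_y)
  }
  keep <- check_fit_inputs(lwc, ln_y)
  if (!is.null(inv_kt)) keep <- keep & is.finite(inv_kt)
  lwc <- lwc[keep]; ln_y <- ln_y[keep]
  if (!is.null(inv_kt)) inv_kt <- inv_kt[keep]
  n <- length(ln_y)
  pnames <- c("g", "k1", "K1", if (!is.null(inv_kt)) "E")
  # resamples refit on a grid centred on the base-fit K1
  K1_hat <- base$params$K1
  grid <- exp(seq(log(K1_hat / 20), log(K1_hat * 20), length.out = 13L))
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  draws <- matrix(NA_real_, nrow = n_boot, ncol = length(pnames),
                  dimnames = list(NULL, pnames))
  for (b in seq_len(n_boot)) {
    ii <- idx[, b]
    res <- tryCatch({
      if (stats::sd(lwc[ii]) == 0) stop("degenerate resample")
      if (!is.null(inv_kt) && stats::sd(inv_kt[ii]) == 0) stop("degenerate resample")
      pf <- .fit_profiled(lwc[ii], ln_y[ii],
                          inv_kt = if (is.null(inv_kt)) NULL else inv_kt[ii],
                          k1_grid = grid)
      c(exp(pf$coef[1]), pf$coef[2], pf$K1,
        if (!is.null(inv_kt)) pf$coef[3])
    }, error = function(e) NULL)
    if (!is.null(res)) draws[b, ] <- res
  }
  ok <- stats::complete.cases(draws)
  n_failed <- sum(!ok)
  a <- (1 - conf_level) / 2
  cis <- t(apply(draws[ok, , drop = FALSE], 2, stats::quantile,
                 probs = c(a, 1 - a), names = FALSE))
  colnames(cis) <- c("lower", "upper")
  structure(list(n_boot = n_boot, seed = seed,
                 param_cis = cis,
                 param_draws_summary = data.frame(
                   parameter = pnames,
                   mean = colMeans(draws[ok, , drop = FALSE]),
                   sd = apply(draws[ok, , drop = FALSE], 2, stats::sd),
                   row.names = NULL),
                 n_failed = n_failed,
                 reliable = n_failed <= n_boot / 2,
                 conf_level = conf_level,
                 base_fit = base),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("Bootstrap (%d resamples, seed %d, %d failed%s)\n",
              x$n_boot, x$seed, x$n_failed,
              if (!x$reliable) "; UNRELIABLE" else ""))
  est <- c(x$base_fit$params$g, x$base_fit$params$k1, x$base_fit$params$K1,
           x$base_fit$params$E)[seq_len(nrow(x$param_cis))]
  for (i in seq_len(nrow(x$param_cis))) {
    cat(sprintf("  %-3s %10.4g  [%.4g, %.4g]\n", rownames(x$param_cis)[i],
                est[i], x$param_cis[i, 1], x$param_cis[i, 2]))
  }
  invisible(x)
}

#' Compare the saturation model to a linear-in-LWC alternative by AIC
#'
#' Fits the simple linear model `ln_y_cor = a + b * lwc` on the same records
#' as an existing saturation fit and compares Gaussian AICs,
#' `AIC = n*ln(RSS/n) + 2p + n*(ln(2*pi) + 1)`, with `p` counting curve
#' parameters plus the residual variance (4 for the saturation model, 3 for
#' the line). The additive constant is kept in both so only the difference
#' is meaningful, and it is computed consistently.
#'
#' @param fit_nonlinear A `"saturation_fit"` from [fit_saturation_model()].
#' @param lwc,ln_y_cor The records the saturation model was fit on.
#' @return An object of class `"aic_comparison"`: `aic_saturation`,
#'   `aic_linear`, `delta` (saturation minus linear), `preferred`.
#' @export
compare_aic <- function(fit_nonlinear, lwc, ln_y_cor) {
  stopifnot(inherits(fit_nonlinear, "saturation_fit"))
  keep <- check_fit_inputs(lwc, ln_y_cor)
  lwc <- lwc[keep]; ln_y <- ln_y_cor[keep]
  n <- length(ln_y)
  if (n != fit_nonlinear$n) {
    stop("records differ from those used for the non-linear fit (n mismatch)",
         call. = FALSE)
  }
  lin <- .lm.fit(cbind(1, lwc), ln_y)
  rss_lin <- sum(lin$residuals^2)
  aic_lin <- .gaussian_aic(max(rss_lin, .Machine$double.xmin), n, 2L)
  delta <- fit_nonlinear$aic - aic_lin
  structure(list(aic_saturation = fit_nonlinear$aic,
                 aic_linear = aic_lin,
                 delta = delta,
                 preferred = if (delta < 0) "saturation" else "linear"),
            class = "aic_comparison")
}

#' @export
print.aic_comparison <- function(x, ...) {
  cat(sprintf("AIC: saturation %.2f vs linear %.2f (delta %.2f) -> %s model preferred\n",
              x$aic_saturation, x$aic_linear, x$delta, x$preferred))
  invisible(x)
}
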