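# Separable least squares, bootstrap, AIC comparison.

test_that("noiseless saturation data are recovered exactly", {
  d <- saturation_data(seed = 2, n = 200, g = 2, k1 = 1.5, K1 = 0.8,
                       noise_sd = 0)
  f <- fit_saturation_model(d$lwc, d$ln_y)
  expect_lt(abs(f$params$g / 2 - 1), 1e-6)
  expect_lt(abs(f$params$k1 / 1.5 - 1), 1e-6)
  expect_lt(abs(f$params$K1 / 0.8 - 1), 1e-6)
  expect_lt(f$residual_ss, 1e-18 * f$n)
  expect_true(f$converged)
})

test_that("profiled fit agrees with an independent Levenberg-Marquardt fit", {
  d <- saturation_data(seed = 8, n = 400, noise_sd = 0.3)
  f <- fit_saturation_model(d$lwc, d$ln_y)
  nls_fit <- minpack.lm::nlsLM(
    ln_y ~ lng + k1 * lwc / (K1 + lwc),
    data = data.frame(lwc = d$lwc, ln_y = d$ln_y),
    start = list(lng = min(d$ln_y), k1 = diff(range(d$ln_y)),
                 K1 = median(d$lwc)),
    lower = c(-Inf, -Inf, 1e-8),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(nls_fit)
  expect_equal(log(f$params$g), unname(cf["lng"]), tolerance = 1e-4)
  expect_equal(f$params$k1, unname(cf["k1"]), tolerance = 1e-3)
  expect_equal(f$params$K1, unname(cf["K1"]), tolerance = 1e-3)
})

test_that("degenerate designs are refused", {
  expect_error(fit_saturation_model(rep(1.5, 50), rnorm(50)),
               "unidentifiable")
  set.seed(4)
  lwc <- exp(rnorm(50))
  lny <- 1 + lwc / (1 + lwc) + rnorm(50, sd = 0.1)
  expect_error(fit_full_model(lwc, rep(40, 50), lny), "unidentifiable")
  expect_error(fit_saturation_model(lwc[1:5], lny[1:5]), "at least 10")
})

test_that("joint model recovers activation energy exactly from noiseless data", {
  set.seed(10)
  n <- 300
  lwc <- exp(rnorm(n, 0.5, 0.4))
  tk <- 273.15 + runif(n, 5, 30)
  p <- model_params(g = 2, k1 = 1, K1 = 0.6, E = 0.03)
  lny <- predict_log_rate(lwc, tk, p)
  f <- fit_full_model(lwc, inverse_kt(tk), lny)
  expect_lt(abs(f$params$g / p$g - 1), 1e-6)
  expect_lt(abs(f$params$k1 / p$k1 - 1), 1e-6)
  expect_lt(abs(f$params$K1 / p$K1 - 1), 1e-6)
  expect_lt(abs(f$params$E / p$E - 1), 1e-6)
})

test_that("bootstrap is deterministic and covers a zero activation energy", {
  set.seed(21)
  n <- 400
  lwc <- exp(rnorm(n, 0.5, 0.35))
  tk <- 273.15 + runif(n, 5, 30)
  p <- model_params(g = 2, k1 = 1, K1 = 0.6, E = 0)
  lny <- predict_log_rate(lwc, tk, p) + rnorm(n, sd = 0.3)
  b1 <- bootstrap_fit(lwc, lny, covariates = list(inv_kt = inverse_kt(tk)),
                      n_boot = 300, seed = 99)
  b2 <- bootstrap_fit(lwc, lny, covariates = list(inv_kt = inverse_kt(tk)),
                      n_boot = 300, seed = 99)
  expect_identical(b1$param_cis, b2$param_cis)
  expect_identical(b1$param_draws_summary, b2$param_draws_summary)
  ci_e <- b1$param_cis["E", ]
  expect_true(ci_e[["lower"]] < 0 && ci_e[["upper"]] > 0)
  expect_true(b1$reliable)
})

test_that("bootstrap intervals bracket the point estimates on well-behaved data", {
  d <- saturation_data(seed = 14, n = 500, noise_sd = 0.3)
  b <- bootstrap_fit(d$lwc, d$ln_y, n_boot = 300, seed = 7)
  est <- c(g = b$base_fit$params$g, k1 = b$base_fit$params$k1,
           K1 = b$base_fit$params$K1)
  for (pn in names(est)) {
    expect_true(b$param_cis[pn, "lower"] <= est[[pn]] &&
                  est[[pn]] <= b$param_cis[pn, "upper"])
  }
})

test_that("estimates of k1 and K1 tighten as the sample grows", {
  sizes <- c(200, 2000)
  mae <- sapply(sizes, function(n) {
    errs <- sapply(1:30, function(rep) {
      d <- saturation_data(seed = 1000 + rep * 10 + log10(n), n = n,
                           noise_sd = 0.3)
      f <- fit_saturation_model(d$lwc, d$ln_y)
      c(abs(f$params$k1 - d$k1), abs(f$params$K1 - d$K1))
    })
    rowMeans(errs)
  })
  expect_lt(mae[1, 2], mae[1, 1])
  expect_lt(mae[2, 2], mae[2, 1])
})

test_that("AIC prefers the generating model", {
  # strong saturation: K1 well inside the LWC range
  d <- saturation_data(seed = 33, n = 1000, g = 2, k1 = 1.5, K1 = 0.6,
                       noise_sd = 0.3)
  f <- fit_saturation_model(d$lwc, d$ln_y)
  cmp <- compare_aic(f, d$lwc, d$ln_y)
  expect_equal(cmp$preferred, "saturation")
  expect_lt(cmp$aic_saturation, cmp$aic_linear)

  # exactly linear in LWC: the line wins or ties within 2
  set.seed(34)
  lwc <- exp(rnorm(1000, 0.5, 0.35))
  lny <- 0.5 + 0.3 * lwc + rnorm(1000, sd = 0.3)
  fl <- fit_saturation_model(lwc, lny)
  cmpl <- compare_aic(fl, lwc, lny)
  expect_lt(cmpl$aic_linear, cmpl$aic_saturation + 2)
})

test_that("AIC difference is invariant to shifting the response", {
  d <- saturation_data(seed = 40, n = 300, noise_sd = 0.3)
  f0 <- fit_saturation_model(d$lwc, d$ln_y)
  c0 <- compare_aic(f0, d$lwc, d$ln_y)
  f5 <- fit_saturation_model(d$lwc, d$ln_y + 5)
  c5 <- compare_aic(f5, d$lwc, d$ln_y + 5)
  expect_equal(c0$delta, c5$delta, tolerance = 1e-6)
  expect_equal(f5$params$g / f0$params$g, exp(5), tolerance = 1e-4)
})

test_that("AIC comparison refuses mismatched record sets", {
  d <- saturation_data(seed = 41, n = 100, noise_sd = 0.2)
  f <- fit_saturation_model(d$lwc, d$ln_y)
  expect_error(compare_aic(f, d$lwc[1:50], d$ln_y[1:50]), "mismatch")
})
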