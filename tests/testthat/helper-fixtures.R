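# Shared fixtures and independent oracles, all built in code.

# Bivariate Gaussian cloud with a given log-log slope.
gaussian_cloud <- function(seed, n = 50, slope = 2, noise_sd = 0.5) {
  set.seed(seed)
  x <- rnorm(n)
  y <- slope * x + rnorm(n, sd = noise_sd)
  list(x = x, y = y)
}

# Independent one-line SMA slope oracle.
sma_slope_oracle <- function(x, y) {
  r <- cor(x, y)
  (if (r < 0) -1 else 1) * sd(y) / sd(x)
}

# Brute-force SMA: numerically minimise the triangle-area loss
# sum((y - a - b x)^2) / (2 |b|) with a profiled out (a = ybar - b xbar).
sma_slope_bruteforce <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  loss <- function(b) sum((yc - b * xc)^2) / (2 * abs(b))
  r <- cor(x, y)
  lim <- 10 * sd(y) / sd(x) + 1
  if (r >= 0) {
    optimize(loss, c(1e-8, lim), tol = 1e-10)$minimum
  } else {
    -optimize(function(b) loss(-b), c(1e-8, lim), tol = 1e-10)$minimum
  }
}

# Saturation-model data on the log scale (temperature-corrected form).
saturation_data <- function(seed, n, g = 2, k1 = 1, K1 = 0.6,
                            noise_sd = 0.3, lwc_meanlog = 0.53,
                            lwc_sdlog = 0.35) {
  set.seed(seed)
  lwc <- exp(rnorm(n, lwc_meanlog, lwc_sdlog))
  ln_y <- log(g) + k1 * lwc / (K1 + lwc) + rnorm(n, sd = noise_sd)
  list(lwc = lwc, ln_y = ln_y, g = g, k1 = k1, K1 = K1)
}

# Minimal raw record table in the harmonization schema.
blank_records <- function(n) {
  df <- data.frame(species = sprintf("sp%02d", seq_len(n)),
                   site_id = "S001", latitude = 45,
                   growth_form = "forb", ecosystem = "grassland",
                   stringsAsFactors = FALSE)
  for (col in setdiff(trait_schema(), names(df))) {
    df[[col]] <- if (col %in% c("flag_greenhouse", "flag_fertilised",
                                "flag_polluted")) FALSE else NA_real_
  }
  df
}
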