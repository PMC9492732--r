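# The data generator: determinism, construction guarantees, configured
# statistical structure.

test_that("identical configurations give byte-identical tables", {
  cfg <- synthetic_config(seed = 101, n_sites = 10, n_species_per_site = 8)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
  f1 <- tempfile(); f2 <- tempfile()
  write_trait_csv(d1, f1); write_trait_csv(d2, f2)
  expect_identical(readLines(f1), readLines(f2))
  c1 <- generate_monthly_climate(cfg)
  expect_identical(c1, generate_monthly_climate(cfg))
  # and the climate embedded in the dataset is the same draw
  expect_true(all(unique(d1$site_id) %in% c1$site_id))
  expect_equal(sort(unique(d1$latitude)), sort(c1$latitude))
})

test_that("invalid configurations are refused", {
  expect_error(synthetic_config(seed = 1, zone_mix = c(tropical = 0.5,
                                                       temperate = 0.5,
                                                       boreal = 0.5)),
               "configuration error")
  expect_error(synthetic_config(), "mandatory")
})

test_that("noiseless generation yields exactly isometric corrected scaling", {
  cfg <- synthetic_config(seed = 55, noise_sd_log = 0,
                          n_sites = 20, n_species_per_site = 20)
  d <- generate_dataset(cfg)
  corrected <- full_correct(d$leaf_area_cm2, d$lwc,
                            celsius_to_kelvin(d$temp_growing_season_c),
                            cfg$params_area)
  f <- sma_fit(log(d$dry_mass_g), log(corrected))
  expect_lt(abs(f$alpha - 1), 1e-10)
  expect_equal(f$r2, 1, tolerance = 1e-12)
})

test_that("generated LWC is independent of dry mass by default", {
  d <- generate_dataset(synthetic_config(seed = 77))
  f <- ols_fit(log(d$dry_mass_g), log(d$lwc))
  expect_true(f$slope_ci[["lower"]] < 0 && f$slope_ci[["upper"]] > 0)
  expect_lt(abs(f$slope), 0.05)
})

test_that("negative LWC-mass coupling depresses the uncorrected exponent", {
  unc <- sapply(c(0, -0.7), function(s) {
    d <- generate_dataset(synthetic_config(seed = 61, lwc_ml_log_slope = s))
    sma_fit(log(d$dry_mass_g), log(d$leaf_area_cm2))$alpha
  })
  expect_lt(unc[2], unc[1])
  expect_lt(unc[2], 0.96)
})

test_that("noise monotonically erodes the scaling r2", {
  r2_at <- function(sdlog) {
    mean(sapply(1:3, function(i) {
      d <- generate_dataset(synthetic_config(seed = 200 + i,
                                             noise_sd_log = sdlog,
                                             n_sites = 20,
                                             n_species_per_site = 25))
      sma_fit(log(d$dry_mass_g), log(d$leaf_area_cm2))$r2
    }))
  }
  r2s <- vapply(c(0.1, 0.3, 0.6), r2_at, numeric(1))
  expect_true(all(diff(r2s) < 0))
})

test_that("climate generator honours amplitude and flags sites with no growing season", {
  cfg <- synthetic_config(seed = 9, n_sites = 12,
                          site_temp_range = list(tropical = c(10, 10),
                                                 temperate = c(10, 10),
                                                 boreal = c(10, 10)),
                          seasonal_amplitude_range = list(tropical = c(0, 0),
                                                          temperate = c(0, 0),
                                                          boreal = c(0, 0)),
                          month_noise_sd = 0)
  cl <- generate_monthly_climate(cfg)
  gs <- growing_season_by_site(cl)
  expect_equal(gs$temp_growing_season_c, rep(10, 12))
  expect_true(all(cl$usable))

  polar <- synthetic_config(seed = 9, n_sites = 6,
                            site_temp_range = list(tropical = c(-20, -15),
                                                   temperate = c(-20, -15),
                                                   boreal = c(-20, -15)),
                            seasonal_amplitude_range = list(tropical = c(0, 0),
                                                            temperate = c(0, 0),
                                                            boreal = c(0, 0)),
                            month_noise_sd = 0)
  clp <- generate_monthly_climate(polar)
  expect_false(any(clp$usable))
})

test_that("records follow the harmonization schema and internal identities", {
  d <- generate_dataset(synthetic_config(seed = 88, n_sites = 8,
                                         n_species_per_site = 10))
  expect_true(all(trait_schema() %in% names(d)))
  expect_equal(d$sla_cm2_g * d$dry_mass_g, d$leaf_area_cm2, tolerance = 1e-12)
  expect_equal(d$lwc, (d$fresh_mass_g - d$dry_mass_g) / d$dry_mass_g,
               tolerance = 1e-12)
  expect_equal(d$water_mass_g, d$lwc * d$dry_mass_g, tolerance = 1e-12)
  expect_equal(d$whole_leaf_photo_nmol_s,
               d$photo_mass_nmol_g_s * d$dry_mass_g, tolerance = 1e-12)
  expect_true(all(d$ldmc > 0 & d$ldmc <= 1))
})
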