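# Derivations, unit conversions, grouping labels, filters.

test_that("LDMC to LWC conversion and its inverse are exact", {
  expect_equal(lwc_from_ldmc(0.5), 1.0)
  expect_equal(lwc_from_ldmc(0.25), 3.0)
  expect_equal(lwc_from_ldmc(1), 0)
  expect_error(lwc_from_ldmc(0), "0, 1")
  expect_error(lwc_from_ldmc(1.2), "0, 1")
  ldmc <- seq(0.05, 1, by = 0.05)
  expect_equal(1 / (1 + lwc_from_ldmc(ldmc)), ldmc, tolerance = 1e-15)
})

test_that("water mass and LWC derive consistently from masses", {
  w <- lwc_and_water_mass_from_masses(2, 1)
  expect_equal(w$lwc, 1); expect_equal(w$water_mass, 1)
  w0 <- lwc_and_water_mass_from_masses(3, 3)
  expect_equal(w0$lwc, 0); expect_equal(w0$water_mass, 0)
  w4 <- lwc_and_water_mass_from_masses(5, 1)
  expect_equal(w4$lwc, 4); expect_equal(w4$water_mass, 4)
  expect_error(lwc_and_water_mass_from_masses(1, 2), "inconsistent")
  expect_error(lwc_and_water_mass_from_masses(1, 0), "positive")

  # derivation-order invariance: masses -> lwc vs masses -> ldmc -> lwc
  fresh <- c(2.2, 8, 1.9); dry <- c(1.1, 2, 1.5)
  via_mass <- lwc_and_water_mass_from_masses(fresh, dry)$lwc
  via_ldmc <- lwc_from_ldmc(dry / fresh)
  expect_equal(via_mass, via_ldmc, tolerance = 1e-14)
})

test_that("area-to-mass photosynthesis conversion follows the unit algebra", {
  expect_equal(mass_specific_photosynthesis(10, 10), 100)
  expect_equal(mass_specific_photosynthesis(1, 1), 1)
  expect_equal(mass_specific_photosynthesis(0, 37), 0)
  expect_error(mass_specific_photosynthesis(-1, 1), "non-negative")
})

test_that("growing season months are strictly above 4.99 degrees", {
  expect_equal(growing_season_temperature(rep(10, 12)), 10)
  m <- c(-5, 0, 5, 15, rep(-10, 8))
  expect_equal(growing_season_temperature(m), 10)
  # a month at exactly 4.99 is excluded
  m2 <- c(4.99, 6, rep(-10, 10))
  expect_equal(growing_season_temperature(m2), 6)
  expect_true(is.na(growing_season_temperature(rep(0, 12))))
  expect_error(growing_season_temperature(1:11), "12 monthly")
})

test_that("latitudinal zones use absolute latitude with half-open bounds", {
  expect_equal(as.character(assign_latitudinal_zone(10)), "tropical")
  expect_equal(as.character(assign_latitudinal_zone(-30)), "temperate")
  expect_equal(as.character(assign_latitudinal_zone(60)), "boreal")
  expect_equal(as.character(assign_latitudinal_zone(c(25, 50, -90))),
               c("temperate", "boreal", "boreal"))
  expect_error(assign_latitudinal_zone(91), "90")
})

test_that("derivation fills the analysis fields and respects precedence", {
  r <- blank_records(3)
  r$dry_mass_g <- c(1, 2, 0.5)
  r$fresh_mass_g <- c(3, NA, NA)
  r$ldmc <- c(NA, 0.25, NA)
  r$lwc <- c(NA, NA, 2)
  r$leaf_area_cm2 <- c(50, 100, 30)
  r$photo_area_umol_m2_s <- c(10, NA, 5)
  h <- derive_traits(r)
  expect_equal(h$lwc, c(2, 3, 2))           # masses, ldmc, passthrough
  expect_equal(h$water_mass_g, c(2, 6, 1))
  expect_equal(h$ldmc, c(1 / 3, 0.25, 1 / 3))
  expect_equal(h$sla_cm2_g, c(50, 50, 60))
  expect_equal(h$lma_g_cm2, 1 / h$sla_cm2_g)
  # 10 umol m^-2 s^-1 * 5 m^2 kg^-1 = 50 nmol g^-1 s^-1
  expect_equal(h$photo_mass_nmol_g_s[1], 50)
  expect_equal(h$whole_leaf_photo_nmol_s[1], 50)
  expect_equal(h$photo_mass_nmol_g_s[3], 5 * 6)
})

test_that("species-site aggregation averages within but never across sites", {
  r <- blank_records(5)
  r$species <- c("a", "a", "a", "b", "b")
  r$site_id <- c("S1", "S1", "S2", "S1", "S1")
  r$dry_mass_g <- c(1, 3, 10, 4, NA)
  agg <- aggregate_species_site_means(r)
  expect_equal(nrow(agg), 3)
  key <- paste(agg$species, agg$site_id)
  expect_equal(agg$dry_mass_g[key == "a S1"], 2)
  expect_equal(agg$dry_mass_g[key == "a S2"], 10)   # not averaged across sites
  expect_equal(agg$dry_mass_g[key == "b S1"], 4)    # NA ignored

  # single-record groups pass through unchanged
  one <- blank_records(1); one$dry_mass_g <- 7
  expect_equal(aggregate_species_site_means(one)$dry_mass_g, 7)

  # conflicting categorical labels are an error
  bad <- blank_records(2)
  bad$species <- "a"; bad$growth_form <- c("tree", "forb")
  expect_error(aggregate_species_site_means(bad), "conflicting")
})

test_that("aggregation preserves the grand mean for equal group sizes", {
  r <- blank_records(6)
  r$species <- rep(c("a", "b", "c"), each = 2)
  r$dry_mass_g <- c(1, 3, 2, 6, 10, 2)
  agg <- aggregate_species_site_means(r)
  expect_equal(mean(agg$dry_mass_g), mean(r$dry_mass_g))
})

test_that("filters keep complete natural records and log every exclusion", {
  r <- blank_records(6)
  r$lwc <- c(1, NA, 1, 1, 1, 1)
  r$ldmc <- NA_real_
  r$fresh_mass_g <- NA_real_
  r$dry_mass_g <- c(1, 1, 1, 1, 1, NA)
  r$leaf_area_cm2 <- 10
  r$flag_greenhouse[3] <- TRUE
  r$flag_fertilised[4] <- TRUE
  r$species[5] <- ""
  rules <- list(species_known = TRUE, natural_site = TRUE,
                require_fields = c("water", "dry_mass_g", "leaf_area_cm2"))
  out <- filter_records(r, rules)
  expect_equal(nrow(out$records), 1)
  expect_equal(sum(out$exclusion_log$count) + nrow(out$records), nrow(r))
  expect_setequal(out$exclusion_log$reason,
                  c("no water measurement", "grown in greenhouse",
                    "fertilised", "species identification lacking",
                    "missing dry_mass_g"))
  expect_error(filter_records(r, list(bogus = TRUE)), "unknown filter rule")
})

test_that("trait CSV round-trips through the schema with aliases", {
  r <- generate_dataset(synthetic_config(seed = 3, n_sites = 4,
                                         n_species_per_site = 5))
  tmp <- tempfile(fileext = ".csv")
  write_trait_csv(r, tmp)
  back <- read_trait_csv(tmp)
  expect_equal(back$dry_mass_g, r$dry_mass_g, tolerance = 1e-12)
  expect_equal(back$species, r$species)

  # alias mapping file
  amap <- tempfile(fileext = ".txt")
  writeLines(c("# source-db aliases", "LeafArea: leaf_area_cm2",
               "DryMass_g: dry_mass_g"), amap)
  src <- tempfile(fileext = ".csv")
  write.csv(data.frame(species = "x", site_id = "s", LeafArea = 12,
                       DryMass_g = 0.3), src, row.names = FALSE)
  tr <- read_trait_csv(src, alias = amap)
  expect_equal(tr$leaf_area_cm2, 12)
  expect_equal(tr$dry_mass_g, 0.3)
  expect_true(all(trait_schema() %in% names(tr)))
})

test_that("harmonize_records attaches growing-season temperature and zone", {
  cfg <- synthetic_config(seed = 12, n_sites = 5, n_species_per_site = 4)
  climate <- generate_monthly_climate(cfg)
  r <- generate_dataset(cfg)
  r$temp_growing_season_c <- NA_real_
  r$zone <- NULL
  h <- harmonize_records(r, climate = climate)
  gs <- growing_season_by_site(climate)
  expect_equal(h$temp_growing_season_c,
               gs$temp_growing_season_c[match(h$site_id, gs$site_id)])
  expect_true(all(h$zone %in% c("tropical", "temperate", "boreal")))
  expect_equal(as.character(h$zone),
               as.character(assign_latitudinal_zone(h$latitude)))
})
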