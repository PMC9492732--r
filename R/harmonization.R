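#' @title Harmonizing heterogeneous leaf-trait records
#' @description
#' Turns raw trait tables into the analysis table: derived water content and
#' water mass, unit conversions, species-site means, growing-season
#' temperature, growth-form / ecosystem / latitudinal-zone labels, and
#' rule-based filtering with an exclusion log. Input and output are plain
#' CSV with a fixed column schema; a column-alias mapping file absorbs the
#' naming differences among source databases.
#' @name harmonization
NULL

growth_forms <- c("tree", "shrub", "graminoid", "forb", "other")
ecosystem_types <- c("forest", "grassland", "desert", "tundra", "wetland", "other")
zone_levels <- c("tropical", "temperate", "boreal")

#' Column schema of the harmonized trait table
#'
#' @return Character vector of canonical column names. Numeric trait columns
#'   carry their unit in the name (e.g. `leaf_area_cm2`, `dry_mass_g`,
#'   `photo_area_umol_m2_s`); `lwc` is dry-mass-based (g water g^-1 dry
#'   mass), `ldmc` fresh-mass-based (g dry g^-1 fresh).
#' @export
trait_schema <- function() {
  c("species", "site_id", "latitude", "growth_form", "ecosystem",
    "leaf_area_cm2", "dry_mass_g", "fresh_mass_g", "ldmc", "lwc",
    "water_mass_g", "photo_area_umol_m2_s", "photo_mass_nmol_g_s",
    "whole_leaf_photo_nmol_s", "sla_cm2_g", "lma_g_cm2",
    "leaf_n_mass_g", "leaf_p_mass_g",
    "temp_measurement_c", "temp_growing_season_c",
    "flag_greenhouse", "flag_fertilised", "flag_polluted")
}

.character_cols <- c("species", "site_id", "growth_form", "ecosystem")
.flag_cols <- c("flag_greenhouse", "flag_fertilised", "flag_polluted")

#' Read a column-alias mapping file
#'
#' Plain-text file with one `source_name: schema_name` pair per line
#' (blank lines and `#` comments ignored), used to rename source-database
#' columns to the canonical [trait_schema()] names.
#'
#' @param path Path to the mapping file.
#' @return Named character vector: names are source columns, values schema
#'   columns.
#' @export
read_alias_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, ":", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("malformed alias line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  map <- trimws(vapply(parts, `[`, "", 2L))
  names(map) <- trimws(vapply(parts, `[`, "", 1L))
  unknown <- setdiff(map, trait_schema())
  if (length(unknown)) {
    stop("alias map targets unknown schema columns: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  map
}

#' Read a trait table from CSV
#'
#' Reads a UTF-8 CSV with a header row, optionally renames columns through an
#' alias map, adds any missing schema columns as `NA`, and coerces types.
#' Extra columns are kept.
#'
#' @param path CSV path.
#' @param alias A named character vector from [read_alias_map()], or a path
#'   to an alias mapping file, or `NULL`.
#' @return A `data.frame` with at least the [trait_schema()] columns.
#' @export
read_trait_csv <- function(path, alias = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (is.character(alias) && length(alias) == 1L && file.exists(alias)) {
    alias <- read_alias_map(alias)
  }
  if (!is.null(alias)) {
    hit <- names(df) %in% names(alias)
    names(df)[hit] <- unname(alias[names(df)[hit]])
  }
  for (col in setdiff(trait_schema(), names(df))) {
    df[[col]] <- if (col %in% .character_cols) NA_character_
                 else if (col %in% .flag_cols) FALSE else NA_real_
  }
  for (col in .flag_cols) df[[col]] <- as.logical(df[[col]]) %in% TRUE
  num_cols <- setdiff(trait_schema(), c(.character_cols, .flag_cols))
  for (col in num_cols) df[[col]] <- as.numeric(df[[col]])
  df
}

#' Write a trait table to CSV
#'
#' @param records Trait table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Dry-mass-based water content from leaf dry matter content
#'
#' LDMC is dry mass per unit fresh mass; the dry-mass-based water content is
#' `(1 - ldmc) / ldmc`. The inverse relation `ldmc = 1/(1 + lwc)` holds to
#' machine precision.
#'
#' @param ldmc Leaf dry matter content (g dry g^-1 fresh), in (0, 1].
#' @return LWC (g water g^-1 dry mass).
#' @export
lwc_from_ldmc <- function(ldmc) {
  stopifnot(is.numeric(ldmc))
  bad <- !is.na(ldmc) & (ldmc <= 0 | ldmc > 1)
  if (any(bad)) stop("'ldmc' must lie in (0, 1]", call. = FALSE)
  (1 - ldmc) / ldmc
}

#' Water content and water mass from fresh and dry mass
#'
#' @param fresh Leaf fresh mass (g); must be at least `dry`.
#' @param dry Leaf dry mass (g); positive.
#' @return List with `lwc` (g g^-1, dry-mass basis) and `water_mass` (g).
#' @export
lwc_and_water_mass_from_masses <- function(fresh, dry) {
  stopifnot(is.numeric(fresh), is.numeric(dry))
  ok <- !is.na(fresh) & !is.na(dry)
  if (any(ok & dry <= 0)) stop("'dry' mass must be positive", call. = FALSE)
  if (any(ok & fresh < dry)) {
    stop("fresh mass below dry mass: inconsistent record", call. = FALSE)
  }
  water <- fresh - dry
  list(lwc = water / dry, water_mass = water)
}

#' Mass-specific photosynthesis from an area-based rate
#'
#' Multiplies an area-based photosynthetic rate (umol m^-2 s^-1) by SLA in
#' m^2 kg^-1; the units resolve exactly to nmol g^-1 s^-1
#' (umol kg^-1 s^-1 = nmol g^-1 s^-1).
#'
#' @param area_rate Area-based light-saturated photosynthesis
#'   (umol m^-2 s^-1), non-negative.
#' @param sla_m2_kg Specific leaf area in m^2 kg^-1 (divide cm^2 g^-1 by 10).
#' @return Mass-specific photosynthesis (nmol g^-1 s^-1).
#' @export
mass_specific_photosynthesis <- function(area_rate, sla_m2_kg) {
  stopifnot(is.numeric(area_rate), is.numeric(sla_m2_kg))
  if (any(area_rate < 0, na.rm = TRUE) || any(sla_m2_kg < 0, na.rm = TRUE)) {
    stop("rates and SLA must be non-negative", call. = FALSE)
  }
  area_rate * sla_m2_kg
}

#' Growing-season mean temperature from monthly means
#'
#' Growing-season months are months with mean temperature strictly greater
#' than 4.99 degrees C; the growing-season temperature is their arithmetic
#' mean. A site where no month qualifies has no growing season and the
#' result is `NA` (such records are excluded from SLA model fitting).
#'
#' @param monthly_mean_temp Numeric vector of exactly 12 monthly mean
#'   temperatures (degrees C).
#' @return Mean over qualifying months (degrees C), or `NA_real_`.
#' @export
growing_season_temperature <- function(monthly_mean_temp) {
  stopifnot(is.numeric(monthly_mean_temp))
  if (length(monthly_mean_temp) != 12L) {
    stop("a climate series has exactly 12 monthly values", call. = FALSE)
  }
  grow <- monthly_mean_temp[monthly_mean_temp > 4.99]
  if (!length(grow)) return(NA_real_)
  mean(grow)
}

#' Growing-season temperature for a climate table
#'
#' @param climate Data frame with `site_id` and monthly columns
#'   `m01`..`m12` (degrees C), as written by [generate_monthly_climate()].
#' @return Data frame with `site_id` and `temp_growing_season_c` (`NA` where
#'   no month exceeds 4.99 degrees C).
#' @export
growing_season_by_site <- function(climate) {
  mcols <- sprintf("m%02d", 1:12)
  stopifnot(all(c("site_id", mcols) %in% names(climate)))
  data.frame(
    site_id = climate$site_id,
    temp_growing_season_c = apply(as.matrix(climate[, mcols]), 1,
                                  growing_season_temperature),
    stringsAsFactors = FALSE)
}

#' Assign a latitudinal zone
#'
#' Zones by absolute latitude: tropical `[0, 25)`, temperate `[25, 50)`,
#' boreal `[50, 90]`. Boundaries are half-open with 25 and 50 belonging to
#' the higher-latitude zone.
#'
#' @param latitude Latitude in degrees, signed; `|latitude| <= 90`.
#' @return Factor with levels tropical, temperate, boreal.
#' @export
assign_latitudinal_zone <- function(latitude) {
  stopifnot(is.numeric(latitude))
  a <- abs(latitude)
  if (any(a > 90, na.rm = TRUE)) stop("|latitude| must not exceed 90", call. = FALSE)
  z <- ifelse(a < 25, "tropical", ifelse(a < 50, "temperate", "boreal"))
  factor(z, levels = zone_levels)
}

#' Fill derivable trait fields
#'
#' Derives, where the inputs are present and the target is missing:
#' `lwc` and `water_mass_g` from fresh and dry mass, else `lwc` from `ldmc`;
#' `ldmc` from `lwc`; `water_mass_g` from `lwc` and dry mass; `sla_cm2_g`
#' from area and dry mass; `lma_g_cm2` as its inverse;
#' `photo_mass_nmol_g_s` from the area-based rate times SLA (m^2 kg^-1);
#' `whole_leaf_photo_nmol_s` as mass-specific rate times dry mass.
#' Derivation happens per record, before any averaging.
#'
#' @param records Trait table with [trait_schema()] columns.
#' @return The table with derived fields filled.
#' @export
derive_traits <- function(records) {
  r <- records
  # water: masses take precedence over LDMC
  has_mass <- !is.na(r$fresh_mass_g) & !is.na(r$dry_mass_g) & r$dry_mass_g > 0
  if (any(has_mass)) {
    w <- lwc_and_water_mass_from_masses(r$fresh_mass_g[has_mass],
                                        r$dry_mass_g[has_mass])
    fill <- is.na(r$lwc[has_mass])
    r$lwc[has_mass][fill] <- w$lwc[fill]
    fillw <- is.na(r$water_mass_g[has_mass])
    r$water_mass_g[has_mass][fillw] <- w$water_mass[fillw]
  }
  use_ldmc <- is.na(r$lwc) & !is.na(r$ldmc)
  if (any(use_ldmc)) r$lwc[use_ldmc] <- lwc_from_ldmc(r$ldmc[use_ldmc])
  back <- is.na(r$ldmc) & !is.na(r$lwc)
  r$ldmc[back] <- 1 / (1 + r$lwc[back])
  mw <- is.na(r$water_mass_g) & !is.na(r$lwc) & !is.na(r$dry_mass_g)
  r$water_mass_g[mw] <- r$lwc[mw] * r$dry_mass_g[mw]
  # area economics
  s <- is.na(r$sla_cm2_g) & !is.na(r$leaf_area_cm2) & !is.na(r$dry_mass_g) &
    r$dry_mass_g > 0
  r$sla_cm2_g[s] <- r$leaf_area_cm2[s] / r$dry_mass_g[s]
  a <- is.na(r$leaf_area_cm2) & !is.na(r$sla_cm2_g) & !is.na(r$dry_mass_g)
  r$leaf_area_cm2[a] <- r$sla_cm2_g[a] * r$dry_mass_g[a]
  l <- is.na(r$lma_g_cm2) & !is.na(r$sla_cm2_g) & r$sla_cm2_g > 0
  r$lma_g_cm2[l] <- 1 / r$sla_cm2_g[l]
  # photosynthesis
  pm <- is.na(r$photo_mass_nmol_g_s) & !is.na(r$photo_area_umol_m2_s) &
    !is.na(r$sla_cm2_g)
  r$photo_mass_nmol_g_s[pm] <-
    mass_specific_photosynthesis(r$photo_area_umol_m2_s[pm],
                                 r$sla_cm2_g[pm] / 10)
  pl <- is.na(r$whole_leaf_photo_nmol_s) & !is.na(r$photo_mass_nmol_g_s) &
    !is.na(r$dry_mass_g)
  r$whole_leaf_photo_nmol_s[pl] <-
    r$photo_mass_nmol_g_s[pl] * r$dry_mass_g[pl]
  r
}

#' Harmonize raw trait records
#'
#' Validates units, fills derivable fields ([derive_traits()]), attaches the
#' growing-season temperature from a climate table, and adds the `zone`
#' label from latitude.
#'
#' @param records Raw trait table (schema columns; see [read_trait_csv()]).
#' @param climate Optional climate table (see [growing_season_by_site()]).
#' @return Harmonized trait table with an added `zone` column.
#' @export
harmonize_records <- function(records, climate = NULL) {
  r <- records
  missing_cols <- setdiff(trait_schema(), names(r))
  if (length(missing_cols)) {
    stop("records lack schema columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  neg <- c("leaf_area_cm2", "dry_mass_g", "fresh_mass_g", "water_mass_g",
           "photo_area_umol_m2_s", "photo_mass_nmol_g_s",
           "whole_leaf_photo_nmol_s", "sla_cm2_g", "lma_g_cm2",
           "leaf_n_mass_g", "leaf_p_mass_g")
  for (col in neg) {
    if (any(r[[col]] < 0, na.rm = TRUE)) {
      stop("negative values in ", col, call. = FALSE)
    }
  }
  if (any(!is.na(r$ldmc) & (r$ldmc <= 0 | r$ldmc > 1))) {
    stop("'ldmc' outside (0, 1]", call. = FALSE)
  }
  r <- derive_traits(r)
  if (!is.null(climate)) {
    gs <- growing_season_by_site(climate)
    m <- match(r$site_id, gs$site_id)
    fill <- is.na(r$temp_growing_season_c) & !is.na(m)
    r$temp_growing_season_c[fill] <- gs$temp_growing_season_c[m[fill]]
  }
  r$zone <- assign_latitudinal_zone(r$latitude)
  r
}

#' Species-site mean trait values
#'
#' Averages every numeric trait arithmetically on its original (non-log)
#' scale within each (species, site) group, after per-record derivation.
#' Species are never averaged across sites, so a species occurring at two
#' sites yields two rows. Categorical labels must be constant within a
#' group.
#'
#' @param records Harmonized trait table.
#' @return One row per (species, site).
#' @export
aggregate_species_site_means <- function(records) {
  r <- records
  key <- interaction(r$species, r$site_id, drop = TRUE)
  cat_cols <- intersect(c("growth_form", "ecosystem", "zone"), names(r))
  for (col in cat_cols) {
    n_lab <- tapply(as.character(r[[col]]), key,
                    function(v) length(unique(v[!is.na(v)])))
    if (any(n_lab > 1, na.rm = TRUE)) {
      stop("conflicting '", col, "' labels within a species-site group",
           call. = FALSE)
    }
  }
  num_cols <- names(r)[vapply(r, is.numeric, logical(1))]
  groups <- split(seq_len(nrow(r)), key)
  out <- lapply(groups, function(ii) {
    row <- r[ii[1], , drop = FALSE]
    for (col in num_cols) {
      v <- r[[col]][ii]
      row[[col]] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter trait records by analysis rules
#'
#' Applies the inclusion rules and returns the kept rows together with an
#' exclusion log. Known rules:
#' \describe{
#'   \item{`require_fields`}{character vector of schema columns that must be
#'     non-missing (the "concurrently measured" requirement); the special
#'     name `"water"` requires any of `lwc`, `ldmc`, or both masses.}
#'   \item{`natural_site`}{if `TRUE`, drop rows flagged greenhouse,
#'     fertilised or polluted.}
#'   \item{`species_known`}{if `TRUE`, drop rows with a missing or empty
#'     species name.}
#' }
#' A row is logged under the first rule it fails. The kept row count plus
#' the exclusion-log counts always sum to the input row count.
#'
#' @param records Trait table.
#' @param rules Named list of rules.
#' @return List with `records` (kept rows), `exclusion_log` (data frame of
#'   reason and count), and `audit` (per-row kept flag and failure reason).
#' @export
filter_records <- function(records,
                           rules = list(species_known = TRUE,
                                        natural_site = TRUE)) {
  known <- c("require_fields", "natural_site", "species_known")
  bad <- setdiff(names(rules), known)
  if (length(bad)) {
    stop("unknown filter rule(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  mark <- function(fail, why) {
    reason[is.na(reason) & fail] <<- why
  }
  if (isTRUE(rules$species_known)) {
    mark(is.na(records$species) | !nzchar(trimws(records$species)),
         "species identification lacking")
  }
  if (isTRUE(rules$natural_site)) {
    mark(records$flag_greenhouse %in% TRUE, "grown in greenhouse")
    mark(records$flag_fertilised %in% TRUE, "fertilised")
    mark(records$flag_polluted %in% TRUE, "polluted site")
  }
  for (f in rules$require_fields) {
    if (f == "water") {
      has_water <- !is.na(records$lwc) | !is.na(records$ldmc) |
        (!is.na(records$fresh_mass_g) & !is.na(records$dry_mass_g))
      mark(!has_water, "no water measurement")
    } else {
      if (!f %in% names(records)) {
        stop("rule requires unknown column: ", f, call. = FALSE)
      }
      mark(is.na(records[[f]]), paste0("missing ", f))
    }
  }
  keep <- is.na(reason)
  log_tab <- table(reason[!keep])
  exclusion_log <- data.frame(reason = names(log_tab),
                              count = as.integer(log_tab),
                              stringsAsFactors = FALSE)
  list(records = records[keep, , drop = FALSE],
       exclusion_log = exclusion_log,
       audit = data.frame(row = seq_len(n), kept = keep,
                          reason = reason, stringsAsFactors = FALSE))
}
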