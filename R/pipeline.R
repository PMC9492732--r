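#' @title Full scaling analysis pipeline
#' @description
#' Orchestrates the analysis: estimate the correction parameters on pooled
#' records, apply the temperature-and-water correction to the whole-leaf
#' trait, fit SMA scaling relationships per group before and after
#' correction, test the corrected exponents against isometry, and quantify
#' LOWESS curvature. A companion comparison ranks leaf nitrogen, phosphorus
#' and water mass as predictors of whole-leaf photosynthesis and area.
#' @name pipeline
NULL

pkg_version <- function() {
  as.character(utils::packageVersion("leafscale"))
}

records_hash <- function(records) {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  utils::write.csv(records, f, row.names = FALSE)
  unname(tools::md5sum(f))
}

.trait_pair_spec <- function(records, trait_pair) {
  switch(trait_pair,
    area = list(
      trait_col = "leaf_area_cm2",
      temp = celsius_to_kelvin(records$temp_growing_season_c),
      label = "leaf area (cm^2)"),
    photosynthesis = list(
      trait_col = "whole_leaf_photo_nmol_s",
      temp = celsius_to_kelvin(records$temp_measurement_c),
      label = "whole-leaf photosynthesis (nmol s^-1)"),
    stop("'trait_pair' must be \"area\" or \"photosynthesis\"", call. = FALSE))
}

#' Group-wise scaling analysis before and after correction
#'
#' For the chosen whole-leaf trait (leaf area or whole-leaf photosynthesis):
#' (1) fit the joint saturation-times-Arrhenius model on the pooled
#' mass-specific trait to estimate `(g, k1, K1, E)` — leaf area uses the
#' growing-season temperature, photosynthesis the measurement temperature;
#' (2) apply [full_correct()] to the whole-leaf trait; (3) SMA-fit the log
#' trait against log dry mass within each group, before and after
#' correction; (4) test each corrected slope against 1 and compute LOWESS
#' curvature indices. Correction parameters are estimated once on pooled
#' data and applied uniformly to all groups unless `per_group_fit = TRUE`.
#'
#' @param records Harmonized trait table (see [harmonize_records()] or
#'   [generate_dataset()]).
#' @param trait_pair `"area"` (leaf area vs dry mass) or `"photosynthesis"`
#'   (whole-leaf photosynthesis vs dry mass).
#' @param grouping `"pooled"`, `"growth_form"`, `"ecosystem"` or `"zone"`.
#' @param conf_level Confidence level for SMA intervals.
#' @param per_group_fit Refit the correction parameters within each group
#'   instead of reusing the pooled fit.
#' @param seed Optional integer recorded in the provenance block (the
#'   analysis itself is deterministic).
#' @param low_n Groups smaller than this are flagged rather than dropped.
#' @return An object of class `"scaling_report"`: `grouping`, `trait_pair`,
#'   `rows` (per-group data frame with n, uncorrected and corrected alpha,
#'   CIs, r^2, p-value of the corrected slope against 1, curvature before and
#'   after, low-n flag), `params` (pooled [model_params()] used for the
#'   correction), `fit` (the pooled `"saturation_fit"`), `provenance`.
#' @export
run_scaling_analysis <- function(records, trait_pair = c("area", "photosynthesis"),
                                 grouping = c("pooled", "growth_form",
                                              "ecosystem", "zone"),
                                 conf_level = 0.95, per_group_fit = FALSE,
                                 seed = NA_integer_, low_n = 20L) {
  trait_pair <- match.arg(trait_pair)
  grouping <- match.arg(grouping)
  spec <- .trait_pair_spec(records, trait_pair)
  trait <- records[[spec$trait_col]]
  ml <- records$dry_mass_g
  lwc <- records$lwc
  ok <- is.finite(trait) & trait > 0 & is.finite(ml) & ml > 0 &
    is.finite(lwc) & lwc >= 0 & is.finite(spec$temp) & spec$temp > 0
  n_dropped <- sum(!ok)
  if (n_dropped) {
    message(sprintf("run_scaling_analysis: dropped %d incomplete record(s)",
                    n_dropped))
  }
  r <- records[ok, , drop = FALSE]
  trait <- trait[ok]; ml <- ml[ok]; lwc <- lwc[ok]
  temp_k <- spec$temp[ok]

  ln_rate <- log(trait / ml)           # mass-specific trait, ln scale
  ikt <- inverse_kt(temp_k)
  pooled_fit <- fit_full_model(lwc, ikt, ln_rate)

  groups <- if (grouping == "pooled") {
    factor(rep("pooled", nrow(r)))
  } else {
    factor(as.character(r[[grouping]]))
  }

  fit_group <- function(ii) {
    fit <- pooled_fit
    if (per_group_fit && grouping != "pooled") {
      fit <- fit_full_model(lwc[ii], ikt[ii], ln_rate[ii])
    }
    corrected <- full_correct(trait[ii], lwc[ii], temp_k[ii], fit$params)
    x <- log(ml[ii])
    y0 <- log(trait[ii])
    y1 <- log(corrected)
    if (length(ii) < 3L) {
      # too few records even for a line: keep the group, flag it
      return(data.frame(group = NA_character_, n = length(ii),
                        alpha_uncorrected = NA_real_,
                        alpha_unc_lower = NA_real_, alpha_unc_upper = NA_real_,
                        r2_uncorrected = NA_real_,
                        alpha_corrected = NA_real_,
                        alpha_cor_lower = NA_real_, alpha_cor_upper = NA_real_,
                        r2_corrected = NA_real_,
                        p_vs_1_corrected = NA_real_,
                        curvature_before = NA_real_,
                        curvature_after = NA_real_,
                        low_n = TRUE, stringsAsFactors = FALSE))
    }
    f0 <- sma_fit(x, y0, conf_level)
    f1 <- sma_fit(x, y1, conf_level)
    curv <- function(y) {
      if (length(ii) >= 10L) curvature_index(x, y) else NA_real_
    }
    data.frame(
      group = NA_character_,
      n = f1$n,
      alpha_uncorrected = f0$alpha,
      alpha_unc_lower = f0$alpha_ci[["lower"]],
      alpha_unc_upper = f0$alpha_ci[["upper"]],
      r2_uncorrected = f0$r2,
      alpha_corrected = f1$alpha,
      alpha_cor_lower = f1$alpha_ci[["lower"]],
      alpha_cor_upper = f1$alpha_ci[["upper"]],
      r2_corrected = f1$r2,
      p_vs_1_corrected = sma_slope_test(f1, x, y1, 1),
      curvature_before = curv(y0),
      curvature_after = curv(y1),
      low_n = length(ii) < low_n,
      stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, lapply(levels(groups), function(g) {
    ii <- which(groups == g)
    out <- fit_group(ii)
    out$group <- g
    out
  }))
  rownames(rows) <- NULL
  structure(list(
    grouping = grouping, trait_pair = trait_pair, rows = rows,
    params = pooled_fit$params, fit = pooled_fit,
    provenance = list(input_hash = records_hash(records),
                      n_records = nrow(r), n_dropped = n_dropped,
                      seed = seed, version = pkg_version())),
    class = "scaling_report")
}

#' @export
print.scaling_report <- function(x, ...) {
  cat(sprintf("Scaling report: %s vs dry mass, grouping = %s (n = %d)\n",
              x$trait_pair, x$grouping, x$provenance$n_records))
  cat(sprintf("  correction: k1 = %.3f, K1 = %.3f g g^-1, E = %.3f eV\n",
              x$params$k1, x$params$K1, x$params$E))
  df <- x$rows
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-10s n=%5d  alpha %.3f [%.3f, %.3f] -> %.3f [%.3f, %.3f]  r2 %.2f -> %.2f%s\n",
                df$group[i], df$n[i],
                df$alpha_uncorrected[i], df$alpha_unc_lower[i], df$alpha_unc_upper[i],
                df$alpha_corrected[i], df$alpha_cor_lower[i], df$alpha_cor_upper[i],
                df$r2_uncorrected[i], df$r2_corrected[i],
                if (df$low_n[i]) " [low n]" else ""))
  }
  invisible(x)
}

#' Compare nitrogen, phosphorus and water mass as whole-leaf predictors
#'
#' Fits the six SMA scaling relationships of whole-leaf photosynthesis and
#' leaf area against leaf nitrogen mass, phosphorus mass and water mass, with
#' LOWESS curvature indices, and declares per response the predictor with
#' the highest r^2 and the one with the lowest curvature.
#'
#' @param records Harmonized trait table containing
#'   `whole_leaf_photo_nmol_s`, `leaf_area_cm2`, `leaf_n_mass_g`,
#'   `leaf_p_mass_g`, `water_mass_g`.
#' @param conf_level Confidence level for SMA intervals.
#' @return An object of class `"predictor_comparison"`: `fits` (data frame
#'   of six rows: response, predictor, n, alpha, CI, r2, curvature),
#'   `best` (per response: predictor with highest r2 / lowest curvature),
#'   `provenance`.
#' @export
run_predictor_comparison <- function(records, conf_level = 0.95) {
  responses <- c(photosynthesis = "whole_leaf_photo_nmol_s",
                 area = "leaf_area_cm2")
  predictors <- c(nitrogen = "leaf_n_mass_g",
                  phosphorus = "leaf_p_mass_g",
                  water = "water_mass_g")
  missing_cols <- setdiff(c(responses, predictors), names(records))
  if (length(missing_cols)) {
    stop("configuration error: records lack column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  fits <- list()
  for (rn in names(responses)) {
    for (pn in names(predictors)) {
      y <- records[[responses[[rn]]]]
      x <- records[[predictors[[pn]]]]
      ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
      f <- sma_fit(log(x[ok]), log(y[ok]), conf_level)
      cv <- curvature_index(log(x[ok]), log(y[ok]))
      fits[[paste(rn, pn, sep = "_")]] <- data.frame(
        response = rn, predictor = pn, n = f$n,
        alpha = f$alpha,
        alpha_lower = f$alpha_ci[["lower"]],
        alpha_upper = f$alpha_ci[["upper"]],
        r2 = f$r2, curvature = cv, stringsAsFactors = FALSE)
    }
  }
  fits <- do.call(rbind, fits)
  rownames(fits) <- NULL
  best <- do.call(rbind, lapply(names(responses), function(rn) {
    sub <- fits[fits$response == rn, ]
    data.frame(response = rn,
               best_r2 = sub$predictor[which.max(sub$r2)],
               lowest_curvature = sub$predictor[which.min(sub$curvature)],
               stringsAsFactors = FALSE)
  }))
  structure(list(fits = fits, best = best,
                 provenance = list(input_hash = records_hash(records),
                                   version = pkg_version())),
            class = "predictor_comparison")
}

#' @export
print.predictor_comparison <- function(x, ...) {
  cat("Whole-leaf predictor comparison (SMA on log-log axes)\n")
  df <- x$fits
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-15s vs %-10s n=%4d  alpha %.3f [%.3f, %.3f]  r2 %.3f  curvature %.4f\n",
                df$response[i], df$predictor[i], df$n[i], df$alpha[i],
                df$alpha_lower[i], df$alpha_upper[i], df$r2[i],
                df$curvature[i]))
  }
  for (i in seq_len(nrow(x$best))) {
    cat(sprintf("  best for %s: %s (r2), %s (curvature)\n",
                x$best$response[i], x$best$best_r2[i],
                x$best$lowest_curvature[i]))
  }
  invisible(x)
}

#' Write analysis reports to disk
#'
#' Writes each report's per-group/per-fit table as CSV and a machine-readable
#' JSON summary with provenance (input hashes, seeds, correction parameter
#' estimates, package version). Re-running with identical inputs reproduces
#' the files byte-identically.
#'
#' @param reports A list of `"scaling_report"` and/or
#'   `"predictor_comparison"` objects (possibly empty).
#' @param output_dir Output directory; created if needed.
#' @return Character vector of file paths written, invisibly.
#' @export
run_report <- function(reports, output_dir) {
  stopifnot(is.list(reports))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) stop("cannot create output dir", call. = FALSE)
  written <- character(0)
  summary <- list(version = pkg_version(), reports = list())
  for (i in seq_along(reports)) {
    rep <- reports[[i]]
    if (inherits(rep, "scaling_report")) {
      fname <- sprintf("scaling_%s_%s.csv", rep$trait_pair, rep$grouping)
      path <- file.path(output_dir, fname)
      utils::write.csv(rep$rows, path, row.names = FALSE)
      written <- c(written, path)
      summary$reports[[length(summary$reports) + 1L]] <- list(
        type = "scaling", trait_pair = rep$trait_pair,
        grouping = rep$grouping, table = fname,
        params = rep$params[c("g", "k1", "K1", "E")],
        provenance = rep$provenance)
    } else if (inherits(rep, "predictor_comparison")) {
      fname <- sprintf("predictor_comparison_%d.csv", i)
      path <- file.path(output_dir, fname)
      utils::write.csv(rep$fits, path, row.names = FALSE)
      written <- c(written, path)
      summary$reports[[length(summary$reports) + 1L]] <- list(
        type = "predictor_comparison", table = fname,
        best = rep$best, provenance = rep$provenance)
    } else {
      stop("unsupported report object of class ",
           paste(class(rep), collapse = "/"), call. = FALSE)
    }
  }
  spath <- file.path(output_dir, "summary.json")
  jsonlite::write_json(summary, spath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  written <- c(written, spath)
  invisible(written)
}
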