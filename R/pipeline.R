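#' Run the full association analysis on a study
#'
#' Executes the whole pipeline on a synthetic study or a study directory
#' layout read by [read_study()]: assigns samples to zones, computes
#' per-zone geometric means, fits study-wide decile scorers and the zone
#' mean soil metal index, derives internal standard rates and zone SIRs,
#' rebuilds the six-domain deprivation index and its zone median deciles,
#' then produces (i) the soil-metal correlation matrix, (ii) the mixed
#' SIR / index / deprivation / air correlation matrix, and (iii) nested
#' log-link GLM candidates (soil term only; + deprivation; + air) with the
#' minimum-AIC fit selected.
#'
#' @param study A `synthetic_study` or the list returned by [read_study()].
#' @param soil_covariate `"index_mean"` (the composite index, default) or
#'   one metal's geometric-mean column (`"As"`, `"Cr"`, `"Cu"`, `"Ni"`,
#'   `"Pb"`, `"Se"`, `"Zn"`, `"K"`).
#' @param air `"no2"` (default) or `"pm10"`; never both, given their
#'   near-collinearity.
#' @param family GLM family, see [fit_sir_glm()].
#' @param rates Optional external [standard_rates()]; default derives
#'   internal rates from the study itself (requires `cases_by_stratum`).
#' @param alpha Significance level for correlation flags.
#' @return An object of class `sir_analysis`: list with `zone_table`,
#'   `scorers`, `standard_rates`, `sir`, `correlations_metals`,
#'   `correlations_mixed`, `candidates` (nested GLM fits) and `best_fit`.
#' @export
#' @examples
#' study <- generate_study(synth_config(seed = 3, n_zones = 24))
#' res <- run_analysis(study)
#' res$best_fit
run_analysis <- function(study,
                         soil_covariate = "index_mean",
                         air = c("no2", "pm10"),
                         family = c("poisson_offset", "gaussian_log"),
                         rates = NULL,
                         alpha = 0.05) {
  air <- match.arg(air)
  family <- match.arg(family)
  zones <- study$zones
  soil <- study$soil

  if (!"zone_id" %in% names(soil) || anyNA(soil$zone_id)) {
    soil <- assign_zones(soil, zones)
  }
  zsum <- summarise_zones(soil, zone_ids = zones$zone_id)

  scorers <- lapply(setNames(CLEA_METALS, CLEA_METALS), function(m) {
    fit_decile_scorer(soil[[m]], m)
  })
  sample_idx <- score_samples(soil, scorers)
  zidx <- zone_mean_index(sample_idx, zone_ids = zones$zone_id)

  if (is.null(rates)) {
    if (is.null(study$cases_by_stratum)) {
      stop("input error: internal standardisation needs cases_by_stratum; ",
           "supply external `rates` otherwise", call. = FALSE)
    }
    rates <- derive_standard_rates(study$population, study$cases_by_stratum)
  }
  sir <- compute_sir(study$population, rates, study$cases)

  composite <- combine_domains(study$deprivation_domains,
                               weights = simd_weights())
  dz_decile <- data.frame(
    datazone_id = study$deprivation_domains$datazone_id,
    zone_id = study$deprivation_domains$zone_id,
    decile = to_deciles(composite$composite_rank),
    stringsAsFactors = FALSE
  )
  zdec <- zone_median_decile(dz_decile, zone_ids = zones$zone_id)

  zone_table <- data.frame(
    zone_id = zones$zone_id,
    urban = zones$urban,
    n_samples = zsum$n_samples[match(zones$zone_id, zsum$zone_id)],
    stringsAsFactors = FALSE
  )
  for (el in intersect(ALL_ELEMENTS, names(zsum))) {
    zone_table[[el]] <- zsum[[el]][match(zones$zone_id, zsum$zone_id)]
  }
  zone_table$index_mean <- zidx$index_mean[match(zones$zone_id,
                                                 zidx$zone_id)]
  zone_table$no2 <- study$air$no2[match(zones$zone_id, study$air$zone_id)]
  zone_table$pm10 <- study$air$pm10[match(zones$zone_id, study$air$zone_id)]
  zone_table$decile <- zdec$median_decile[match(zones$zone_id,
                                                zdec$zone_id)]
  zone_table$observed <- sir$observed[match(zones$zone_id, sir$zone_id)]
  zone_table$expected <- sir$expected[match(zones$zone_id, sir$zone_id)]
  zone_table$sir <- sir$sir[match(zones$zone_id, sir$zone_id)]

  cor_metals <- correlation_matrix(
    zone_table, intersect(ALL_ELEMENTS, names(zone_table)), alpha = alpha
  )
  cor_mixed <- correlation_matrix(
    zone_table, c("sir", "index_mean", "decile", "no2", "pm10"),
    alpha = alpha
  )

  candidates <- list(
    soil_only = fit_sir_glm(sir, zone_table, soil_covariate,
                            include_deprivation = FALSE,
                            include_air = FALSE, family = family),
    soil_deprivation = fit_sir_glm(sir, zone_table, soil_covariate,
                                   include_deprivation = TRUE,
                                   include_air = FALSE, family = family),
    soil_deprivation_air = fit_sir_glm(sir, zone_table, soil_covariate,
                                       air = air,
                                       include_deprivation = TRUE,
                                       include_air = TRUE, family = family)
  )
  best <- select_model(candidates)

  structure(list(
    zone_table = zone_table,
    scorers = scorers,
    standard_rates = rates,
    sir = sir,
    correlations_metals = cor_metals,
    correlations_mixed = cor_mixed,
    candidates = candidates,
    best_fit = best,
    soil_covariate = soil_covariate,
    air = air,
    family = family
  ), class = "sir_analysis")
}

#' @export
print.sir_analysis <- function(x, ...) {
  cat("Small-area association analysis\n")
  cat(sprintf("  %d zones; soil covariate '%s'; air '%s'; family %s\n",
              nrow(x$zone_table), x$soil_covariate, x$air, x$family))
  cat(sprintf("  candidate AICs: %s\n",
              paste(sprintf("%s %.2f", names(x$candidates),
                            vapply(x$candidates, function(f) f$aic,
                                   numeric(1))),
                    collapse = "; ")))
  cat("\nSelected model:\n")
  print(x$best_fit)
  invisible(x)
}

#' Write analysis outputs to a directory
#'
#' Emits `zone_table.csv`, `correlations_metals.csv`,
#' `correlations_mixed.csv`, `glm_<covariate>.csv` (the selected model's
#' coefficient table with its AIC), `scorers.json` (decile cut points for
#' audit) and a human-readable `report.md`.
#'
#' @param analysis A `sir_analysis` from [run_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  stopifnot(inherits(analysis, "sir_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(analysis$zone_table, file.path(dir, "zone_table.csv"),
            row.names = FALSE)
  write.csv(analysis$correlations_metals$pairs,
            file.path(dir, "correlations_metals.csv"), row.names = FALSE)
  write.csv(analysis$correlations_mixed$pairs,
            file.path(dir, "correlations_mixed.csv"), row.names = FALSE)
  best <- analysis$best_fit
  glm_out <- best$coef_table
  glm_out$aic <- best$aic
  write.csv(glm_out,
            file.path(dir, paste0("glm_", analysis$soil_covariate, ".csv")),
            row.names = FALSE)
  jsonlite::write_json(
    lapply(analysis$scorers, function(s) {
      list(metal = s$metal, n = s$n, cut_points = s$cut_points)
    }),
    file.path(dir, "scorers.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )

  lines <- c(
    "# Small-area association analysis report",
    "",
    sprintf("Zones analysed: %d. Soil covariate: `%s`. Air covariate: `%s`. Family: `%s`.",
            nrow(analysis$zone_table), analysis$soil_covariate,
            analysis$air, analysis$family),
    sprintf("Critical |r| at alpha = %g, n = %d: %.3f.",
            analysis$correlations_mixed$alpha,
            analysis$correlations_mixed$n,
            analysis$correlations_mixed$critical_r),
    "",
    "## Mixed correlation matrix (SIR, index, deprivation, air)",
    "",
    paste(utils::capture.output(
      print(analysis$correlations_mixed)), collapse = "\n"),
    "",
    "## Selected GLM (minimum AIC)",
    "",
    paste(utils::capture.output(print(best)), collapse = "\n"),
    ""
  )
  writeLines(lines, file.path(dir, "report.md"))
  invisible(dir)
}
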