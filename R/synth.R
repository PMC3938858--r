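# draw n rows from N(mu, Sigma) via an eigen square root; tolerates
# semi-definite Sigma (zero eigenvalues clipped)
rmvnorm_eigen <- function(n, mu, Sigma) {
  p <- length(mu)
  ev <- eigen(Sigma, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  A <- ev$vectors %*% (t(ev$vectors) * sqrt(lam))
  Z <- matrix(rnorm(n * p), n, p)
  sweep(Z %*% t(A), 2, mu, `+`)
}

#' Generate the reporting-zone layout
#'
#' Lays `n_zones` contiguous rectangular zones on a near-square grid, each
#' zone a block of `grid_shape` 1 km2 cells. The `round(urban_fraction *
#' n_zones)` zones nearest the grid centre (Chebyshev distance, ties by zone
#' index) form the central urban block; the remainder are rural.
#'
#' @param config A [synth_config()].
#' @return Data frame with one row per zone: `zone_id`, `urban` (logical),
#'   cell extents `xmin`, `xmax`, `ymin`, `ymax` (km), and `n_cells`.
#' @export
#' @examples
#' z <- generate_zones(synth_config(seed = 1, n_zones = 4, urban_fraction = 0.5))
#' table(z$urban)
generate_zones <- function(config) {
  validate_synth_config(config)
  n <- config$n_zones
  rows_km <- config$grid_shape[1]
  cols_km <- config$grid_shape[2]
  zr <- floor(sqrt(n))
  zc <- ceiling(n / zr)
  k <- seq_len(n)
  ri <- (k - 1) %/% zc + 1
  ci <- (k - 1) %% zc + 1
  centre_r <- (min(ri) + max(ri)) / 2
  centre_c <- (min(ci) + max(ci)) / 2
  cheb <- pmax(abs(ri - centre_r), abs(ci - centre_c))
  n_urban <- round(config$urban_fraction * n)
  urban <- logical(n)
  urban[order(cheb, k)[seq_len(n_urban)]] <- TRUE
  data.frame(
    zone_id = sprintf("Z%03d", k),
    urban = urban,
    xmin = (ci - 1) * cols_km,
    xmax = ci * cols_km,
    ymin = (ri - 1) * rows_km,
    ymax = ri * rows_km,
    n_cells = rows_km * cols_km,
    stringsAsFactors = FALSE
  )
}

#' Generate point soil-sample geochemistry
#'
#' Scatters samples over the zones at the configured urban/rural densities
#' (a fixed count per urban km2 cell; one Bernoulli sample per rural cell
#' when the rural density is below 1) and draws the seven metals
#' multivariate log-normal with an urban location shift. Potassium, the
#' control element, is drawn independently of the metals and is slightly
#' higher in rural soil. Every zone is guaranteed at least one sample, so
#' zone summaries exist for the whole study region.
#'
#' @param config A [synth_config()].
#' @param zones Output of [generate_zones()].
#' @return A soil sample table: `sample_id`, `x`, `y`, `zone_id`, one
#'   column per element (`As` ... `Zn` in mg/kg, `K` in wt%).
#' @export
generate_soil <- function(config, zones) {
  validate_synth_config(config)
  set.seed(component_seed(config$seed, "soil"))
  rows_km <- config$grid_shape[1]
  cols_km <- config$grid_shape[2]

  per_zone <- lapply(seq_len(nrow(zones)), function(i) {
    z <- zones[i, ]
    cells <- expand.grid(
      cx = seq(z$xmin, z$xmax - 1), cy = seq(z$ymin, z$ymax - 1),
      KEEP.OUT.ATTRS = FALSE
    )
    if (z$urban) {
      cnt <- rep(max(1L, round(config$samples_per_km2_urban)), nrow(cells))
    } else {
      d <- config$samples_per_km2_rural
      cnt <- if (d <= 1) rbinom(nrow(cells), 1L, d) else
        rep(max(1L, round(d)), nrow(cells))
      if (sum(cnt) == 0) cnt[sample.int(length(cnt), 1L)] <- 1L
    }
    if (sum(cnt) == 0) return(NULL)
    idx <- rep(seq_len(nrow(cells)), cnt)
    data.frame(
      zone_id = z$zone_id,
      urban = z$urban,
      x = cells$cx[idx] + runif(length(idx)),
      y = cells$cy[idx] + runif(length(idx)),
      stringsAsFactors = FALSE
    )
  })
  pts <- do.call(rbind, per_zone)

  n <- nrow(pts)
  logc <- matrix(NA_real_, n, length(PHE_METALS),
                 dimnames = list(NULL, PHE_METALS))
  for (grp in c(TRUE, FALSE)) {
    sel <- pts$urban == grp
    if (!any(sel)) next
    mu <- if (grp) config$metal_log_means_urban else config$metal_log_means_rural
    logc[sel, ] <- rmvnorm_eigen(sum(sel), mu, config$metal_log_cov)
  }
  conc <- exp(logc)
  k_mu <- ifelse(pts$urban, config$k_log_mean_urban, config$k_log_mean_rural)
  K <- exp(rnorm(n, k_mu, config$k_log_sd))

  out <- data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    x = pts$x, y = pts$y, zone_id = pts$zone_id,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(conc), K = K)
  rownames(out) <- NULL
  out
}

#' Generate zone-mean air pollution
#'
#' NO2 and PM10 zone means share an urban/rural shift and strongly
#' correlated zone-level noise, reproducing the near-collinearity of the
#' two pollutants typically observed across a city (r close to 0.98).
#'
#' @inheritParams generate_soil
#' @return Data frame `zone_id`, `no2`, `pm10` (ug/m3).
#' @export
generate_air <- function(config, zones) {
  validate_synth_config(config)
  set.seed(component_seed(config$seed, "air"))
  ap <- config$air_params
  n <- nrow(zones)
  z1 <- rnorm(n)
  z2 <- ap$cor * z1 + sqrt(1 - ap$cor^2) * rnorm(n)
  grp <- ifelse(zones$urban, "urban", "rural")
  no2 <- ap$no2_mean[grp] + ap$no2_sd * z1
  pm10 <- ap$pm10_mean[grp] + ap$pm10_sd * z2
  data.frame(
    zone_id = zones$zone_id,
    no2 = pmax(no2, 1), pm10 = pmax(pm10, 1),
    stringsAsFactors = FALSE
  )
}

#' Generate data-zone deprivation domain rankings
#'
#' Builds `dz_per_zone` data zones inside each zone. A latent zone
#' deprivation factor correlates with the (standardised) zone soil metal
#' index by `soil_assoc`; data zones scatter around their zone's latent
#' with sd `dz_noise_sd`. Seven domain scores (health, income, employment,
#' education, housing, access, crime) share the latent so that their
#' pairwise correlation is about `domain_cor`, and each domain is returned
#' as ranks 1..n with 1 = most deprived.
#'
#' @inheritParams generate_soil
#' @param zone_index Data frame `zone_id`, `index_mean` — the per-zone mean
#'   soil metal index (see [zone_mean_index()]).
#' @return Data frame `datazone_id`, `zone_id`, and one rank column per
#'   domain.
#' @export
generate_deprivation_domains <- function(config, zones, zone_index) {
  validate_synth_config(config)
  n_dz_total <- nrow(zones) * config$dz_per_zone
  if (n_dz_total < 10) {
    stop("configuration error: need at least 10 data zones", call. = FALSE)
  }
  set.seed(component_seed(config$seed, "deprivation"))

  idx <- zone_index$index_mean[match(zones$zone_id, zone_index$zone_id)]
  if (anyNA(idx)) {
    stop("input error: every zone needs a soil index for deprivation generation",
         call. = FALSE)
  }
  idx_std <- as.numeric(scale(idx))
  if (anyNA(idx_std)) idx_std <- rep(0, length(idx)) # constant index edge case
  a <- config$soil_assoc
  latent_zone <- a * idx_std + sqrt(max(0, 1 - a^2)) * rnorm(nrow(zones))

  dz_zone <- rep(seq_len(nrow(zones)), each = config$dz_per_zone)
  latent_dz <- latent_zone[dz_zone] + rnorm(n_dz_total, 0, config$dz_noise_sd)
  latent_dz <- as.numeric(scale(latent_dz))

  domains <- c("health", "income", "employment", "education",
               "housing", "access", "crime")
  b <- sqrt(max(0, min(1, config$domain_cor)))
  ranks <- sapply(domains, function(d) {
    score <- b * latent_dz + sqrt(1 - b^2) * rnorm(n_dz_total)
    rank(-score, ties.method = "first") # 1 = most deprived
  })
  out <- data.frame(
    datazone_id = sprintf("DZ%04d", seq_len(n_dz_total)),
    zone_id = zones$zone_id[dz_zone],
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(ranks))
}

#' Generate stratum populations and Poisson respiratory admissions
#'
#' Zone populations vary log-normally around `households_per_zone *
#' persons_per_household` and are split across age bands and sexes by the
#' configured proportions. The expected count for a zone is the sum over
#' strata of population x baseline rate x exp(linear predictor), where the
#' linear predictor applies `true_beta` to the zone's soil index,
#' deprivation decile (decile 1 = reference) and NO2. Observed counts are
#' Poisson draws, returned both by stratum and as zone totals.
#'
#' @inheritParams generate_soil
#' @param covariates Data frame `zone_id`, `index_mean`, `decile`, `no2`.
#' @return List with `population` (`zone_id`, `age_band`, `sex`, `pop`),
#'   `cases` (`zone_id`, `observed`), `cases_by_stratum`, and
#'   `expected_true` (`zone_id`, `expected`) — the generator's own expected
#'   counts, useful for calibration checks.
#' @export
generate_population_and_cases <- function(config, zones, covariates) {
  validate_synth_config(config)
  need <- c("zone_id", "index_mean", "decile", "no2")
  if (!all(need %in% names(covariates))) {
    stop("input error: covariates must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  cov <- covariates[match(zones$zone_id, covariates$zone_id), ]
  if (anyNA(cov[need])) {
    stop("input error: missing covariate value for at least one zone",
         call. = FALSE)
  }

  set.seed(component_seed(config$seed, "population"))
  mean_pop <- config$households_per_zone * config$persons_per_household
  totals <- round(mean_pop * exp(rnorm(nrow(zones), 0, config$pop_log_sd)))

  strata <- expand.grid(
    age_band = config$age_bands$label, sex = c("F", "M"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  prop <- config$age_bands$prop[match(strata$age_band, config$age_bands$label)]
  prop <- prop * ifelse(strata$sex == "F", config$sex_split,
                        1 - config$sex_split)

  population <- do.call(rbind, lapply(seq_len(nrow(zones)), function(i) {
    data.frame(
      zone_id = zones$zone_id[i],
      age_band = strata$age_band, sex = strata$sex,
      pop = round(totals[i] * prop),
      stringsAsFactors = FALSE
    )
  }))

  beta <- config$true_beta
  dec_eff <- c(0, beta$decile)[cov$decile] # decile 1 = reference
  eta <- beta$intercept + beta$soil_index * cov$index_mean +
    beta$no2 * cov$no2 + dec_eff

  rates <- config$baseline_rates
  key <- paste(population$age_band, population$sex, sep = ".")
  rate <- rates$rate[match(key, paste(rates$age_band, rates$sex, sep = "."))]
  zi <- match(population$zone_id, zones$zone_id)
  mu_stratum <- population$pop * rate / 1e5 * exp(eta[zi])

  set.seed(component_seed(config$seed, "cases"))
  obs_stratum <- rpois(length(mu_stratum), mu_stratum)

  cases_by_stratum <- data.frame(
    zone_id = population$zone_id,
    age_band = population$age_band, sex = population$sex,
    observed = obs_stratum, stringsAsFactors = FALSE
  )
  totals_by_zone <- tapply(obs_stratum, factor(population$zone_id,
                                               levels = zones$zone_id), sum)
  cases <- data.frame(
    zone_id = zones$zone_id,
    observed = as.integer(totals_by_zone),
    stringsAsFactors = FALSE
  )
  expected_true <- data.frame(
    zone_id = zones$zone_id,
    expected = as.numeric(tapply(mu_stratum, factor(population$zone_id,
                                                    levels = zones$zone_id),
                                 sum)),
    stringsAsFactors = FALSE
  )
  list(population = population, cases = cases,
       cases_by_stratum = cases_by_stratum, expected_true = expected_true)
}

#' Generate a complete synthetic study region
#'
#' Runs every generator in sequence: zones, soil geochemistry, air
#' pollution, the soil metal index (computed with the same aggregation and
#' decile-scoring machinery the analysis uses, so parameter recovery is well
#' posed), deprivation domain rankings and their zone-median deciles, and
#' finally stratum populations with Poisson admissions.
#'
#' @param config A [synth_config()], or an integer seed as shorthand.
#' @return An object of class `synthetic_study`: a list with `config`,
#'   `zones`, `soil`, `air`, `population`, `cases`, `cases_by_stratum`,
#'   `deprivation_domains`, `zone_covariates` (the covariates the cases
#'   were generated from) and `truth` (generating parameters).
#' @export
#' @examples
#' study <- generate_study(synth_config(seed = 7, n_zones = 24))
#' study
generate_study <- function(config) {
  if (is.numeric(config)) config <- synth_config(seed = config)
  validate_synth_config(config)

  zones <- generate_zones(config)
  soil <- generate_soil(config, zones)
  air <- generate_air(config, zones)

  # soil metal index exactly as the analysis computes it
  scorers <- lapply(setNames(CLEA_METALS, CLEA_METALS), function(m) {
    fit_decile_scorer(soil[[m]], m)
  })
  sample_idx <- score_samples(soil, scorers)
  zone_index <- zone_mean_index(sample_idx)

  depriv <- generate_deprivation_domains(config, zones, zone_index)
  composite <- combine_domains(depriv, weights = simd_weights())
  dz_decile <- data.frame(
    datazone_id = depriv$datazone_id, zone_id = depriv$zone_id,
    decile = to_deciles(composite$composite_rank),
    stringsAsFactors = FALSE
  )
  zone_dec <- zone_median_decile(dz_decile)

  covariates <- data.frame(
    zone_id = zones$zone_id,
    index_mean = zone_index$index_mean[match(zones$zone_id,
                                             zone_index$zone_id)],
    decile = zone_dec$median_decile[match(zones$zone_id, zone_dec$zone_id)],
    no2 = air$no2[match(zones$zone_id, air$zone_id)],
    stringsAsFactors = FALSE
  )
  pc <- generate_population_and_cases(config, zones, covariates)

  out <- list(
    config = config, zones = zones, soil = soil, air = air,
    population = pc$population, cases = pc$cases,
    cases_by_stratum = pc$cases_by_stratum,
    deprivation_domains = depriv,
    zone_covariates = covariates,
    truth = list(true_beta = config$true_beta,
                 expected_true = pc$expected_true)
  )
  class(out) <- "synthetic_study"
  out
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic small-area study\n")
  cat(sprintf("  %d zones (%d urban, %d rural); %d soil samples; %d data zones\n",
              nrow(x$zones), sum(x$zones$urban), sum(!x$zones$urban),
              nrow(x$soil), nrow(x$deprivation_domains)))
  cat(sprintf("  total population %s; total admissions %d\n",
              format(sum(x$population$pop), big.mark = ","),
              sum(x$cases$observed)))
  invisible(x)
}
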