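test_that("zone generation honours counts, urban fraction and determinism", {
  z279 <- generate_zones(synth_config(seed = 1))
  expect_equal(nrow(z279), 279)

  z4 <- generate_zones(synth_config(seed = 1, n_zones = 4,
                                    urban_fraction = 0.5))
  expect_equal(sum(z4$urban), 2)
  expect_equal(sum(!z4$urban), 2)

  again <- generate_zones(synth_config(seed = 1, n_zones = 4,
                                       urban_fraction = 0.5))
  expect_identical(z4, again)

  expect_error(synth_config(n_zones = 1), "at least 2")
  expect_error(synth_config(grid_shape = c(0, 3)), "grid_shape")
})

test_that("soil sampling densities follow the survey design", {
  cfg <- small_config()
  zones <- generate_zones(cfg)
  soil <- generate_soil(cfg, zones)

  urban_ids <- zones$zone_id[zones$urban]
  urban_km2 <- sum(zones$n_cells[zones$urban])
  n_urban <- sum(soil$zone_id %in% urban_ids)
  expect_equal(n_urban / urban_km2, 4) # fixed 4 per urban km2

  # rural density is Bernoulli(0.5) per cell: at most 1 per km2,
  # and every zone retains at least one sample
  rural_km2 <- sum(zones$n_cells[!zones$urban])
  n_rural <- sum(!(soil$zone_id %in% urban_ids))
  expect_lte(n_rural, rural_km2)
  expect_true(all(zones$zone_id %in% soil$zone_id))
  expect_true(all(soil[PHE_METALS] > 0))
  expect_false(anyDuplicated(soil$sample_id) > 0)
})

test_that("zero metal covariance gives uncorrelated metals; K independent", {
  sds <- rep(0.7, 7)
  cfg <- small_config(
    seed = 7, n_zones = 60,
    metal_log_cov = diag(sds^2, 7, 7)
  )
  zones <- generate_zones(cfg)
  soil <- generate_soil(cfg, zones)
  urban <- soil[soil$zone_id %in% zones$zone_id[zones$urban], ]
  lc <- log(as.matrix(urban[c(PHE_METALS, "K")]))
  R <- cor(lc)
  off <- R[lower.tri(R)]
  # ~700 urban samples: independence within Monte-Carlo error
  expect_lt(max(abs(off)), 4 / sqrt(nrow(urban)) + 0.02)
})

test_that("urban-rural geometric mean contrast follows the location shift", {
  # Monte-Carlo sign check over >= 20 seeds, including a flipped-shift world
  flipped <- log(c(As = 9, Cr = 107, Cu = 48, Ni = 46, Pb = 118,
                   Se = 0.9, Zn = 144))
  for (seed in 1:20) {
    cfg <- small_config(seed = seed, n_zones = 12)
    zones <- generate_zones(cfg)
    soil <- generate_soil(cfg, zones)
    urban <- soil$zone_id %in% zones$zone_id[zones$urban]
    for (m in PHE_METALS) {
      expect_gt(geometric_mean(soil[[m]][urban]),
                geometric_mean(soil[[m]][!urban]))
    }
  }
  cfg <- small_config(seed = 3, n_zones = 12,
                      metal_log_means_urban = flipped - log(3),
                      metal_log_means_rural = flipped)
  zones <- generate_zones(cfg)
  soil <- generate_soil(cfg, zones)
  urban <- soil$zone_id %in% zones$zone_id[zones$urban]
  expect_lt(geometric_mean(soil$Pb[urban]), geometric_mean(soil$Pb[!urban]))
})

test_that("log-scale sample moments converge to configured parameters", {
  cfg <- synth_config(seed = 11, n_zones = 100, urban_fraction = 1,
                      samples_per_km2_urban = 40)
  zones <- generate_zones(cfg)
  soil <- generate_soil(cfg, zones) # 12,000 urban samples
  lc <- log(as.matrix(soil[PHE_METALS]))
  expect_equal(colMeans(lc), cfg$metal_log_means_urban, tolerance = 0.02)
  expect_equal(unname(diag(cov(lc))), unname(diag(cfg$metal_log_cov)),
               tolerance = 0.05)
})

test_that("air pollution is collinear and urban-elevated", {
  study <- small_study(seed = 5, n_zones = 100)
  air <- study$air
  zones <- study$zones
  expect_gt(pearson_r(air$no2, air$pm10), 0.9)
  expect_gt(mean(air$no2[zones$urban]), mean(air$no2[!zones$urban]))
})

test_that("deprivation domain ranks are permutations with configured structure", {
  study <- small_study(seed = 9, n_zones = 30)
  dd <- study$deprivation_domains
  n <- nrow(dd)
  domains <- c("health", "income", "employment", "education",
               "housing", "access", "crime")
  for (d in domains) expect_setequal(dd[[d]], seq_len(n))

  # independence limit: domain_cor = 0 gives near-zero rank correlations
  cfg0 <- small_config(seed = 9, n_zones = 30, domain_cor = 0,
                       soil_assoc = 0)
  zones <- generate_zones(cfg0)
  soil <- generate_soil(cfg0, zones)
  scorers <- lapply(setNames(CLEA_METALS, CLEA_METALS),
                    function(m) fit_decile_scorer(soil[[m]], m))
  zidx <- zone_mean_index(score_samples(soil, scorers))
  dd0 <- generate_deprivation_domains(cfg0, zones, zidx)
  R <- cor(as.matrix(dd0[domains]), method = "spearman")
  expect_lt(max(abs(R[lower.tri(R)])), 4 / sqrt(nrow(dd0)) + 0.05)
})

test_that("soil-deprivation coupling yields a negative index-decile correlation", {
  # sign check over seeds: metal-rich zones are more deprived, and
  # decile 1 = most deprived, so the zone-level correlation is negative
  rs <- vapply(1:8, function(seed) {
    study <- small_study(seed = seed, n_zones = 40)
    cov <- study$zone_covariates
    pearson_r(cov$index_mean, cov$decile)
  }, numeric(1))
  expect_true(all(rs < 0))
})

test_that("case generation matches its stated expected-count structure", {
  study <- small_study(seed = 13)
  expect_true(all(study$cases$observed >= 0))
  expect_true(all(study$cases$observed == round(study$cases$observed)))
  # zone totals equal stratum sums
  tot <- tapply(study$cases_by_stratum$observed,
                study$cases_by_stratum$zone_id, sum)
  expect_equal(as.integer(tot[study$cases$zone_id]),
               study$cases$observed)

  # doubling every baseline rate doubles every expected count
  cfg <- small_config(seed = 13)
  zones <- generate_zones(cfg)
  cov <- study$zone_covariates
  pc1 <- generate_population_and_cases(cfg, zones, cov)
  cfg2 <- cfg
  cfg2$baseline_rates$rate <- cfg2$baseline_rates$rate * 2
  pc2 <- generate_population_and_cases(cfg2, zones, cov)
  expect_equal(pc2$expected_true$expected, 2 * pc1$expected_true$expected)

  expect_error(
    generate_population_and_cases(cfg, zones, cov[-1, ]),
    "missing covariate"
  )
})

test_that("null generating model gives SIRs averaging about 1", {
  beta0 <- list(intercept = 0, soil_index = 0, no2 = 0, decile = rep(0, 9))
  study <- small_study(seed = 17, n_zones = 40, true_beta = beta0)
  rates <- derive_standard_rates(study$population, study$cases_by_stratum)
  sir <- compute_sir(study$population, rates, study$cases)
  expect_equal(mean(sir$sir), 1, tolerance = 0.02)
})

test_that("a fixed seed reproduces the study bit for bit", {
  s1 <- small_study(seed = 101)
  s2 <- small_study(seed = 101)
  expect_identical(s1$soil, s2$soil)
  expect_identical(s1$cases, s2$cases)
  expect_identical(s1$deprivation_domains, s2$deprivation_domains)
  s3 <- small_study(seed = 102)
  expect_false(identical(s1$soil, s3$soil))
})
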