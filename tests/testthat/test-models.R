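test_that("pearson_r matches exact lines and the direct-formula oracle", {
  x <- c(1, 2, 4, 8, 9)
  expect_equal(pearson_r(x, 2 * x + 3), 1)
  expect_equal(pearson_r(x, -x), -1)

  set.seed(51)
  for (i in 1:1000) {
    n <- sample(3:40, 1)
    a <- rnorm(n)
    b <- rnorm(n)
    expect_equal(pearson_r(a, b), oracle_pearson(a, b), tolerance = 1e-12)
  }

  expect_error(pearson_r(1:3, 1:4), "equal length")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_true(is.na(pearson_r(rep(1, 5), rnorm(5)))) # zero variance
})

test_that("critical r reproduces the n = 279 threshold and the t closed form", {
  # the printed table convention at the study's sample size
  expect_equal(round(critical_r(279, 0.05), 3), 0.118)

  # exact t inversion: n = 3 plugs t_{0.025,1} = 12.706 into the closed form
  t1 <- qt(0.975, 1)
  expect_equal(critical_r(3, method = "exact"), t1 / sqrt(t1^2 + 1))
  expect_equal(round(critical_r(3, method = "exact"), 3), 0.997)

  # strictly decreasing toward zero over a wide grid, both methods
  grid <- round(seq(10, 1e4, length.out = 60))
  for (m in c("table", "exact")) {
    v <- critical_r(grid, method = m)
    expect_true(all(diff(v) < 0))
    expect_lt(v[length(v)], 0.02)
  }
  expect_error(critical_r(2), "at least 3")
})

test_that("correlation matrix is symmetric, flagged, and listwise-deleted", {
  study <- small_study(seed = 52, n_zones = 40)
  res <- run_analysis(study)
  cm <- res$correlations_mixed
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, ncol(cm$r)))
  expect_equal(nrow(cm$pairs), choose(5, 2))
  expect_equal(cm$pairs$significant, abs(cm$pairs$r) > cm$critical_r)

  # variable-order permutation leaves pairwise values unchanged
  zt <- res$zone_table
  cm2 <- correlation_matrix(zt, c("pm10", "decile", "sir", "no2",
                                  "index_mean"))
  key <- function(p) {
    v <- t(apply(p[c("var1", "var2")], 1, sort))
    setNames(p$r, paste(v[, 1], v[, 2]))
  }
  k1 <- key(cm$pairs)
  expect_equal(k1[names(key(cm2$pairs))], key(cm2$pairs))

  # listwise deletion reports the retained n
  zt$no2[1:3] <- NA
  cm3 <- correlation_matrix(zt, c("sir", "no2"))
  expect_equal(cm3$n, nrow(zt) - 3)

  expect_error(correlation_matrix(zt, c("sir", "nope")), "not found")
})

test_that("an independently generated control element is rarely significant", {
  # mirrors the behaviour of K, the control element: over seeds, its
  # correlation with the index metals should be non-significant about 95%
  # of the time at the 5% level
  hits <- 0
  trials <- 0
  for (seed in 1:40) {
    cfg <- small_config(seed = seed, n_zones = 50, soil_assoc = 0)
    zones <- generate_zones(cfg)
    soil <- generate_soil(cfg, zones)
    urban <- soil[soil$zone_id %in% zones$zone_id[zones$urban], ]
    # within one stratum the metals and K are independent by construction
    r <- pearson_r(log(urban$K), log(urban$Pb))
    hits <- hits + (abs(r) > critical_r(nrow(urban)))
    trials <- trials + 1
  }
  expect_lte(hits / trials, 0.15)
})

test_that("poisson-offset GLM has the closed-form intercept and offset equivalence", {
  # zones with identical O/E = c: intercept-only fit returns log c
  sir <- data.frame(zone_id = sprintf("Z%d", 1:20),
                    observed = rep(30, 20), expected = rep(12, 20))
  sir$sir <- sir$observed / sir$expected
  cov <- data.frame(zone_id = sir$zone_id)
  fit <- fit_sir_glm(sir, cov, soil_covariate = NULL,
                     include_deprivation = FALSE, include_air = FALSE)
  expect_equal(fit$coef_table$estimate, log(30 / 12), tolerance = 1e-8)

  # with E identically 1 the offset model reduces to a Poisson
  # log-linear model on the raw counts
  set.seed(53)
  d <- data.frame(zone_id = sprintf("Z%d", 1:60),
                  x = rnorm(60))
  d$observed <- rpois(60, exp(1 + 0.5 * d$x))
  d$expected <- 1
  ours <- fit_sir_glm(d, d[c("zone_id", "x")], soil_covariate = "x",
                      include_deprivation = FALSE, include_air = FALSE)
  ref <- glm(observed ~ x, data = d, family = poisson())
  expect_equal(ours$coef_table$estimate, unname(coef(ref)),
               tolerance = 1e-10)
  expect_equal(ours$aic, AIC(ref), tolerance = 1e-10)
})

test_that("the one-metal-at-a-time multicollinearity policy is enforced", {
  study <- small_study(seed = 54)
  res <- run_analysis(study)
  expect_error(
    fit_sir_glm(res$sir, res$zone_table,
                soil_covariate = c("Ni", "Pb")),
    "multicollinearity"
  )
})

test_that("both GLM families agree on the direction of a strong soil effect", {
  study <- small_study(seed = 55, n_zones = 60)
  res_p <- run_analysis(study, family = "poisson_offset")
  res_g <- run_analysis(study, family = "gaussian_log")
  bp <- res_p$best_fit$coef_table
  bg <- res_g$best_fit$coef_table
  est_p <- bp$estimate[bp$term == "index_mean"]
  est_g <- bg$estimate[bg$term == "index_mean"]
  expect_gt(est_p, 0)
  expect_gt(est_g, 0)
  expect_true(res_g$best_fit$converged)
})

test_that("model selection picks minimum AIC with ties to the smaller model", {
  study <- small_study(seed = 56, n_zones = 60)
  res <- run_analysis(study)
  aics <- vapply(res$candidates, function(f) f$aic, numeric(1))
  expect_equal(res$best_fit$aic, min(aics))

  # single candidate returns itself
  one <- res$candidates$soil_only
  expect_identical(select_model(list(one)), one)

  # equal AICs: the smaller model wins
  a <- res$candidates$soil_only
  b <- res$candidates$soil_deprivation_air
  b$aic <- a$aic
  expect_identical(select_model(list(b, a)), a)

  expect_error(select_model(list()), "no converged")
})

test_that("AIC keeps true covariates and mostly rejects pure noise", {
  # with a real soil effect, the true-covariate model always beats the
  # null; under a null generating model (so the intercept-only model is
  # correctly specified) a pure-noise covariate survives AIC selection
  # only when its chance deviance gain exceeds 2, i.e. ~16% of the time
  beta0 <- list(intercept = 0, soil_index = 0, no2 = 0, decile = rep(0, 9))
  wins_true <- 0
  wins_noise <- 0
  n_rep <- 12
  for (seed in 1:n_rep) {
    study <- small_study(seed = seed, n_zones = 50)
    rates <- derive_standard_rates(study$population,
                                   study$cases_by_stratum)
    sir <- compute_sir(study$population, rates, study$cases)
    true_fit <- fit_sir_glm(sir, study$zone_covariates,
                            soil_covariate = "index_mean",
                            include_deprivation = FALSE,
                            include_air = FALSE)
    null_fit <- fit_sir_glm(sir, study$zone_covariates,
                            soil_covariate = NULL,
                            include_deprivation = FALSE,
                            include_air = FALSE)
    wins_true <- wins_true +
      identical(select_model(list(null_fit, true_fit)), true_fit)

    null_study <- small_study(seed = seed, n_zones = 50,
                              true_beta = beta0)
    rates0 <- derive_standard_rates(null_study$population,
                                    null_study$cases_by_stratum)
    sir0 <- compute_sir(null_study$population, rates0, null_study$cases)
    cov0 <- null_study$zone_covariates
    set.seed(seed + 1000)
    cov0$noise <- rnorm(nrow(cov0))
    null0 <- fit_sir_glm(sir0, cov0, soil_covariate = NULL,
                         include_deprivation = FALSE,
                         include_air = FALSE)
    noise0 <- fit_sir_glm(sir0, cov0, soil_covariate = "noise",
                          include_deprivation = FALSE,
                          include_air = FALSE)
    wins_noise <- wins_noise +
      identical(select_model(list(null0, noise0)), noise0)
  }
  expect_equal(wins_true, n_rep) # strong signal: always selected
  expect_lte(wins_noise, 6) # chance-level retention stays a minority
})
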