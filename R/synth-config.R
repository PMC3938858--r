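#' Configuration for the synthetic study-region generator
#'
#' Collects every knob of the data-generating world in one validated object.
#' Defaults describe a Glasgow-sized study: 279 zones of roughly 4,000
#' households each, a 3 km2 footprint per zone, urban soil sampled on a
#' systematic grid at 4 samples per km2 and rural land from every second
#' km2, seven positively skewed, mutually correlated metals elevated about
#' threefold in urban soil, an independent control element (K), collinear
#' NO2/PM10 zone means, and Poisson respiratory admissions generated from a
#' log-linear model with known coefficients.
#'
#' The generating coefficients (`true_beta`) are modelling choices of this
#' package, exposed so that parameter-recovery tests are well posed; they are
#' not estimates taken from any survey.
#'
#' @param seed Integer seed; all components draw from sub-streams derived
#'   deterministically from it.
#' @param n_zones Number of reporting zones (default 279).
#' @param grid_shape Integer `(rows, cols)`: 1 km2 cells making up each
#'   zone's footprint (default `c(1, 3)`, i.e. 3 km2 per zone).
#' @param urban_fraction Proportion of zones forming the central urban block.
#'   The default 117/279 reproduces the survey's approximate urban/rural
#'   sample split at the stated sampling densities.
#' @param samples_per_km2_urban Fixed samples per urban cell (default 4).
#' @param samples_per_km2_rural Expected samples per rural cell; values
#'   below 1 are realised as one Bernoulli sample per cell (default 0.5,
#'   "every second square kilometre").
#' @param metal_log_means_urban,metal_log_means_rural Named vectors of log
#'   mg/kg location parameters for the seven metals As, Cr, Cu, Ni, Pb, Se,
#'   Zn. Defaults put urban levels ~3x rural.
#' @param metal_log_cov Positive semi-definite 7x7 covariance of the metals
#'   on the log scale.
#' @param k_log_mean_urban,k_log_mean_rural,k_log_sd Log-scale parameters
#'   for potassium (wt%), drawn independently of the other metals.
#' @param air_params List with `no2_mean = c(urban, rural)`,
#'   `pm10_mean = c(urban, rural)`, `no2_sd`, `pm10_sd`, and `cor` (the
#'   correlation of the two pollutants' zone-level noise).
#' @param age_bands Data frame with columns `label`, `lower`, `upper`,
#'   `prop` (population share of each band).
#' @param sex_split Proportion female within each band.
#' @param households_per_zone,persons_per_household Mean zone size; zone
#'   totals vary log-normally around the product.
#' @param pop_log_sd Log-sd of zone population totals.
#' @param baseline_rates Data frame `age_band`, `sex`, `rate` — admission
#'   rates per 100,000 person-years by stratum.
#' @param true_beta List of generating log-linear coefficients:
#'   `intercept`, `soil_index`, `no2`, and `decile` (length-9 vector for
#'   deciles 2..10; decile 1 is the reference).
#' @param dz_per_zone Data zones nested in each zone (default 5).
#' @param domain_cor Common pairwise correlation of the seven deprivation
#'   domain scores (default 0.6).
#' @param soil_assoc Correlation of the latent zone deprivation factor with
#'   the (standardised) zone soil metal index; positive means metal-rich
#'   zones are more deprived (default 0.45).
#' @param dz_noise_sd Within-zone sd of data-zone deprivation around the
#'   zone latent (default 0.4; the zone latent has sd 1).
#'
#' @return An object of class `synth_config` (a validated list).
#' @seealso [generate_study()]
#' @export
#' @examples
#' cfg <- synth_config(seed = 1, n_zones = 20, urban_fraction = 0.5)
#' cfg$n_zones
synth_config <- function(seed = 1L,
                         n_zones = 279L,
                         grid_shape = c(1L, 3L),
                         urban_fraction = 117 / 279,
                         samples_per_km2_urban = 4L,
                         samples_per_km2_rural = 0.5,
                         metal_log_means_urban = NULL,
                         metal_log_means_rural = NULL,
                         metal_log_cov = NULL,
                         k_log_mean_urban = log(1.2),
                         k_log_mean_rural = log(1.5),
                         k_log_sd = 0.2,
                         air_params = NULL,
                         age_bands = NULL,
                         sex_split = 0.5,
                         households_per_zone = 4000,
                         persons_per_household = 2.2,
                         pop_log_sd = 0.08,
                         baseline_rates = NULL,
                         true_beta = NULL,
                         dz_per_zone = 5L,
                         domain_cor = 0.6,
                         soil_assoc = 0.45,
                         dz_noise_sd = 0.4) {
  if (is.null(metal_log_means_urban)) {
    # locations near typical urban topsoil medians (mg/kg)
    metal_log_means_urban <- log(c(
      As = 9, Cr = 107, Cu = 48, Ni = 46, Pb = 118, Se = 0.9, Zn = 144
    ))
  }
  if (is.null(metal_log_means_rural)) {
    metal_log_means_rural <- metal_log_means_urban - log(3)
  }
  if (is.null(metal_log_cov)) {
    sds <- rep(0.7, length(PHE_METALS))
    R <- matrix(0.6, 7, 7)
    diag(R) <- 1
    metal_log_cov <- outer(sds, sds) * R
    dimnames(metal_log_cov) <- list(PHE_METALS, PHE_METALS)
  }
  if (is.null(air_params)) {
    air_params <- list(
      no2_mean = c(urban = 32, rural = 14), no2_sd = 4,
      pm10_mean = c(urban = 19, rural = 12), pm10_sd = 2.5,
      cor = 0.95
    )
  }
  if (is.null(age_bands)) {
    age_bands <- data.frame(
      label = c("0-14", "15-44", "45-64", "65+"),
      lower = c(0, 15, 45, 65),
      upper = c(14, 44, 64, Inf),
      prop = c(0.17, 0.42, 0.25, 0.16),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(baseline_rates)) {
    baseline_rates <- expand.grid(
      age_band = age_bands$label, sex = c("F", "M"),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    rate_tab <- c(
      `0-14.F` = 1800, `0-14.M` = 2500,
      `15-44.F` = 700, `15-44.M` = 600,
      `45-64.F` = 1300, `45-64.M` = 1500,
      `65+.F` = 5000, `65+.M` = 6000
    )
    baseline_rates$rate <-
      rate_tab[paste(baseline_rates$age_band, baseline_rates$sex, sep = ".")]
    names(baseline_rates$rate) <- NULL
  }
  if (is.null(true_beta)) {
    true_beta <- list(
      intercept = -0.2,
      soil_index = 0.01,
      no2 = 0.01,
      decile = -0.06 * (1:9)
    )
  }

  cfg <- list(
    seed = as.integer(seed), n_zones = as.integer(n_zones),
    grid_shape = as.integer(grid_shape), urban_fraction = urban_fraction,
    samples_per_km2_urban = samples_per_km2_urban,
    samples_per_km2_rural = samples_per_km2_rural,
    metal_log_means_urban = metal_log_means_urban,
    metal_log_means_rural = metal_log_means_rural,
    metal_log_cov = metal_log_cov,
    k_log_mean_urban = k_log_mean_urban,
    k_log_mean_rural = k_log_mean_rural, k_log_sd = k_log_sd,
    air_params = air_params, age_bands = age_bands, sex_split = sex_split,
    households_per_zone = households_per_zone,
    persons_per_household = persons_per_household, pop_log_sd = pop_log_sd,
    baseline_rates = baseline_rates, true_beta = true_beta,
    dz_per_zone = as.integer(dz_per_zone), domain_cor = domain_cor,
    soil_assoc = soil_assoc, dz_noise_sd = dz_noise_sd
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(length(cfg$seed) == 1, is.finite(cfg$seed))
  if (cfg$n_zones < 2) {
    stop("configuration error: n_zones must be at least 2", call. = FALSE)
  }
  if (length(cfg$grid_shape) != 2 || any(cfg$grid_shape < 1) ||
      any(is.na(cfg$grid_shape))) {
    stop("configuration error: grid_shape must be two positive integers",
         call. = FALSE)
  }
  if (cfg$urban_fraction < 0 || cfg$urban_fraction > 1) {
    stop("configuration error: urban_fraction must lie in [0, 1]",
         call. = FALSE)
  }
  if (cfg$samples_per_km2_urban <= 0 || cfg$samples_per_km2_rural <= 0) {
    stop("configuration error: sampling densities must be positive",
         call. = FALSE)
  }
  S <- cfg$metal_log_cov
  if (!is.matrix(S) || nrow(S) != length(PHE_METALS) ||
      ncol(S) != length(PHE_METALS)) {
    stop("configuration error: metal_log_cov must be 7x7", call. = FALSE)
  }
  if (max(abs(S - t(S))) > 1e-8) {
    stop("configuration error: metal_log_cov must be symmetric",
         call. = FALSE)
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop("configuration error: metal_log_cov is not positive semi-definite",
         call. = FALSE)
  }
  if (any(cfg$baseline_rates$rate < 0)) {
    stop("configuration error: baseline_rates must be non-negative",
         call. = FALSE)
  }
  if (length(cfg$true_beta$decile) != 9) {
    stop("configuration error: true_beta$decile must have length 9 ",
         "(deciles 2..10)", call. = FALSE)
  }
  if (abs(sum(cfg$age_bands$prop) - 1) > 1e-6) {
    stop("configuration error: age band proportions must sum to 1",
         call. = FALSE)
  }
  if (cfg$dz_per_zone < 1) {
    stop("configuration error: dz_per_zone must be >= 1", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  seed %d; %d zones (%d x %d km cells each); urban fraction %.2f\n",
              x$seed, x$n_zones, x$grid_shape[1], x$grid_shape[2],
              x$urban_fraction))
  cat(sprintf("  sampling density: urban %s / km2, rural %s / km2\n",
              format(x$samples_per_km2_urban),
              format(x$samples_per_km2_rural)))
  cat(sprintf("  generating model: log SIR = %.3g + %.3g*index + %.3g*NO2 + decile effects\n",
              x$true_beta$intercept, x$true_beta$soil_index, x$true_beta$no2))
  invisible(x)
}

# deterministic per-component sub-seed so adding a component never perturbs
# the draws of another; kept below 2^31 for 32-bit R integers
component_seed <- function(seed, component) {
  offsets <- c(zones = 11L, soil = 23L, air = 37L, deprivation = 53L,
               population = 71L, cases = 89L)
  off <- offsets[[component]]
  as.integer((as.numeric(seed) %% 2097143) * 1009 + off)
}
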