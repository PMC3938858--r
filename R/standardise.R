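#' Derive standard age-sex admission rates from the whole study
#'
#' Internal (indirect) standardisation: the standard population is the
#' study itself, so each stratum's rate is total study cases divided by
#' total study population in that stratum, expressed per 100,000. Used
#' with [compute_sir()], this guarantees that expected counts sum to
#' observed counts over the study.
#'
#' @param population Data frame `zone_id`, `age_band`, `sex`, `pop`.
#' @param cases_by_stratum Data frame `zone_id`, `age_band`, `sex`,
#'   `observed` (or already-aggregated `age_band`, `sex`, `observed`).
#' @return An object of class `standard_rates`: data frame `age_band`,
#'   `sex`, `pop`, `cases`, `rate` (per 100,000).
#' @export
#' @examples
#' pop <- data.frame(zone_id = "Z1", age_band = "all", sex = "F", pop = 1e5)
#' cs <- data.frame(zone_id = "Z1", age_band = "all", sex = "F", observed = 50)
#' derive_standard_rates(pop, cs)$rate # 50 per 100,000
derive_standard_rates <- function(population, cases_by_stratum) {
  stopifnot(all(c("age_band", "sex", "pop") %in% names(population)),
            all(c("age_band", "sex", "observed") %in%
                  names(cases_by_stratum)))
  pop_tot <- aggregate(pop ~ age_band + sex, data = population, sum)
  case_tot <- aggregate(observed ~ age_band + sex, data = cases_by_stratum,
                        sum)
  tab <- merge(pop_tot, case_tot, by = c("age_band", "sex"), all = TRUE)
  tab$observed[is.na(tab$observed)] <- 0
  if (any(tab$pop == 0 & tab$observed > 0)) {
    stop("data error: cases observed in a stratum with zero population",
         call. = FALSE)
  }
  tab$rate <- ifelse(tab$pop > 0, 1e5 * tab$observed / tab$pop, 0)
  names(tab)[names(tab) == "observed"] <- "cases"
  tab <- tab[order(tab$age_band, tab$sex), ]
  rownames(tab) <- NULL
  class(tab) <- c("standard_rates", "data.frame")
  tab
}

#' Build a standard-rates object from an external reference table
#'
#' Wraps an externally supplied rate table (per 100,000 person-years by
#' age band and sex) so it can be used in place of internally derived
#' rates, e.g. national reference rates or the known baseline rates of a
#' synthetic study.
#'
#' @param rates Data frame `age_band`, `sex`, `rate`.
#' @return A `standard_rates` object.
#' @export
standard_rates <- function(rates) {
  stopifnot(all(c("age_band", "sex", "rate") %in% names(rates)))
  if (any(rates$rate < 0)) {
    stop("data error: standard rates must be non-negative", call. = FALSE)
  }
  tab <- rates[order(rates$age_band, rates$sex),
               c("age_band", "sex", "rate")]
  rownames(tab) <- NULL
  class(tab) <- c("standard_rates", "data.frame")
  tab
}

#' Standardised incidence ratios by indirect standardisation
#'
#' For each zone, the expected count is the sum over age-sex strata of the
#' zone's population times the standard rate, and the SIR is observed over
#' expected. A SIR of 1 means parity between observed and expected counts.
#' Zones with expected counts below `e_floor` are flagged `unstable`
#' (retained, not dropped); zones with zero expected count get a missing
#' SIR.
#'
#' @param population Data frame `zone_id`, `age_band`, `sex`, `pop`.
#' @param rates A `standard_rates` object ([derive_standard_rates()] or
#'   [standard_rates()]).
#' @param observed Data frame `zone_id`, `observed` — total cases per zone.
#' @param e_floor Expected-count floor below which a zone is flagged
#'   unstable (default 0.5).
#' @return Data frame `zone_id`, `observed`, `expected`, `sir`,
#'   `unstable`.
#' @export
compute_sir <- function(population, rates, observed, e_floor = 0.5) {
  stopifnot(inherits(rates, "standard_rates"),
            all(c("zone_id", "observed") %in% names(observed)))
  key <- paste(population$age_band, population$sex, sep = ".")
  rkey <- paste(rates$age_band, rates$sex, sep = ".")
  hit <- match(key, rkey)
  if (anyNA(hit)) {
    stop("data error: population strata missing from the standard rates: ",
         paste(unique(key[is.na(hit)]), collapse = ", "), call. = FALSE)
  }
  exp_stratum <- population$pop * rates$rate[hit] / 1e5
  zone_ids <- unique(observed$zone_id)
  grp <- factor(population$zone_id, levels = zone_ids)
  expected <- as.numeric(tapply(exp_stratum, grp, sum))
  expected[is.na(expected)] <- 0

  out <- data.frame(
    zone_id = zone_ids,
    observed = observed$observed[match(zone_ids, observed$zone_id)],
    expected = expected,
    stringsAsFactors = FALSE
  )
  out$sir <- ifelse(out$expected > 0, out$observed / out$expected, NA_real_)
  out$unstable <- out$expected < e_floor
  out
}
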