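#' Default six-domain deprivation weights (health excluded)
#'
#' The published SIMD-2009 domain weighting (income 28%, employment 28%,
#' health 14%, education 14%, access 9%, crime 5%, housing 2%) with the
#' health domain removed and the remaining six weights renormalised to sum
#' to one. When relating deprivation to a health outcome, keeping the
#' health domain inside the index would make the comparison circular, so
#' the index is rebuilt without it. These weights are a documented default
#' of this package, not values printed in any one study.
#'
#' @return Named numeric vector over income, employment, education,
#'   housing, access, crime, summing to 1.
#' @export
#' @examples
#' simd_weights()
simd_weights <- function() {
  w <- c(income = 0.28, employment = 0.28, education = 0.14,
         housing = 0.02, access = 0.09, crime = 0.05)
  w / sum(w)
}

# SIMD-style exponential rank transform: ranks are scaled so the most
# deprived unit maps to 100 and the tail of deprivation carries most of the
# weight; constant 23 as in the published methodology
exp_rank_transform <- function(rank, n) {
  R <- (n - rank + 1) / n # rank 1 (most deprived) -> R = 1
  -23 * log(1 - R * (1 - exp(-100 / 23)))
}

#' Combine domain rankings into a composite deprivation ranking
#'
#' Weighted combination of per-domain rankings (1 = most deprived) into a
#' composite score, re-ranked 1..n. The default transform is the SIMD
#' exponential rank transform, which concentrates weight in the deprived
#' tail so that extreme deprivation on one domain is not averaged away; a
#' linear transform (`n - rank + 1`) is available for sensitivity work.
#'
#' @param domain_ranks Data frame whose columns named in `weights` each
#'   hold a complete ranking (a permutation of 1..n) of the same data
#'   zones. Extra columns are ignored.
#' @param weights Named non-negative weights; normalised to sum 1. Default
#'   [simd_weights()] (six domains, health excluded).
#' @param transform `"exponential"` (default, SIMD methodology) or
#'   `"linear"`.
#' @return Data frame `composite_score`, `composite_rank` (permutation of
#'   1..n, 1 = most deprived; ties broken by row order).
#' @export
combine_domains <- function(domain_ranks, weights = simd_weights(),
                            transform = c("exponential", "linear")) {
  transform <- match.arg(transform)
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    stop("input error: weights must be named by domain", call. = FALSE)
  }
  if (any(weights < 0)) {
    stop("input error: weights must be non-negative", call. = FALSE)
  }
  if ("health" %in% names(weights)) {
    stop("input error: the health domain must not enter the composite",
         call. = FALSE)
  }
  missing_dom <- setdiff(names(weights), names(domain_ranks))
  if (length(missing_dom) > 0) {
    stop("input error: domain columns missing: ",
         paste(missing_dom, collapse = ", "), call. = FALSE)
  }
  weights <- weights / sum(weights)
  ranks <- as.matrix(as.data.frame(domain_ranks)[names(weights)])
  n <- nrow(ranks)
  for (d in colnames(ranks)) {
    if (!setequal(ranks[, d], seq_len(n))) {
      stop("input error: domain '", d,
           "' is not a complete ranking of the same data zones",
           call. = FALSE)
    }
  }
  X <- switch(transform,
              exponential = exp_rank_transform(ranks, n),
              linear = n - ranks + 1)
  score <- as.numeric(X %*% weights)
  data.frame(
    composite_score = score,
    composite_rank = rank(-score, ties.method = "first")
  )
}

#' Classify composite ranks into deciles
#'
#' Ranks are grouped into ten equally sized classes: decile `d` contains
#' ranks in `((d-1)*n/10, d*n/10]`, so class sizes differ by at most one
#' for any n. Decile 1 is the most deprived tenth, decile 10 the least.
#'
#' @param composite_rank Permutation of 1..n (1 = most deprived).
#' @return Integer deciles in 1..10.
#' @export
#' @examples
#' to_deciles(1:100)[c(1, 10, 11, 100)] # 1 1 2 10
to_deciles <- function(composite_rank) {
  n <- length(composite_rank)
  if (n < 10) stop("need at least 10 data zones for deciles", call. = FALSE)
  if (!setequal(composite_rank, seq_len(n))) {
    stop("input error: composite_rank must be a permutation of 1..n",
         call. = FALSE)
  }
  as.integer(ceiling(10 * composite_rank / n))
}

#' Zone-level deprivation as the median data-zone decile
#'
#' Converts data-zone deciles to the coarser reporting zones by taking the
#' median decile of the member data zones. Half-integer medians (even
#' member counts) are floored — rounded toward the more deprived class, a
#' conservative convention for an inequality analysis.
#'
#' @param dz_deciles Data frame `datazone_id`, `zone_id`, `decile`.
#' @param zone_ids Optional full set of zone ids to report (zones without
#'   data zones get a missing median).
#' @return Data frame `zone_id`, `n_datazones`, `median_decile`.
#' @export
#' @examples
#' dz <- data.frame(datazone_id = c("a", "b"), zone_id = "Z1",
#'                  decile = c(4L, 6L))
#' zone_median_decile(dz)$median_decile # 5
zone_median_decile <- function(dz_deciles, zone_ids = NULL) {
  stopifnot(all(c("zone_id", "decile") %in% names(dz_deciles)))
  if (is.null(zone_ids)) zone_ids <- sort(unique(dz_deciles$zone_id))
  grp <- factor(dz_deciles$zone_id, levels = zone_ids)
  med <- tapply(dz_deciles$decile, grp, function(d) floor(median(d)))
  data.frame(
    zone_id = zone_ids,
    n_datazones = as.integer(table(grp)),
    median_decile = as.integer(med),
    stringsAsFactors = FALSE
  )
}
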