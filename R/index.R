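#' Fit a decile scorer for one metal
#'
#' Step 1 of the composite soil metal index: each metal's study-wide
#' concentration distribution is split into deciles of its empirical CDF
#' and concentrations are scored 1 (lowest tenth) to 10 (highest tenth).
#' Scoring is purely rank-based — a value's score is
#' `ceiling(10 * rank / n)` where rank is the smallest rank of its tie
#' group in the fitted sample — so any strictly monotone transform of the
#' concentrations (including the log transform applied before fitting)
#' leaves scores unchanged. Interpolated decile cut points (type-7
#' quantiles of the log values) are stored for audit and export.
#'
#' @param values Strictly positive concentrations, at least 10, with at
#'   least 2 distinct values.
#' @param metal Metal name (label only).
#' @return An object of class `decile_scorer`.
#' @seealso [score_samples()], [zone_mean_index()]
#' @export
#' @examples
#' sc <- fit_decile_scorer(1:100, "Pb")
#' table(score_values(sc, 1:100))
fit_decile_scorer <- function(values, metal = "metal") {
  values <- values[!is.na(values)]
  if (length(values) < 10) {
    stop("domain error: need at least 10 observations to fit deciles",
         call. = FALSE)
  }
  if (any(values <= 0)) {
    stop("domain error: concentrations must be strictly positive",
         call. = FALSE)
  }
  if (length(unique(values)) < 2) {
    stop("degenerate distribution: all values identical for ", metal,
         call. = FALSE)
  }
  lv <- sort(log(values))
  structure(
    list(
      metal = metal,
      n = length(lv),
      sorted_log = lv,
      cut_points_log = quantile(lv, probs = seq(0.1, 0.9, by = 0.1),
                                type = 7, names = FALSE),
      cut_points = exp(quantile(lv, probs = seq(0.1, 0.9, by = 0.1),
                                type = 7, names = FALSE))
    ),
    class = "decile_scorer"
  )
}

#' @export
print.decile_scorer <- function(x, ...) {
  cat(sprintf("Decile scorer for %s (n = %d)\n", x$metal, x$n))
  cat("  cut points:", paste(signif(x$cut_points, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Score concentrations with a fitted decile scorer
#'
#' @param scorer A [fit_decile_scorer()] object.
#' @param values Concentrations to score (positive; `NA` stays `NA`).
#' @return Integer scores in 1..10; ties at a decile boundary share the
#'   lower score, and values beyond the fitted range clamp to 1 or 10.
#' @export
score_values <- function(scorer, values) {
  stopifnot(inherits(scorer, "decile_scorer"))
  out <- rep(NA_integer_, length(values))
  ok <- !is.na(values)
  if (any(values[ok] <= 0)) {
    stop("domain error: concentrations must be strictly positive",
         call. = FALSE)
  }
  lv <- log(values[ok])
  # smallest rank the value would take among the fitted sample
  rank_min <- findInterval(lv, scorer$sorted_log, left.open = TRUE) + 1L
  sc <- as.integer(ceiling(10 * rank_min / scorer$n))
  out[ok] <- pmin(10L, pmax(1L, sc))
  out
}

#' Score samples and form the per-sample metal index
#'
#' Step 2: per-sample decile scores for the five index metals (As, Cr, Ni,
#' Pb, Se) are summed into a total in 5..50. Samples missing any of the
#' five concentrations are flagged incomplete and carry a missing total,
#' which excludes them from zone means.
#'
#' @param samples Soil sample table with the five metal columns.
#' @param scorers Named list of [fit_decile_scorer()] objects for exactly
#'   the five index metals, fitted on this study's distributions.
#' @return Data frame `sample_id`, `zone_id` (if present), `score_<metal>`
#'   columns, `total`, `complete`.
#' @export
score_samples <- function(samples, scorers) {
  if (!setequal(names(scorers), CLEA_METALS)) {
    stop("scorers must be supplied for exactly the five index metals: ",
         paste(CLEA_METALS, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(sample_id = samples$sample_id, stringsAsFactors = FALSE)
  if ("zone_id" %in% names(samples)) out$zone_id <- samples$zone_id
  score_mat <- sapply(CLEA_METALS, function(m) {
    score_values(scorers[[m]], samples[[m]])
  })
  if (is.null(dim(score_mat))) score_mat <- matrix(score_mat, nrow = 1)
  colnames(score_mat) <- paste0("score_", CLEA_METALS)
  out <- cbind(out, as.data.frame(score_mat))
  out$total <- as.integer(rowSums(score_mat))
  out$complete <- !is.na(out$total)
  out
}

#' Zone mean of the sample metal index
#'
#' Step 3: the arithmetic mean of the per-sample index totals within each
#' zone — the zone-level land-quality covariate used downstream. Zones
#' without any complete scored sample are reported with a missing mean.
#'
#' @param sample_indices Output of [score_samples()] including `zone_id`.
#' @param zone_ids Optional full set of zone ids to report.
#' @return Data frame `zone_id`, `n_scored`, `index_mean`.
#' @export
zone_mean_index <- function(sample_indices, zone_ids = NULL) {
  stopifnot("zone_id" %in% names(sample_indices))
  use <- sample_indices[sample_indices$complete &
                          !is.na(sample_indices$zone_id), , drop = FALSE]
  if (is.null(zone_ids)) zone_ids <- sort(unique(use$zone_id))
  grp <- factor(use$zone_id, levels = zone_ids)
  data.frame(
    zone_id = zone_ids,
    n_scored = as.integer(table(grp)),
    index_mean = as.numeric(tapply(use$total, grp, mean)),
    stringsAsFactors = FALSE
  )
}
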