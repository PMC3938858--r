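#' Pearson product-moment correlation
#'
#' Thin, validated wrapper around the standard product-moment coefficient,
#' used throughout the correlation tables.
#'
#' @param x,y Numeric vectors of equal length >= 3. Pairs with missing
#'   values are dropped.
#' @return The coefficient in \[-1, 1\], or `NA` if either vector has zero
#'   variance after pair deletion.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    stop("input error: x and y must have equal length", call. = FALSE)
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    stop("input error: need at least 3 complete pairs", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Critical value of Pearson's r at a given sample size
#'
#' The smallest absolute correlation significant at level `alpha` for `n`
#' pairs. Method `"table"` (default) uses the large-sample normal form
#' `z_{alpha/2} / sqrt(n - 2)`, the convention of classic critical-r
#' look-up tables (for n = 279 at the 5% level it gives 0.118). Method
#' `"exact"` inverts the t test of a correlation:
#' `t / sqrt(t^2 + n - 2)` with `t = qt(1 - alpha/2, n - 2)` (0.117 at
#' n = 279 — the two conventions differ in the third decimal). The
#' threshold is strictly decreasing in n under either method.
#'
#' @param n Number of pairs (>= 3; `"table"` additionally needs n > 2).
#' @param alpha Significance level (default 0.05).
#' @param two_sided Two-sided test (default `TRUE`).
#' @param method `"table"` or `"exact"`.
#' @return The critical |r|.
#' @export
#' @examples
#' round(critical_r(279), 3) # 0.118
critical_r <- function(n, alpha = 0.05, two_sided = TRUE,
                       method = c("table", "exact")) {
  method <- match.arg(method)
  if (any(n < 3)) stop("domain error: n must be at least 3", call. = FALSE)
  p <- if (two_sided) 1 - alpha / 2 else 1 - alpha
  if (method == "table") {
    qnorm(p) / sqrt(n - 2)
  } else {
    t <- qt(p, df = n - 2)
    t / sqrt(t^2 + n - 2)
  }
}

#' Pairwise Pearson correlation matrix with significance flags
#'
#' Computes every lower-triangle pairwise correlation among the selected
#' zone-level variables on complete cases (listwise deletion, with the
#' retained n reported), and flags coefficients whose absolute value
#' exceeds the n-dependent critical value at `alpha`. When deprivation is
#' among the variables remember the direction convention: decile 1 is the
#' most deprived, so a negative correlation with deprivation means worse
#' conditions in more deprived zones.
#'
#' @param data Zone-level data frame.
#' @param variables Column names to correlate (>= 2).
#' @param alpha Significance level for the critical value (default 0.05).
#' @param method Critical-value convention, see [critical_r()].
#' @return An object of class `correlation_matrix`: list with `r` (the
#'   full symmetric matrix), `pairs` (long lower-triangle data frame:
#'   `var1`, `var2`, `r`, `n`, `critical_r`, `significant`), `n`,
#'   `critical_r`, `alpha`.
#' @export
correlation_matrix <- function(data, variables, alpha = 0.05,
                               method = c("table", "exact")) {
  method <- match.arg(method)
  stopifnot(length(variables) >= 2)
  missing_v <- setdiff(variables, names(data))
  if (length(missing_v) > 0) {
    stop("input error: variables not found: ",
         paste(missing_v, collapse = ", "), call. = FALSE)
  }
  d <- data[variables]
  d <- d[complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n < 3) stop("input error: fewer than 3 complete cases", call. = FALSE)
  R <- cor(as.matrix(d))
  rc <- critical_r(n, alpha = alpha, method = method)
  comb <- which(lower.tri(R), arr.ind = TRUE)
  pairs <- data.frame(
    var1 = variables[comb[, "col"]],
    var2 = variables[comb[, "row"]],
    r = R[comb],
    n = n,
    critical_r = rc,
    stringsAsFactors = FALSE
  )
  pairs$significant <- abs(pairs$r) > rc
  structure(list(r = R, pairs = pairs, n = n, critical_r = rc,
                 alpha = alpha, method = method),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Pearson correlation matrix (n = %d, critical |r| = %.3f at alpha = %g)\n",
              x$n, x$critical_r, x$alpha))
  R <- round(x$r, digits)
  R[upper.tri(R, diag = TRUE)] <- NA
  print(R[-1, -ncol(R), drop = FALSE], na.print = "")
  cat("coefficients with |r| above the critical value are significant\n")
  invisible(x)
}

#' Log-link GLM of standardised incidence ratios
#'
#' Models zone SIRs against one land-quality covariate, deprivation decile
#' (categorical, decile 1 = reference) and one air pollutant. The default
#' family is Poisson on the observed counts with `log(expected)` as
#' offset — the count-level formulation of a log-link model of the SIR —
#' with a Gaussian log-link fit directly on the SIRs as an alternative.
#' Exactly one soil covariate is allowed per model: soil metals are
#' strongly inter-correlated, and entering several at once invites
#' multicollinearity, so metals (or the composite index) are assessed one
#' at a time.
#'
#' @param sir Output of [compute_sir()].
#' @param covariates Zone-level data frame containing `zone_id`, the soil
#'   covariate column, `decile`, and the air pollutant column.
#' @param soil_covariate Name of the single soil covariate column, e.g.
#'   `"index_mean"` or a metal geometric-mean column such as `"Ni"`.
#'   At most one; `NULL` fits a model without a soil term (for null or
#'   nested candidates).
#' @param air Air pollutant column (default `"no2"`), or `NULL` to omit.
#' @param include_deprivation,include_air Drop terms to build nested
#'   candidate models for AIC selection.
#' @param family `"poisson_offset"` (default) or `"gaussian_log"`.
#' @return An object of class `sir_glm`: list with `coef_table` (`term`,
#'   `estimate`, `se`, `p_value`), `aic`, `family`, `formula`, `n`,
#'   `converged`, `soil_covariate`, and the underlying `fit`.
#' @export
fit_sir_glm <- function(sir, covariates, soil_covariate = "index_mean",
                        air = "no2",
                        include_deprivation = TRUE, include_air = TRUE,
                        family = c("poisson_offset", "gaussian_log")) {
  family <- match.arg(family)
  if (length(soil_covariate) > 1) {
    stop("multicollinearity policy: soil metals are strongly ",
         "inter-correlated, enter exactly one soil covariate per model",
         call. = FALSE)
  }
  stopifnot(all(c("zone_id", "observed", "expected") %in% names(sir)))
  cov_cols <- setdiff(names(covariates),
                      c("observed", "expected", "sir", "unstable"))
  d <- merge(sir[c("zone_id", "observed", "expected")],
             covariates[cov_cols], by = "zone_id")
  need <- c(soil_covariate, if (include_deprivation) "decile",
            if (include_air && !is.null(air)) air)
  missing_v <- setdiff(need, names(d))
  if (length(missing_v) > 0) {
    stop("input error: covariate columns not found: ",
         paste(missing_v, collapse = ", "), call. = FALSE)
  }
  d <- d[d$expected > 0, , drop = FALSE]
  d <- d[complete.cases(d[c("observed", "expected", need)]), , drop = FALSE]
  if (include_deprivation) {
    d$decile_f <- droplevels(factor(d$decile, levels = 1:10))
  }

  rhs <- c(soil_covariate,
           if (include_deprivation) "decile_f",
           if (include_air && !is.null(air)) air)
  if (length(rhs) == 0) rhs <- "1" # null (intercept-only) model
  if (family == "poisson_offset") {
    fml <- as.formula(paste("observed ~", paste(rhs, collapse = " + "),
                            "+ offset(log(expected))"))
    fit <- glm(fml, data = d, family = poisson())
  } else {
    d$sir_resp <- d$observed / d$expected
    fml <- as.formula(paste("sir_resp ~", paste(rhs, collapse = " + ")))
    start <- tryCatch({
      lf <- lm(as.formula(paste("log(pmax(sir_resp, 0.01)) ~",
                                paste(rhs, collapse = " + "))), data = d)
      coef(lf)
    }, error = function(e) NULL)
    fit <- glm(fml, data = d, family = gaussian(link = "log"),
               start = start)
  }

  sm <- summary(fit)$coefficients
  term <- rownames(sm)
  term <- sub("^decile_f", "Decile ", term)
  coef_table <- data.frame(
    term = term,
    estimate = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    p_value = sm[, ncol(sm)],
    stringsAsFactors = FALSE
  )
  rownames(coef_table) <- NULL

  structure(list(
    coef_table = coef_table,
    aic = AIC(fit),
    family = family,
    formula = fml,
    n = nrow(d),
    converged = isTRUE(fit$converged),
    soil_covariate = soil_covariate,
    air = if (include_air) air else NULL,
    fit = fit
  ), class = "sir_glm")
}

#' @export
print.sir_glm <- function(x, digits = 4, ...) {
  cat(sprintf("Log-link GLM of respiratory SIRs (%s, n = %d zones)\n",
              x$family, x$n))
  tab <- x$coef_table
  tab$estimate <- round(tab$estimate, digits)
  tab$se <- round(tab$se, digits)
  tab$p_value <- round(tab$p_value, digits)
  names(tab) <- c("Coefficient", "Estimate", "SE", "p value")
  print(tab, row.names = FALSE)
  cat(sprintf("AIC %.2f\n", x$aic))
  if (!x$converged) cat("WARNING: fit did not converge\n")
  invisible(x)
}

#' Select the best-fitting model by minimum AIC
#'
#' @param fits List of converged [fit_sir_glm()] objects on the same
#'   response and data.
#' @return The fit with the smallest AIC; ties go to the model with fewer
#'   coefficients.
#' @export
select_model <- function(fits) {
  if (inherits(fits, "sir_glm")) fits <- list(fits)
  fits <- Filter(function(f) isTRUE(f$converged) && is.finite(f$aic), fits)
  if (length(fits) == 0) {
    stop("model selection error: no converged candidate models",
         call. = FALSE)
  }
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  k <- vapply(fits, function(f) nrow(f$coef_table), numeric(1))
  best <- order(aics, k)[1]
  fits[[best]]
}
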