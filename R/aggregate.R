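#' Geometric mean of positive values
#'
#' The zone-level average used throughout for positively skewed metal
#' concentrations: `exp(mean(log(x)))`. By the AM-GM inequality it never
#' exceeds the arithmetic mean.
#'
#' @param x Numeric vector, strictly positive. `NA`s are removed when
#'   `na.rm = TRUE`.
#' @param na.rm Drop missing values first (default `TRUE`).
#' @return The geometric mean, or `NA_real_` for an empty vector.
#' @export
#' @examples
#' geometric_mean(c(1, 100)) # 10
geometric_mean <- function(x, na.rm = TRUE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  if (any(x <= 0)) {
    stop("domain error: geometric mean requires strictly positive values",
         call. = FALSE)
  }
  exp(mean(log(x)))
}

#' Assign point samples to zones
#'
#' Spatial join of sample coordinates to zone footprints. Grid zones (the
#' rectangle table produced by [generate_zones()]) use the half-open cell
#' convention `[xmin, xmax) x [ymin, ymax)`, so a point on a shared
#' boundary belongs to exactly one zone. Polygon zones (from
#' [read_zones_geojson()]) use even-odd ray casting with
#' first-containing-polygon ordering. Points outside every zone get
#' `NA` and are counted as unassigned.
#'
#' @param samples Data frame with `x`, `y` columns.
#' @param zones Grid-zone data frame (`zone_id`, `xmin`, `xmax`, `ymin`,
#'   `ymax`) or a polygon zone list from [read_zones_geojson()].
#' @return `samples` with its `zone_id` column (re)computed.
#' @export
assign_zones <- function(samples, zones) {
  stopifnot(all(c("x", "y") %in% names(samples)))
  if (is.data.frame(zones)) {
    stopifnot(all(c("zone_id", "xmin", "xmax", "ymin", "ymax") %in%
                    names(zones)))
    if (zones_overlap(zones)) {
      stop("geometry error: zone rectangles overlap", call. = FALSE)
    }
    zone_of <- rep(NA_character_, nrow(samples))
    for (i in seq_len(nrow(zones))) {
      z <- zones[i, ]
      hit <- is.na(zone_of) &
        samples$x >= z$xmin & samples$x < z$xmax &
        samples$y >= z$ymin & samples$y < z$ymax
      zone_of[hit] <- z$zone_id
    }
  } else {
    zone_of <- assign_zones_polygon(samples, zones)
  }
  samples$zone_id <- zone_of
  samples
}

# rectangles overlap iff some pair intersects with positive area
zones_overlap <- function(zones) {
  n <- nrow(zones)
  if (n < 2) return(FALSE)
  for (i in seq_len(n - 1)) {
    xi <- zones[i, ]
    j <- (i + 1):n
    ox <- pmin(xi$xmax, zones$xmax[j]) > pmax(xi$xmin, zones$xmin[j])
    oy <- pmin(xi$ymax, zones$ymax[j]) > pmax(xi$ymin, zones$ymin[j])
    if (any(ox & oy)) return(TRUE)
  }
  FALSE
}

# even-odd ray casting; boundary points resolve by first containing polygon
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py)) {
      xint <- vx[i] + (py - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

assign_zones_polygon <- function(samples, zones) {
  zone_of <- rep(NA_character_, nrow(samples))
  for (z in zones) {
    todo <- which(is.na(zone_of))
    if (length(todo) == 0) break
    hit <- vapply(todo, function(k) {
      point_in_polygon(samples$x[k], samples$y[k], z$x, z$y)
    }, logical(1))
    zone_of[todo[hit]] <- z$zone_id
  }
  zone_of
}

#' Summarise soil geochemistry by zone
#'
#' Computes, for each zone with at least one assigned sample, the sample
#' count and each element's untransformed geometric mean together with the
#' log-scale mean and sd. Zones present in `zone_ids` but without samples
#' appear with `n_samples = 0` and missing summaries. Values flagged below
#' the detection limit (encoded `NA` with a `detection_limits` entry) are
#' substituted at half the detection limit by default, or excluded.
#'
#' @param samples Assigned soil sample table (see [assign_zones()]).
#' @param elements Element columns to summarise (default all of
#'   As, Cr, Cu, Ni, Pb, Se, Zn, K present in `samples`).
#' @param zone_ids Optional vector of all zone ids, so empty zones are
#'   reported explicitly.
#' @param below_detection `"halve"` (default) substitutes DL/2 for `NA`
#'   concentrations of elements named in `detection_limits`; `"exclude"`
#'   drops them.
#' @param detection_limits Named vector of detection limits (mg/kg).
#' @return Data frame with `zone_id`, `n_samples`, and per element
#'   `<el>` (geometric mean), `<el>_log_mean`, `<el>_log_sd`.
#' @export
summarise_zones <- function(samples,
                            elements = intersect(ALL_ELEMENTS, names(samples)),
                            zone_ids = NULL,
                            below_detection = c("halve", "exclude"),
                            detection_limits = NULL) {
  below_detection <- match.arg(below_detection)
  stopifnot("zone_id" %in% names(samples), length(elements) > 0)
  if (!is.null(detection_limits) && below_detection == "halve") {
    for (el in intersect(names(detection_limits), elements)) {
      miss <- is.na(samples[[el]])
      samples[[el]][miss] <- detection_limits[[el]] / 2
    }
  }
  assigned <- samples[!is.na(samples$zone_id), , drop = FALSE]
  if (is.null(zone_ids)) zone_ids <- sort(unique(assigned$zone_id))

  grp <- factor(assigned$zone_id, levels = zone_ids)
  out <- data.frame(zone_id = zone_ids, stringsAsFactors = FALSE)
  out$n_samples <- as.integer(table(grp))
  for (el in elements) {
    v <- assigned[[el]]
    out[[el]] <- as.numeric(tapply(v, grp, geometric_mean))
    out[[paste0(el, "_log_mean")]] <-
      as.numeric(tapply(v, grp, function(z) mean(log(z[!is.na(z)]))))
    out[[paste0(el, "_log_sd")]] <-
      as.numeric(tapply(v, grp, function(z) stats::sd(log(z[!is.na(z)]))))
  }
  out
}
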