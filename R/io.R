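#' Write a synthetic study to a directory of plain-text files
#'
#' Emits the on-disk interchange layout consumed by [read_study()] and the
#' command-line tools: `soil.csv`, `zones.csv`, `zones.geojson`,
#' `air.csv`, `population.csv`, `cases.csv`, `cases_by_stratum.csv`,
#' `deprivation.csv`, and `truth.json` holding the generating parameters.
#'
#' @param study A `synthetic_study` from [generate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(d, f) write.csv(d, file.path(dir, f), row.names = FALSE)
  wr(study$soil, "soil.csv")
  wr(study$zones, "zones.csv")
  wr(study$air, "air.csv")
  wr(study$population, "population.csv")
  wr(study$cases, "cases.csv")
  wr(study$cases_by_stratum, "cases_by_stratum.csv")
  wr(study$deprivation_domains, "deprivation.csv")
  write_zones_geojson(study$zones, file.path(dir, "zones.geojson"))
  truth <- list(
    seed = study$config$seed,
    n_zones = study$config$n_zones,
    true_beta = study$config$true_beta,
    baseline_rates = study$config$baseline_rates
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir Directory containing the CSV layout.
#' @return A list with the same tabular components as a
#'   `synthetic_study` (`zones`, `soil`, `air`, `population`, `cases`,
#'   `cases_by_stratum` if present, `deprivation_domains`).
#' @export
read_study <- function(dir) {
  rd <- function(f) read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  out <- list(
    zones = rd("zones.csv"),
    soil = rd("soil.csv"),
    air = rd("air.csv"),
    population = rd("population.csv"),
    cases = rd("cases.csv"),
    deprivation_domains = rd("deprivation.csv")
  )
  cbs <- file.path(dir, "cases_by_stratum.csv")
  if (file.exists(cbs)) {
    out$cases_by_stratum <- read.csv(cbs, stringsAsFactors = FALSE)
  }
  out
}

#' Write zone footprints as GeoJSON polygons
#'
#' Rectangular grid zones are emitted as a FeatureCollection of closed
#' polygons with `zone_id` and `urban` properties, so real polygon
#' geographies and the synthetic grid share one interchange format.
#'
#' @param zones Grid-zone data frame from [generate_zones()].
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_zones_geojson <- function(zones, path) {
  features <- lapply(seq_len(nrow(zones)), function(i) {
    z <- zones[i, ]
    ring <- list(
      c(z$xmin, z$ymin), c(z$xmax, z$ymin), c(z$xmax, z$ymax),
      c(z$xmin, z$ymax), c(z$xmin, z$ymin)
    )
    list(
      type = "Feature",
      properties = list(zone_id = z$zone_id, urban = z$urban),
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read zone polygons from GeoJSON
#'
#' Minimal reader for FeatureCollections of `Polygon` features (outer
#' ring only) carrying a `zone_id` property. Returned zones are accepted
#' by [assign_zones()], which resolves containment by even-odd ray
#' casting in feature order.
#'
#' @param path Path to a `.geojson` file.
#' @return List of zones, each `list(zone_id, x, y)` with the ring
#'   vertex coordinates.
#' @export
read_zones_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) {
    stop("input error: expected a GeoJSON FeatureCollection", call. = FALSE)
  }
  lapply(fc$features, function(f) {
    if (!identical(f$geometry$type, "Polygon")) {
      stop("input error: only Polygon features are supported",
           call. = FALSE)
    }
    ring <- f$geometry$coordinates[[1]]
    list(
      zone_id = f$properties$zone_id,
      x = vapply(ring, function(p) as.numeric(p[[1]]), numeric(1)),
      y = vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    )
  })
}
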