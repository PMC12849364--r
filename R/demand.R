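#' Estimate the population of a grid cell
#'
#' The population carried by a demand point is its hexagon cell area
#' multiplied by the local population density. The product is kept
#' fractional — demand points are weights, not counts; rounding happens only
#' at presentation.
#'
#' @param cell_area cell area in km^2 (> 0); vectorized.
#' @param density population density in persons/km^2 (>= 0); vectorized.
#' @return persons (possibly fractional).
#' @examples
#' estimatePopulation(2, 150)  # 300
#' @export
estimatePopulation <- function(cell_area, density) {
  if (any(cell_area <= 0)) stop("cell_area must be positive")
  if (any(density < 0)) stop("density must be non-negative")
  cell_area * density
}

#' Construct a DemandSet from a plain table
#'
#' @param df `data.frame` with columns `point_id`, `x`, `y`, `region_id`,
#'   `urbanization`, `density`, `cell_area` (and optionally `population`,
#'   which is checked against `density * cell_area`, tolerance 1e-9).
#' @param mode `"planar"` (km) or `"wgs84"` (degrees).
#' @return a [DemandSet-class].
#' @export
makeDemandSet <- function(df, mode = c("planar", "wgs84")) {
  mode <- match.arg(mode)
  need <- c("point_id", "x", "y", "region_id", "urbanization", "density",
            "cell_area")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing demand columns: ", paste(miss, collapse = ", "))
  pop <- estimatePopulation(df$cell_area, df$density)
  if ("population" %in% names(df)) {
    bad <- abs(df$population - pop) > 1e-9 * pmax(1, abs(pop))
    if (any(bad))
      stop("stored population disagrees with density * cell_area for: ",
           paste(df$point_id[bad], collapse = ", "))
  }
  df$population <- pop
  df$point_id <- as.character(df$point_id)
  df$region_id <- as.character(df$region_id)
  new("DemandSet", points = df[, c(need, "population")], mode = mode)
}

#' Construct a HospitalSet from a plain table
#'
#' @param df `data.frame` with columns `hospital_id`, `x`, `y` and
#'   `service` (logical current-service flag).
#' @param mode `"planar"` (km) or `"wgs84"` (degrees).
#' @return a [HospitalSet-class].
#' @export
makeHospitalSet <- function(df, mode = c("planar", "wgs84")) {
  mode <- match.arg(mode)
  need <- c("hospital_id", "x", "y", "service")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing hospital columns: ", paste(miss, collapse = ", "))
  df$hospital_id <- as.character(df$hospital_id)
  df$service <- as.logical(df$service)
  new("HospitalSet", sites = df[, need], mode = mode)
}

geojsonPointFeatures <- function(coords, props) {
  lapply(seq_len(nrow(coords)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(coords[i, 1L], coords[i, 2L])),
         properties = as.list(props[i, , drop = FALSE]))
  })
}

writeGeojson <- function(features, mode, path) {
  fc <- list(type = "FeatureCollection",
             mode = jsonlite::unbox(mode),
             features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write / read demand points
#'
#' `writeDemand` serializes a [DemandSet-class] as a GeoJSON
#' FeatureCollection of Point features (properties `point_id`, `region_id`,
#' `urbanization`, `density_per_km2`, `area_km2`) or as flat CSV with
#' columns `point_id`, `x`/`lon`, `y`/`lat`, `region_id`, `urbanization`,
#' `density_per_km2`, `area_km2`. `readDemand` inverts it; the population is
#' recomputed on load and checked against any stored value. Units: km and
#' persons/km^2 throughout.
#'
#' @param demand a [DemandSet-class].
#' @param path file path; format chosen by extension (`.geojson`/`.json`
#'   vs `.csv`) unless `format` is given.
#' @param format `"geojson"`, `"csv"` or `"auto"`.
#' @return `readDemand` returns a [DemandSet-class]; `writeDemand` the path,
#'   invisibly.
#' @export
writeDemand <- function(demand, path, format = c("auto", "geojson", "csv")) {
  stopifnot(is(demand, "DemandSet"))
  format <- resolveFormat(match.arg(format), path)
  df <- demand@points
  planar <- demand@mode == "planar"
  if (format == "csv") {
    out <- data.frame(point_id = df$point_id, df$x, df$y,
                      region_id = df$region_id,
                      urbanization = df$urbanization,
                      density_per_km2 = df$density,
                      area_km2 = df$cell_area, stringsAsFactors = FALSE)
    names(out)[2:3] <- if (planar) c("x", "y") else c("lon", "lat")
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    props <- data.frame(point_id = df$point_id, region_id = df$region_id,
                        urbanization = df$urbanization,
                        density_per_km2 = df$density,
                        area_km2 = df$cell_area, stringsAsFactors = FALSE)
    writeGeojson(geojsonPointFeatures(cbind(df$x, df$y), props),
                 demand@mode, path)
  }
  invisible(path)
}

#' @rdname writeDemand
#' @export
readDemand <- function(path, format = c("auto", "geojson", "csv")) {
  format <- resolveFormat(match.arg(format), path)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    mode <- if (all(c("x", "y") %in% names(df))) "planar"
            else if (all(c("lon", "lat") %in% names(df))) "wgs84"
            else stop("demand CSV must have x,y (planar) or lon,lat (wgs84)")
    cn <- if (mode == "planar") c("x", "y") else c("lon", "lat")
    tab <- data.frame(point_id = as.character(df$point_id),
                      x = df[[cn[1L]]], y = df[[cn[2L]]],
                      region_id = df$region_id,
                      urbanization = df$urbanization,
                      density = df$density_per_km2,
                      cell_area = df$area_km2, stringsAsFactors = FALSE)
  } else {
    fc <- jsonlite::read_json(path)
    mode <- fc$mode %||% "planar"
    tab <- parsePointFeatures(fc$features, "point_id",
      c("region_id", "urbanization", "density_per_km2", "area_km2"))
    names(tab)[names(tab) == "density_per_km2"] <- "density"
    names(tab)[names(tab) == "area_km2"] <- "cell_area"
  }
  makeDemandSet(tab, mode)
}

parsePointFeatures <- function(features, id_field, prop_fields) {
  rows <- lapply(seq_along(features), function(i) {
    f <- features[[i]]
    pr <- f$properties
    want <- c(id_field, prop_fields)
    miss <- want[!vapply(want, function(p)
      p %in% names(pr) && !is.null(pr[[p]]), logical(1L))]
    if (length(miss))
      stop("feature ", i, " (", pr[[id_field]] %||% "unnamed",
           ") is missing properties: ", paste(miss, collapse = ", "))
    co <- unlist(f$geometry$coordinates)
    out <- data.frame(id = as.character(pr[[id_field]]), x = co[1L],
                      y = co[2L], stringsAsFactors = FALSE)
    for (p in prop_fields) out[[p]] <- unlist(pr[[p]])
    out
  })
  tab <- do.call(rbind, rows)
  names(tab)[1L] <- id_field
  tab
}

#' Write / read candidate hospital sites
#'
#' GeoJSON Point features with properties `hospital_id` and `pediatric`
#' (the current-service flag), or CSV with columns `hospital_id`,
#' `x`/`lon`, `y`/`lat`, `pediatric`.
#'
#' @param hospitals a [HospitalSet-class].
#' @inheritParams writeDemand
#' @return `readHospitals` returns a [HospitalSet-class]; `writeHospitals`
#'   the path, invisibly.
#' @export
writeHospitals <- function(hospitals, path,
                           format = c("auto", "geojson", "csv")) {
  stopifnot(is(hospitals, "HospitalSet"))
  format <- resolveFormat(match.arg(format), path)
  df <- hospitals@sites
  planar <- hospitals@mode == "planar"
  if (format == "csv") {
    out <- data.frame(hospital_id = df$hospital_id, df$x, df$y,
                      pediatric = df$service, stringsAsFactors = FALSE)
    names(out)[2:3] <- if (planar) c("x", "y") else c("lon", "lat")
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    props <- data.frame(hospital_id = df$hospital_id,
                        pediatric = df$service, stringsAsFactors = FALSE)
    writeGeojson(geojsonPointFeatures(cbind(df$x, df$y), props),
                 hospitals@mode, path)
  }
  invisible(path)
}

#' @rdname writeHospitals
#' @export
readHospitals <- function(path, format = c("auto", "geojson", "csv")) {
  format <- resolveFormat(match.arg(format), path)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    mode <- if (all(c("x", "y") %in% names(df))) "planar"
            else if (all(c("lon", "lat") %in% names(df))) "wgs84"
            else stop("hospital CSV must have x,y (planar) or lon,lat (wgs84)")
    cn <- if (mode == "planar") c("x", "y") else c("lon", "lat")
    tab <- data.frame(hospital_id = as.character(df$hospital_id),
                      x = df[[cn[1L]]], y = df[[cn[2L]]],
                      service = as.logical(df$pediatric),
                      stringsAsFactors = FALSE)
  } else {
    fc <- jsonlite::read_json(path)
    mode <- fc$mode %||% "planar"
    tab <- parsePointFeatures(fc$features, "hospital_id", "pediatric")
    tab$service <- as.logical(tab$pediatric)
    tab$pediatric <- NULL
  }
  if (anyDuplicated(tab$hospital_id))
    stop("duplicate hospital_id: ",
         paste(unique(tab$hospital_id[duplicated(tab$hospital_id)]),
               collapse = ", "))
  new("HospitalSet", sites = tab, mode = mode)
}

#' Real-geography hexagonal demand adapter
#'
#' Builds a demand grid from hexagonal-index cell centroids covering a
#' WGS84 country polygon, with cell areas from an equal-area projection.
#' This package bundles no geospatial indexing backend: the caller must
#' supply one as `backend`, a function `(polygon, resolution)` returning a
#' data.frame with columns `point_id`, `lon`, `lat`, `area_km2`. Densities
#' and urbanization classes are joined afterwards from user-supplied region
#' tables. Without a backend the synthetic (planar) pipeline is unaffected;
#' this entry point simply refuses.
#'
#' @param country_polygon polygon in WGS84 lon/lat (passed to the backend).
#' @param resolution hexagonal-index resolution, integer in 0..15.
#' @param backend optional backend function as described.
#' @return a wgs84-mode [DemandSet-class] with density 0 placeholders.
#' @export
h3DemandAdapter <- function(country_polygon, resolution, backend = NULL) {
  if (!is.numeric(resolution) || resolution < 0 || resolution > 15)
    stop("resolution must lie in 0..15")
  if (is.null(backend))
    stop("real-geo mode unavailable: no hexagonal-index backend supplied")
  cells <- backend(country_polygon, resolution)
  need <- c("point_id", "lon", "lat", "area_km2")
  if (!all(need %in% names(cells)))
    stop("backend must return columns: ", paste(need, collapse = ", "))
  makeDemandSet(data.frame(point_id = cells$point_id, x = cells$lon,
                           y = cells$lat, region_id = NA_character_,
                           urbanization = "urban", density = 0,
                           cell_area = cells$area_km2,
                           stringsAsFactors = FALSE), mode = "wgs84")
}

#' Write a provenance sidecar for a generated artifact
#'
#' Every generated artifact gets a `<path>.meta.json` recording the
#' generator configuration and seed, so outputs are traceable to their
#' inputs.
#'
#' @param path the artifact path.
#' @param config a `SyntheticCountryConfig` (or any list of parameters).
#' @param extra optional named list of extra fields.
#' @return the sidecar path, invisibly.
#' @export
writeSidecar <- function(path, config, extra = list()) {
  side <- paste0(path, ".meta.json")
  payload <- c(list(schema_version = 1L,
                    config = unclass(config)), extra)
  jsonlite::write_json(payload, side, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(side)
}

resolveFormat <- function(format, path) {
  if (format != "auto") return(format)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "geojson"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
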