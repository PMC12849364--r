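#' Configuration of the synthetic-country generator
#'
#' Assembles and validates the parameters of the synthetic geography used to
#' exercise the whole pipeline offline. The defaults mirror the scale ratios
#' of a countrywide analysis at roughly one tenth the size: a 280 x 380 km
#' country, about 1100 hexagon centroids, 100 candidate hospitals of which
#' 31 currently provide the service (the service share of about 30 percent
#' matches the ratio of pediatric to acute hospitals that motivates the
#' analysis).
#'
#' @param country_width_km,country_height_km rectangle extents in km.
#' @param n_regions number of Voronoi regions.
#' @param class_shares named numeric of length 3 (urban, intermediate,
#'   rural) summing to 1: the probability of each urbanization class.
#' @param density_ranges named list of `c(low, high)` density intervals in
#'   persons/km^2, one per class, `low < high`.
#' @param hex_spacing_km centre-to-centre spacing of the hexagonal demand
#'   grid.
#' @param n_hospitals number of candidate sites.
#' @param n_service number of sites flagged as current service sites.
#' @param site_density_bias exponent >= 0 biasing site placement towards
#'   dense cells (0 = uniform).
#' @param seed integer seed governing every random draw of the generator.
#' @return a validated `SyntheticCountryConfig` list.
#' @examples
#' cfg <- syntheticCountryConfig(seed = 7)
#' cfg$n_hospitals
#' @export
syntheticCountryConfig <- function(country_width_km = 280,
                                   country_height_km = 380,
                                   n_regions = 40,
                                   class_shares = c(urban = 0.25,
                                                    intermediate = 0.40,
                                                    rural = 0.35),
                                   density_ranges = list(
                                     urban = c(500, 3000),
                                     intermediate = c(100, 500),
                                     rural = c(30, 150)),
                                   hex_spacing_km = 10.5,
                                   n_hospitals = 100,
                                   n_service = 31,
                                   site_density_bias = 1,
                                   seed = 1L) {
  if (country_width_km <= 0 || country_height_km <= 0)
    stop("country rectangle must have positive area")
  if (n_regions < 1) stop("n_regions must be positive")
  if (length(class_shares) != 3L || any(class_shares < 0))
    stop("class_shares must be three non-negative numbers")
  if (abs(sum(class_shares) - 1) > 1e-9)
    stop("class_shares must sum to 1 (tolerance 1e-9), got ",
         format(sum(class_shares), digits = 12))
  names(class_shares) <- URBANIZATION_CLASSES
  if (!all(URBANIZATION_CLASSES %in% names(density_ranges)))
    stop("density_ranges must name urban, intermediate and rural")
  for (cl in URBANIZATION_CLASSES) {
    rg <- density_ranges[[cl]]
    if (length(rg) != 2L || rg[1L] <= 0 || rg[1L] >= rg[2L])
      stop("density range for ", cl, " must be positive with low < high")
  }
  if (hex_spacing_km <= 0) stop("hex_spacing_km must be positive")
  if (n_hospitals < 1) stop("n_hospitals must be positive")
  if (n_service < 0 || n_service > n_hospitals)
    stop("n_service must lie in [0, n_hospitals]")
  if (site_density_bias < 0) stop("site_density_bias must be >= 0")
  structure(list(
    country_width_km = country_width_km,
    country_height_km = country_height_km,
    n_regions = as.integer(n_regions),
    class_shares = class_shares,
    density_ranges = density_ranges[URBANIZATION_CLASSES],
    hex_spacing_km = hex_spacing_km,
    n_hospitals = as.integer(n_hospitals),
    n_service = as.integer(n_service),
    site_density_bias = site_density_bias,
    seed = as.integer(seed)),
    class = "SyntheticCountryConfig")
}

#' Generate the regional tiling of a synthetic country
#'
#' Partitions the country rectangle into `n_regions` Voronoi cells of
#' uniformly sampled seed points — the simplest tiling with irregular shapes
#' resembling administrative units. Each region is assigned an urbanization
#' class with probabilities `class_shares` and a density drawn uniformly
#' from its class interval. Deterministic given `config$seed`.
#'
#' @param config a [syntheticCountryConfig()].
#' @return a [RegionSet-class].
#' @export
generateRegions <- function(config) {
  stopifnot(inherits(config, "SyntheticCountryConfig"))
  w <- config$country_width_km
  h <- config$country_height_km
  n <- config$n_regions
  withr::with_seed(config$seed, {
    seeds <- cbind(stats::runif(n, 0, w), stats::runif(n, 0, h))
    cls <- sample(URBANIZATION_CLASSES, n, replace = TRUE,
                  prob = config$class_shares)
    dens <- vapply(cls, function(cl) {
      rg <- config$density_ranges[[cl]]
      stats::runif(1L, rg[1L], rg[2L])
    }, numeric(1L), USE.NAMES = FALSE)
  })
  ids <- sprintf("R%03d", seq_len(n))
  polys <- lapply(seq_len(n), function(k) voronoiCell(seeds, k, w, h))
  names(polys) <- ids
  areas <- vapply(polys, polygonArea, numeric(1L))
  new("RegionSet",
      regions = data.frame(region_id = ids, urbanization = cls,
                           density = dens, seed_x = seeds[, 1L],
                           seed_y = seeds[, 2L], area_km2 = unname(areas),
                           stringsAsFactors = FALSE),
      polygons = polys, bbox = c(w, h))
}

# Area of one pointy-top hexagon cell with centre spacing s km.
hexCellArea <- function(spacing) sqrt(3) / 2 * spacing^2

#' Lay a hexagonal demand grid over a region tiling
#'
#' Places the centroids of a pointy-top hexagonal lattice (centre-to-centre
#' spacing `hex_spacing_km`) over the country rectangle, anchored half a
#' spacing in from the origin, and keeps centroids inside the rectangle.
#' Each centroid stands for the homes of patients in its hexagon cell: it
#' inherits the density and urbanization class of the region containing it
#' (boundary ties broken by lowest region id) and carries the full hexagon
#' cell area, from which the cell population is derived.
#'
#' @param regions a [RegionSet-class].
#' @param hex_spacing_km centre spacing in km; must leave at least one
#'   centroid inside the rectangle.
#' @param seed unused (the lattice is deterministic); accepted so every
#'   generator stage shares one calling convention.
#' @return a planar-mode [DemandSet-class].
#' @export
generateDemandGrid <- function(regions, hex_spacing_km, seed = 0L) {
  stopifnot(is(regions, "RegionSet"))
  s <- hex_spacing_km
  if (s <= 0) stop("hex spacing must be positive")
  w <- regions@bbox[1L]
  h <- regions@bbox[2L]
  v <- s * sqrt(3) / 2
  if (v / 2 > h || s / 2 > w)
    stop("hex spacing ", s, " km exceeds the country extent: empty grid")
  ys <- seq(v / 2, h, by = v)
  pts <- NULL
  if (length(ys) && v / 2 <= h) {
    rows <- lapply(seq_along(ys) - 1L, function(row) {
      x0 <- s / 2 + (row %% 2L) * (s / 2)
      if (x0 > w) return(NULL)
      xs <- seq(x0, w, by = s)
      cbind(xs, ys[row + 1L])
    })
    pts <- do.call(rbind, rows)
  }
  if (is.null(pts) || nrow(pts) == 0L)
    stop("hex spacing ", s, " km exceeds the country extent: empty grid")
  seeds <- as.matrix(regions@regions[, c("seed_x", "seed_y")])
  ridx <- nearestSeed(pts[, 1L], pts[, 2L], seeds)
  area <- hexCellArea(s)
  df <- data.frame(
    point_id = sprintf("C%05d", seq_len(nrow(pts))),
    x = pts[, 1L], y = pts[, 2L],
    region_id = regions@regions$region_id[ridx],
    urbanization = regions@regions$urbanization[ridx],
    density = regions@regions$density[ridx],
    cell_area = area, stringsAsFactors = FALSE)
  df$population <- df$density * df$cell_area
  new("DemandSet", points = df, mode = "planar")
}

#' Place candidate hospital sites on demand centroids
#'
#' Samples `n_hospitals` distinct demand centroids as candidate sites, with
#' probability proportional to `density^site_density_bias` (sites
#' concentrate where people are, as real hospitals do), then flags exactly
#' `n_service` of them as current service sites by the same biased sampling.
#' Placing sites on centroids makes zero travel time attainable and keeps
#' degenerate cases exercised.
#'
#' @param demand a [DemandSet-class].
#' @param n_hospitals,n_service counts (`n_service <= n_hospitals`).
#' @param site_density_bias exponent >= 0; 0 gives uniform placement.
#' @param seed integer seed.
#' @return a [HospitalSet-class] in the demand set's coordinate mode.
#' @export
generateHospitals <- function(demand, n_hospitals, n_service,
                              site_density_bias = 1, seed = 1L) {
  stopifnot(is(demand, "DemandSet"))
  df <- demand@points
  m <- nrow(df)
  if (n_hospitals > m)
    stop("n_hospitals (", n_hospitals, ") exceeds the number of demand points (",
         m, ")")
  if (n_service > n_hospitals)
    stop("n_service must not exceed n_hospitals")
  wgt <- df$density^site_density_bias
  if (all(wgt == 0)) wgt <- rep(1, m)
  withr::with_seed(seed, {
    pick <- sample.int(m, n_hospitals, replace = FALSE, prob = wgt)
    svc <- if (n_service > 0L)
      sample(seq_len(n_hospitals), n_service, replace = FALSE,
             prob = wgt[pick])
    else integer(0)
  })
  sites <- data.frame(
    hospital_id = sprintf("H%04d", seq_len(n_hospitals)),
    x = df$x[pick], y = df$y[pick],
    service = seq_len(n_hospitals) %in% svc,
    demand_point_id = df$point_id[pick],
    stringsAsFactors = FALSE)
  new("HospitalSet", sites = sites, mode = demand@mode)
}

#' Generate a complete synthetic country
#'
#' Runs the three generator stages — region tiling, hexagonal demand grid,
#' biased site placement — from one configuration. Stage seeds are derived
#' from `config$seed` so the whole geography is reproducible bit for bit.
#'
#' @param config a [syntheticCountryConfig()].
#' @return list with elements `regions` ([RegionSet-class]), `demand`
#'   ([DemandSet-class]), `hospitals` ([HospitalSet-class]) and `config`.
#' @examples
#' ctry <- generateSyntheticCountry(syntheticCountryConfig(
#'   country_width_km = 100, country_height_km = 100, n_regions = 5,
#'   hex_spacing_km = 12, n_hospitals = 10, n_service = 3, seed = 42))
#' nrow(demandPoints(ctry$demand))
#' @export
generateSyntheticCountry <- function(config = syntheticCountryConfig()) {
  regions <- generateRegions(config)
  demand <- generateDemandGrid(regions, config$hex_spacing_km)
  hospitals <- generateHospitals(demand, config$n_hospitals,
                                 config$n_service,
                                 config$site_density_bias,
                                 seed = config$seed + 1L)
  list(regions = regions, demand = demand, hospitals = hospitals,
       config = config)
}
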