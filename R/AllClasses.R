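#' @import methods
NULL

#' Tiling of a rectangular country into density-homogeneous regions
#'
#' A `RegionSet` partitions the rectangle `[0, width] x [0, height]` (planar
#' kilometre coordinates) into convex polygonal regions, each carrying an
#' urbanization class (`"urban"`, `"intermediate"` or `"rural"`) and a
#' constant population density in persons per square kilometre. It stands in
#' for the administrative regions (with their urban-rural typology and
#' density) that drive demand weighting in the accessibility analysis.
#'
#' @slot regions `data.frame` with columns `region_id` (character, unique),
#'   `urbanization` (one of the three classes), `density` (persons/km^2, > 0),
#'   `seed_x`, `seed_y` (generator points of the Voronoi cells) and
#'   `area_km2` (polygon area).
#' @slot polygons named `list` of two-column matrices (x, y vertices of each
#'   closed convex cell), names matching `region_id`.
#' @slot bbox numeric of length 2: country width and height in km.
#'
#' @seealso [generateRegions()]
#' @export
setClass("RegionSet",
  slots = c(regions = "data.frame", polygons = "list", bbox = "numeric"))

setValidity("RegionSet", function(object) {
  msg <- character()
  df <- object@regions
  need <- c("region_id", "urbanization", "density", "seed_x", "seed_y", "area_km2")
  if (!all(need %in% names(df)))
    return(paste("regions must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(df$region_id)) msg <- c(msg, "duplicate region_id")
  if (!all(df$urbanization %in% URBANIZATION_CLASSES))
    msg <- c(msg, "urbanization must be urban/intermediate/rural")
  if (any(df$density <= 0)) msg <- c(msg, "densities must be positive")
  if (length(object@bbox) != 2L || any(object@bbox <= 0))
    msg <- c(msg, "bbox must be two positive extents")
  if (!identical(sort(names(object@polygons)), sort(as.character(df$region_id))))
    msg <- c(msg, "polygon names must match region ids")
  tot <- sum(df$area_km2)
  if (abs(tot - prod(object@bbox)) > 1e-6 * prod(object@bbox))
    msg <- c(msg, "region areas do not tile the country rectangle")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Demand points: hexagon centroids with population weights
#'
#' A `DemandSet` is an ordered collection of demand points, each the centroid
#' of a hexagonal grid cell standing in for patient homes. Every point
#' carries its region's population density, its cell area, and the derived
#' cell population (density times area; kept fractional so that weighted
#' statistics are exact).
#'
#' @slot points `data.frame` with columns `point_id` (unique), `x`, `y`
#'   (km in planar mode, lon/lat degrees in wgs84 mode), `region_id`,
#'   `urbanization`, `density` (persons/km^2), `cell_area` (km^2) and
#'   `population` (persons, = density * cell_area).
#' @slot mode `"planar"` or `"wgs84"`.
#'
#' @seealso [generateDemandGrid()], [readDemand()], [writeDemand()]
#' @export
setClass("DemandSet", slots = c(points = "data.frame", mode = "character"))

setValidity("DemandSet", function(object) {
  df <- object@points
  msg <- character()
  need <- c("point_id", "x", "y", "region_id", "urbanization", "density",
            "cell_area", "population")
  if (!all(need %in% names(df)))
    return(paste("points must have columns:", paste(need, collapse = ", ")))
  if (nrow(df) < 1L) msg <- c(msg, "a DemandSet needs at least one point")
  if (anyDuplicated(df$point_id))
    msg <- c(msg, paste("duplicate point_id:",
      paste(unique(df$point_id[duplicated(df$point_id)]), collapse = ", ")))
  if (!object@mode %in% c("planar", "wgs84"))
    msg <- c(msg, "mode must be 'planar' or 'wgs84'")
  if (any(df$density < 0)) msg <- c(msg, "densities must be non-negative")
  if (any(df$cell_area <= 0)) msg <- c(msg, "cell areas must be positive")
  bad <- abs(df$population - df$density * df$cell_area) >
    1e-9 * pmax(1, abs(df$population))
  if (any(bad))
    msg <- c(msg, paste("population != density * cell_area for:",
      paste(df$point_id[bad], collapse = ", ")))
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Candidate hospital sites
#'
#' A `HospitalSet` holds candidate facility sites; a subset is flagged as
#' currently providing the service under study (in the motivating analysis,
#' pediatric emergency and inpatient care).
#'
#' @slot sites `data.frame` with columns `hospital_id` (unique), `x`, `y`,
#'   and `service` (logical: currently a service site).
#' @slot mode `"planar"` or `"wgs84"`.
#'
#' @seealso [generateHospitals()], [readHospitals()], [writeHospitals()]
#' @export
setClass("HospitalSet", slots = c(sites = "data.frame", mode = "character"))

setValidity("HospitalSet", function(object) {
  df <- object@sites
  msg <- character()
  need <- c("hospital_id", "x", "y", "service")
  if (!all(need %in% names(df)))
    return(paste("sites must have columns:", paste(need, collapse = ", ")))
  if (nrow(df) < 1L) msg <- c(msg, "a HospitalSet needs at least one site")
  if (anyDuplicated(df$hospital_id)) msg <- c(msg, "duplicate hospital_id")
  if (!is.logical(df$service)) msg <- c(msg, "service flag must be logical")
  if (!object@mode %in% c("planar", "wgs84"))
    msg <- c(msg, "mode must be 'planar' or 'wgs84'")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Origin-destination travel-time matrix
#'
#' Car travel times in minutes between every demand point (rows) and every
#' candidate hospital (columns). All entries must be finite and
#' non-negative: unreachable pairs are a data error, not infinity, because
#' the optimization objective must stay finite.
#'
#' @slot values numeric matrix, minutes; rownames are demand point ids and
#'   colnames hospital ids.
#' @export
setClass("TravelMatrix", slots = c(values = "matrix"))

setValidity("TravelMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must carry demand ids as rownames and hospital ids as colnames")
  if (anyDuplicated(rownames(v)) || anyDuplicated(colnames(v)))
    msg <- c(msg, "duplicate row or column ids")
  if (!all(is.finite(v))) msg <- c(msg, "all travel times must be finite")
  else if (any(v < 0)) msg <- c(msg, "travel times must be non-negative")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Population-weighted travel-time matrix
#'
#' Entry (c, h) is `w_ch = p_c * t_ch`: the travel time from demand point c
#' to hospital h scaled by c's population density. These are the objective
#' coefficients of the p-median program.
#'
#' @slot values numeric matrix of weighted travel times (row/col ids as in
#'   [TravelMatrix-class]).
#' @slot densities named numeric: the per-row density weights `p_c`.
#' @export
setClass("WeightedMatrix", slots = c(values = "matrix", densities = "numeric"))

setValidity("WeightedMatrix", function(object) {
  v <- object@values
  d <- object@densities
  msg <- character()
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must carry demand ids as rownames and hospital ids as colnames")
  if (!identical(names(d), rownames(v)))
    msg <- c(msg, "density names must match matrix rownames")
  if (!all(is.finite(v))) msg <- c(msg, "all weighted times must be finite")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Policy scenario for site selection
#'
#' Describes which sites may be selected and how many. In the `liberal`
#' scenario any candidate may receive the service; in the `prioritized`
#' scenario existing service sites are retained when p exceeds their count,
#' and selection is restricted to them when p is below it.
#'
#' @slot p integer: number of sites to open.
#' @slot mode `"liberal"` or `"prioritized"`.
#' @slot serviceSet character: ids of current service sites (required for
#'   prioritized mode).
#' @slot linking `"per_pair"` (x_ch <= y_h for every pair) or `"big_m"`
#'   (sum_c x_ch <= M y_h per site).
#' @slot bigM numeric: the Big-M constant; `NA` means "use m, the number of
#'   demand points", the tightest valid constant.
#' @seealso [scenarioConfig()]
#' @export
setClass("ScenarioConfig",
  slots = c(p = "integer", mode = "character", serviceSet = "character",
            linking = "character", bigM = "numeric"))

setValidity("ScenarioConfig", function(object) {
  msg <- character()
  if (length(object@p) != 1L || is.na(object@p) || object@p < 1L)
    msg <- c(msg, "p must be a single positive integer")
  if (!object@mode %in% c("liberal", "prioritized"))
    msg <- c(msg, "mode must be 'liberal' or 'prioritized'")
  if (object@mode == "prioritized" && length(object@serviceSet) == 0L)
    msg <- c(msg, "prioritized mode requires a non-empty service set")
  if (!object@linking %in% c("per_pair", "big_m"))
    msg <- c(msg, "linking must be 'per_pair' or 'big_m'")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' p-median integer program (built, not yet solved)
#'
#' The explicit optimization model assembled from a [WeightedMatrix-class]
#' and a [ScenarioConfig-class]: objective `min sum_c sum_h x_ch * w_ch`,
#' assignment constraints `sum_h x_ch = 1`, a linking family tying x to the
#' open-site indicators y, pinned y values implied by the scenario, and a
#' cardinality constraint on y.
#'
#' @slot W the [WeightedMatrix-class] providing the objective coefficients.
#' @slot candidates character: hospital ids whose y is a free variable.
#' @slot pinnedOpen character: hospital ids with y fixed to 1.
#' @slot pinnedClosed character: hospital ids with y fixed to 0.
#' @slot cardinality integer: required number of open sites among
#'   `candidates` plus `pinnedOpen`.
#' @slot linking,bigM linking formulation (see [ScenarioConfig-class]);
#'   `bigM` is resolved to its numeric value here.
#' @slot scenario the originating [ScenarioConfig-class].
#' @slot nX,nY integer: numbers of assignment and site variables.
#' @seealso [buildPMedianModel()], [solvePMedian()]
#' @export
setClass("PMedianModel",
  slots = c(W = "WeightedMatrix", candidates = "character",
            pinnedOpen = "character", pinnedClosed = "character",
            cardinality = "integer", linking = "character", bigM = "numeric",
            scenario = "ScenarioConfig", nX = "integer", nY = "integer"))

#' Solved site selection and assignment
#'
#' The result of an exact p-median solve, a brute-force enumeration, or the
#' k-means allocation heuristic: the set of open sites, the nearest-open
#' assignment of every demand point, and the population-weighted objective
#' `z = sum_c min_{h open} w_ch`.
#'
#' @slot openSites character: ids of the selected sites.
#' @slot assignment `data.frame` with columns `point_id`, `hospital_id`,
#'   `minutes` (travel time to the assigned site).
#' @slot objective numeric: weighted objective z (person-density-minutes).
#' @slot status `"optimal"`, `"heuristic"` or `"infeasible"`.
#' @slot gap numeric: solver integrality gap (0 for enumeration).
#' @slot method `"milp"`, `"brute_force"`, `"kmeans"` or `"fixed"`.
#' @slot scenario list echoing the scenario / configuration used.
#' @export
setClass("AllocationSolution",
  slots = c(openSites = "character", assignment = "data.frame",
            objective = "numeric", status = "character", gap = "numeric",
            method = "character", scenario = "list"))

setValidity("AllocationSolution", function(object) {
  msg <- character()
  if (!object@status %in% c("optimal", "heuristic", "infeasible"))
    msg <- c(msg, "status must be optimal, heuristic or infeasible")
  if (object@status != "infeasible") {
    need <- c("point_id", "hospital_id", "minutes")
    if (!all(need %in% names(object@assignment)))
      msg <- c(msg, "assignment needs point_id, hospital_id, minutes")
    else if (!all(object@assignment$hospital_id %in% object@openSites))
      msg <- c(msg, "assignments must target open sites")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Accessibility statistics for one stratum
#'
#' Weighted and unweighted summaries of nearest-facility travel time.
#' "Weighted" means population-frequency-weighted: each demand point
#' contributes its cell population as a frequency weight, so results stay in
#' minutes. Quantiles use the lower weighted quantile (smallest value whose
#' cumulative weight reaches the target mass; no interpolation).
#'
#' @slot weightedMean,weightedMedian,weightedIqrLow,weightedIqrHigh minutes.
#' @slot unweightedMean,unweightedMedian,unweightedIqrLow,unweightedIqrHigh minutes.
#' @slot propAboveThreshold fraction of population with travel time strictly
#'   above the threshold.
#' @slot populationAboveThreshold persons above the threshold.
#' @slot populationTotal persons in the stratum.
#' @slot thresholdMinutes the threshold (default 40 min, the regulatory
#'   accessibility benchmark).
#' @slot stratum `"overall"`, `"urban"`, `"intermediate"` or `"rural"`.
#' @slot n integer: number of demand points summarized.
#' @seealso [accessSummary()], [stratifiedMetrics()]
#' @export
setClass("AccessMetrics",
  slots = c(weightedMean = "numeric", weightedMedian = "numeric",
            weightedIqrLow = "numeric", weightedIqrHigh = "numeric",
            unweightedMean = "numeric", unweightedMedian = "numeric",
            unweightedIqrLow = "numeric", unweightedIqrHigh = "numeric",
            propAboveThreshold = "numeric",
            populationAboveThreshold = "numeric",
            populationTotal = "numeric",
            thresholdMinutes = "numeric", stratum = "character",
            n = "integer"))

setValidity("AccessMetrics", function(object) {
  msg <- character()
  if (object@propAboveThreshold < 0 || object@propAboveThreshold > 1)
    msg <- c(msg, "propAboveThreshold must lie in [0, 1]")
  if (object@weightedIqrLow > object@weightedMedian + 1e-9 ||
      object@weightedMedian > object@weightedIqrHigh + 1e-9)
    msg <- c(msg, "weighted IQR must bracket the weighted median")
  if (object@unweightedIqrLow > object@unweightedMedian + 1e-9 ||
      object@unweightedMedian > object@unweightedIqrHigh + 1e-9)
    msg <- c(msg, "unweighted IQR must bracket the unweighted median")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Two-sample travel-time distribution comparison
#'
#' @slot statistic Mann-Whitney U (convention: number of pairs in which the
#'   first sample exceeds the second, plus half the ties).
#' @slot pValue two-sided p value, tie-corrected normal approximation.
#' @slot normalityPA,normalityPB Shapiro-Wilk p values of each sample
#'   (computed on evenly spaced order statistics when a sample exceeds 5000).
#' @seealso [compareDistributions()]
#' @export
setClass("ComparisonResult",
  slots = c(statistic = "numeric", pValue = "numeric",
            normalityPA = "numeric", normalityPB = "numeric"))

#' k-means clustering of demand points in weighted-travel-time space
#'
#' @slot labels integer cluster index per demand point (1..k).
#' @slot centers k x n matrix of cluster centers in the per-hospital
#'   weighted-travel-time feature space.
#' @slot inertia within-cluster sum of squares.
#' @slot memberPopulation numeric: total population per cluster.
#' @seealso [clusterDemand()]
#' @export
setClass("ClusterResult",
  slots = c(labels = "integer", centers = "matrix", inertia = "numeric",
            memberPopulation = "numeric"))

#' Hospital-quantity sweep result
#'
#' One row per (mode, p): the optimization objective, the open-site count,
#' and evaluation-grid accessibility metrics.
#'
#' @slot table `data.frame` with columns `mode`, `p`, `status`, `objective`,
#'   `n_open`, `weighted_mean`, `unweighted_mean`, `weighted_median`,
#'   `prop_above_threshold`, `population_above`.
#' @seealso [runSweep()], [exportSweep()]
#' @export
setClass("SweepResult", slots = c(table = "data.frame"))

URBANIZATION_CLASSES <- c("urban", "intermediate", "rural")
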