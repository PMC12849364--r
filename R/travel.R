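#' Synthetic road travel model
#'
#' Stands in for a routing engine: travel time is straight-line distance
#' inflated by a circuity (detour) factor at a constant driving speed,
#' `minutes = 60 * detour_factor * distance_km / speed_kmh`. Distance is
#' Euclidean in planar mode and great-circle (haversine) in wgs84 mode. The
#' default detour factor of 1.3 approximates typical road-network circuity;
#' the default speed of 70 km/h a mixed rural/highway car journey.
#'
#' @param speed_kmh positive driving speed.
#' @param detour_factor circuity multiplier, >= 1.
#' @return a `SyntheticTravelParams` list.
#' @export
syntheticTravelParams <- function(speed_kmh = 70, detour_factor = 1.3) {
  if (speed_kmh <= 0) stop("speed_kmh must be positive")
  if (detour_factor < 1) stop("detour_factor must be >= 1")
  structure(list(speed_kmh = speed_kmh, detour_factor = detour_factor),
            class = "SyntheticTravelParams")
}

#' Travel time between two points under the synthetic road model
#'
#' @param origin,dest length-2 numeric coordinates (km in planar mode,
#'   lon/lat degrees in wgs84 mode).
#' @param params a [syntheticTravelParams()].
#' @param mode `"planar"` or `"wgs84"`.
#' @return minutes.
#' @examples
#' syntheticTravelTime(c(0, 0), c(30, 40))  # 60 * 1.3 * 50 / 70
#' @export
syntheticTravelTime <- function(origin, dest,
                                params = syntheticTravelParams(),
                                mode = c("planar", "wgs84")) {
  mode <- match.arg(mode)
  d <- if (mode == "planar")
    sqrt((origin[1L] - dest[1L])^2 + (origin[2L] - dest[2L])^2)
  else
    haversineKm(origin[1L], origin[2L], dest[1L], dest[2L])
  60 * params$detour_factor * d / params$speed_kmh
}

#' Build the demand-by-hospital travel-time matrix
#'
#' Computes `t[c, h]` for every demand point c (rows) and hospital h
#' (columns), preserving input order on both axes. The default travel
#' function is the synthetic road model; any function
#' `(ox, oy, dx, dy) -> minutes` (vectorized over origins) can be plugged
#' in instead.
#'
#' @param demand a [DemandSet-class].
#' @param hospitals a [HospitalSet-class] in the same coordinate mode.
#' @param params a [syntheticTravelParams()] for the default travel model.
#' @param travel_fn optional replacement travel function.
#' @return a [TravelMatrix-class] in minutes.
#' @export
buildTravelMatrix <- function(demand, hospitals,
                              params = syntheticTravelParams(),
                              travel_fn = NULL) {
  stopifnot(is(demand, "DemandSet"), is(hospitals, "HospitalSet"))
  if (demand@mode != hospitals@mode)
    stop("demand (", demand@mode, ") and hospitals (", hospitals@mode,
         ") use different coordinate modes")
  dp <- demand@points
  hs <- hospitals@sites
  if (nrow(dp) == 0L || nrow(hs) == 0L)
    stop("demand and hospital sets must be non-empty")
  vals <- vapply(seq_len(nrow(hs)), function(j) {
    if (is.null(travel_fn)) {
      d <- if (demand@mode == "planar")
        sqrt((dp$x - hs$x[j])^2 + (dp$y - hs$y[j])^2)
      else
        haversineKm(dp$x, dp$y, hs$x[j], hs$y[j])
      60 * params$detour_factor * d / params$speed_kmh
    } else {
      travel_fn(dp$x, dp$y, hs$x[j], hs$y[j])
    }
  }, numeric(nrow(dp)))
  vals <- matrix(vals, nrow = nrow(dp), ncol = nrow(hs),
                 dimnames = list(dp$point_id, hs$hospital_id))
  new("TravelMatrix", values = vals)
}

#' Population-weight a travel-time matrix
#'
#' Scales row c of the travel matrix by the density p_c of demand point c,
#' giving the weighted travel times `w[c, h] = p_c * t[c, h]` that form the
#' p-median objective coefficients.
#'
#' @param tmat a [TravelMatrix-class].
#' @param demand the [DemandSet-class] whose row ids must match the matrix.
#' @return a [WeightedMatrix-class].
#' @export
weightMatrix <- function(tmat, demand) {
  stopifnot(is(tmat, "TravelMatrix"), is(demand, "DemandSet"))
  if (!identical(rownames(tmat@values), demand@points$point_id))
    stop("travel-matrix rows do not match the demand point ids")
  dens <- demand@points$density
  names(dens) <- demand@points$point_id
  new("WeightedMatrix", values = tmat@values * dens, densities = dens)
}

#' Nearest open facility for every demand point
#'
#' For a subset of open hospitals, assigns each demand point to the open
#' hospital with minimal travel time; ties are broken by first column
#' order, deterministically.
#'
#' @param tmat a [TravelMatrix-class] (or [WeightedMatrix-class]; the
#'   argmin is taken over its columns either way).
#' @param open_set non-empty character vector of hospital ids, a subset of
#'   the matrix columns.
#' @return `data.frame` with columns `point_id`, `hospital_id`, `minutes`
#'   (or weighted value when given a weighted matrix).
#' @export
nearestAssignment <- function(tmat, open_set) {
  v <- if (is(tmat, "TravelMatrix") || is(tmat, "WeightedMatrix"))
    tmat@values else tmat
  if (length(open_set) == 0L) stop("open_set must be non-empty")
  missing <- setdiff(open_set, colnames(v))
  if (length(missing))
    stop("open sites not among hospital columns: ",
         paste(missing, collapse = ", "))
  sub <- v[, open_set, drop = FALSE]
  idx <- max.col(-sub, ties.method = "first")
  data.frame(point_id = rownames(v),
             hospital_id = open_set[idx],
             minutes = sub[cbind(seq_len(nrow(sub)), idx)],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write / read a travel-time matrix as CSV
#'
#' Layout: first column `point_id` (demand rows), remaining columns named
#' by hospital id, entries in minutes written with full precision.
#'
#' @param tmat a [TravelMatrix-class].
#' @param path CSV path.
#' @return `readTravelMatrix` returns a [TravelMatrix-class];
#'   `writeTravelMatrix` the path, invisibly.
#' @export
writeTravelMatrix <- function(tmat, path) {
  stopifnot(is(tmat, "TravelMatrix"))
  df <- data.frame(point_id = rownames(tmat@values),
                   tmat@values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTravelMatrix
#' @export
readTravelMatrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "point_id")
    stop("travel-matrix CSV must start with a point_id column")
  v <- as.matrix(df[, -1L, drop = FALSE])
  rownames(v) <- as.character(df$point_id)
  if (any(!is.finite(v)))
    stop("travel-matrix contains non-finite entries; unreachable pairs ",
         "must be resolved before optimization")
  new("TravelMatrix", values = v)
}

#' Adapter contract for external matrix routing
#'
#' The real-geography path sources travel times from an external routing
#' engine. This adapter implements the cache side of that contract: when
#' `cache` exists, the matrix is replayed from CSV with no network access;
#' otherwise a user-supplied `fetch` function `(demand, hospitals) ->
#' matrix` is called and its (validated) result cached. In synthetic mode
#' the adapter refuses — the synthetic travel model is authoritative there.
#'
#' @param demand a [DemandSet-class] (wgs84 mode).
#' @param hospitals a [HospitalSet-class] (wgs84 mode).
#' @param cache CSV cache path.
#' @param fetch optional function performing the external matrix request.
#' @return a [TravelMatrix-class].
#' @export
routingAdapter <- function(demand, hospitals, cache, fetch = NULL) {
  if (demand@mode != "wgs84")
    stop("routing adapter is disabled in synthetic (planar) mode; ",
         "use buildTravelMatrix instead")
  if (file.exists(cache)) {
    tmat <- readTravelMatrix(cache)
  } else {
    if (is.null(fetch))
      stop("no cached matrix at ", cache, " and no fetch function supplied")
    vals <- fetch(demand, hospitals)
    if (!all(is.finite(vals)) || any(vals < 0))
      stop("routing backend returned unreachable or negative pairs; ",
           "all entries must be finite and non-negative")
    if (!identical(dim(vals),
                   c(nrow(demand@points), nrow(hospitals@sites))))
      stop("routing backend returned a matrix of the wrong dimensions")
    dimnames(vals) <- list(demand@points$point_id,
                           hospitals@sites$hospital_id)
    tmat <- new("TravelMatrix", values = vals)
    writeTravelMatrix(tmat, cache)
  }
  if (!identical(rownames(tmat@values), demand@points$point_id) ||
      !identical(colnames(tmat@values), hospitals@sites$hospital_id))
    stop("cached matrix ids do not match the demand/hospital sets")
  tmat
}
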