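#' k-means allocation settings
#'
#' @param k number of clusters = number of sites to select.
#' @param n_restarts independent k-means++ restarts; the best inertia wins.
#' @param max_iter Lloyd iteration cap per restart.
#' @param seed integer seed; restart r uses derived seed `seed + r - 1`.
#' @param matching `"center_argmin"` (default): each cluster opens the
#'   hospital with the smallest coordinate of its center in
#'   weighted-travel-time feature space — i.e. the hospital with least mean
#'   weighted travel time from the cluster's members, which recovers the
#'   exact 1-median when k = 1. `"geographic"`: cluster demand coordinates
#'   weighted by population and match each center to the travel-time-nearest
#'   hospital of its closest demand point.
#' @return a `KMeansConfig` object.
#' @export
kMeansConfig <- function(k, n_restarts = 10, max_iter = 300, seed = 1L,
                         matching = c("center_argmin", "geographic")) {
  if (k < 1) stop("k must be positive")
  new("KMeansConfig", k = as.integer(k),
      nRestarts = as.integer(n_restarts), maxIter = as.integer(max_iter),
      seed = as.integer(seed), matching = match.arg(matching))
}
setClass("KMeansConfig",
  slots = c(k = "integer", nRestarts = "integer", maxIter = "integer",
            seed = "integer", matching = "character"))

# k-means++ seeding: first center uniform, subsequent centers sampled with
# probability proportional to squared distance from the nearest chosen
# center. Expects the RNG to be seeded by the caller.
kmeansPPIndices <- function(X, k) {
  m <- nrow(X)
  idx <- integer(k)
  idx[1L] <- sample.int(m, 1L)
  d2 <- rowSums((X - matrix(X[idx[1L], ], m, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    idx[j] <- if (sum(d2) > 0) sample.int(m, 1L, prob = d2)
              else sample(setdiff(seq_len(m), idx[seq_len(j - 1L)]), 1L)
    d2 <- pmin(d2, rowSums((X - matrix(X[idx[j], ], m, ncol(X),
                                       byrow = TRUE))^2))
  }
  idx
}

# One weighted Lloyd run from given initial centers; returns labels,
# centers, inertia. Empty clusters are reseeded at the worst-served point.
lloyd <- function(X, centers, wts, max_iter) {
  m <- nrow(X)
  k <- nrow(centers)
  labels <- integer(m)
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(centers) +
      outer(rep(1, m), rowSums(centers^2))
    new_labels <- max.col(-d2, ties.method = "first")
    nearest_d2 <- d2[cbind(seq_len(m), new_labels)]
    for (j in which(tabulate(new_labels, k) == 0L)) {
      far <- which.max(nearest_d2)
      new_labels[far] <- j
      nearest_d2[far] <- 0
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (j in seq_len(k)) {
      mem <- labels == j
      centers[j, ] <- colSums(X[mem, , drop = FALSE] * wts[mem]) /
        sum(wts[mem])
    }
  }
  d2 <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(centers) +
    outer(rep(1, m), rowSums(centers^2))
  list(labels = labels, centers = centers,
       inertia = sum(wts * pmax(0, d2[cbind(seq_len(m), labels)])))
}

#' Cluster demand points in weighted-travel-time feature space
#'
#' Transposes the view of the weighted matrix: each demand point becomes an
#' observation whose n features are its weighted travel times to the n
#' hospitals; k-means (Lloyd, k-means++ seeding, best of `n_restarts`)
#' groups demand points that are expensive to serve from the same places.
#'
#' @param W a [WeightedMatrix-class] (or plain feature matrix).
#' @param config a [kMeansConfig()].
#' @param weights optional per-observation populations; they set the
#'   cluster priority used later for duplicate-target resolution and, only
#'   when `weight_centers` is `TRUE`, also weight the center updates.
#' @param weight_centers weight observations in the center updates
#'   (population-weighted clustering; the default follows the matching
#'   rule: plain k-means for `center_argmin`, weighted for `geographic`).
#' @return a [ClusterResult-class].
#' @export
clusterDemand <- function(W, config, weights = NULL,
                          weight_centers = config@matching == "geographic") {
  X <- if (is(W, "WeightedMatrix")) W@values else as.matrix(W)
  m <- nrow(X)
  k <- config@k
  if (k > m) stop("k (", k, ") exceeds the number of demand points (", m, ")")
  wts <- if (is.null(weights)) rep(1, m) else as.numeric(weights)
  cwts <- if (weight_centers) wts else rep(1, m)
  ndistinct <- nrow(unique(X))
  if (k > ndistinct)
    stop("k exceeds the number of distinct demand rows (", ndistinct, ")")
  best <- NULL
  for (r in seq_len(config@nRestarts)) {
    init <- withr::with_seed(config@seed + r - 1L, {
      kmeansPPIndices(X, k)
    })
    fit <- lloyd(X, X[init, , drop = FALSE], cwts, config@maxIter)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  new("ClusterResult", labels = best$labels, centers = best$centers,
      inertia = best$inertia,
      memberPopulation = as.numeric(tapply(wts, factor(best$labels,
                                                       seq_len(k)), sum)))
}

#' Map cluster centers to distinct hospitals
#'
#' Under `center_argmin` matching, each cluster opens the hospital whose
#' coordinate in the cluster's center vector is minimal — the hospital with
#' the smallest mean weighted travel time from the cluster's members. When
#' two clusters point at the same hospital, clusters are processed in
#' descending total-member-population order and each takes its best
#' not-yet-taken hospital (a warning reports every such collision), so the
#' returned set always holds exactly k distinct sites.
#'
#' @param result a [ClusterResult-class] with centers in hospital-feature
#'   space (one coordinate per hospital).
#' @param hospital_ids character ids naming the feature columns.
#' @return character vector of k distinct hospital ids, in hospital order.
#' @export
matchClustersToHospitals <- function(result, hospital_ids) {
  centers <- result@centers
  k <- nrow(centers)
  n <- length(hospital_ids)
  if (k > n) stop("more clusters than hospitals")
  prio <- order(-result@memberPopulation, seq_len(k))
  taken <- logical(n)
  chosen <- integer(k)
  for (cl in prio) {
    pref <- order(centers[cl, ])
    pick <- pref[!taken[pref]][1L]
    if (pick != pref[1L])
      warning("cluster ", cl, " lost its best hospital to a larger ",
              "cluster; taking the next available")
    chosen[cl] <- pick
    taken[pick] <- TRUE
  }
  hospital_ids[sort(chosen)]
}

#' k-means-based site selection and allocation
#'
#' The full heuristic: cluster demand points in weighted-travel-time
#' feature space (or geographically, population-weighted, under
#' `matching = "geographic"`), map the k cluster centers to k distinct
#' hospitals, then assign every demand point to its nearest open hospital.
#' The objective is reported as `sum_c min_{h open} w_ch`, directly
#' comparable with the exact p-median objective — and never below it.
#'
#' @param W a [WeightedMatrix-class].
#' @param tmat the matching [TravelMatrix-class].
#' @param demand the [DemandSet-class] (populations weight the clusters).
#' @param config a [kMeansConfig()].
#' @return an [AllocationSolution-class] with method `"kmeans"` and status
#'   `"heuristic"`.
#' @export
kmeansAllocate <- function(W, tmat, demand, config) {
  stopifnot(is(W, "WeightedMatrix"), is(tmat, "TravelMatrix"),
            is(demand, "DemandSet"))
  pops <- demand@points$population
  ids <- colnames(W@values)
  if (config@matching == "center_argmin") {
    cl <- clusterDemand(W, config, weights = pops)
    open <- matchClustersToHospitals(cl, ids)
  } else {
    coords <- as.matrix(demand@points[, c("x", "y")])
    cl <- clusterDemand(coords, config, weights = pops)
    # each geographic center adopts the travel-time preferences of its
    # closest demand point; dedup as in center_argmin matching
    cidx <- vapply(seq_len(config@k), function(j) {
      which.min((coords[, 1L] - cl@centers[j, 1L])^2 +
                (coords[, 2L] - cl@centers[j, 2L])^2)
    }, integer(1L))
    feat <- tmat@values[cidx, , drop = FALSE]
    open <- matchClustersToHospitals(
      new("ClusterResult", labels = cl@labels, centers = feat,
          inertia = cl@inertia, memberPopulation = cl@memberPopulation),
      ids)
  }
  sol <- solutionFromOpen(W, open, "kmeans", "heuristic", 0,
                          list(p = config@k, mode = "kmeans",
                               matching = config@matching,
                               n_restarts = config@nRestarts,
                               seed = config@seed, linking = NA,
                               big_m = NA),
                          tmat)
  sol
}
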