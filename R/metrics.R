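#' Lower weighted quantile
#'
#' Sorts the values and returns the smallest value whose cumulative weight
#' reaches `q` times the total weight. No interpolation: the estimate is
#' always an observed value, which keeps weighted medians and quartiles
#' reproducible and order-statistic exact. With uniform weights this is the
#' lower sample quantile.
#'
#' @param values numeric (travel times in minutes).
#' @param weights non-negative weights (cell populations), not all zero.
#' @param q quantile level(s) in `[0, 1]`; vectorized.
#' @return minutes, one value per `q`.
#' @examples
#' weightedQuantile(c(10, 5, 5), c(1, 2, 1), 0.5)  # 5
#' @export
weightedQuantile <- function(values, weights, q) {
  if (length(values) != length(weights))
    stop("values and weights must have equal length")
  if (any(weights < 0)) stop("weights must be non-negative")
  tot <- sum(weights)
  if (tot == 0) stop("weights must not all be zero")
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]")
  o <- order(values)
  v <- values[o]
  cw <- cumsum(weights[o])
  vapply(q, function(qi) v[which(cw >= qi * tot - 1e-12 * tot)[1L]],
         numeric(1L))
}

#' Summarize nearest-facility travel times for one stratum
#'
#' Computes the full accessibility panel from per-demand-point travel
#' times: the population-weighted mean `sum(pop * t) / sum(pop)`, the
#' unweighted mean, weighted and unweighted medians and interquartile
#' ranges (lower weighted quantiles at 0.25/0.5/0.75), and the share of
#' population whose travel time strictly exceeds the threshold
#' ("exceeding" is read as a strict inequality).
#'
#' @param minutes per-demand-point travel time to the assigned facility.
#' @param demand the matching [DemandSet-class] (populations and strata),
#'   or a numeric vector of populations.
#' @param threshold threshold in minutes (default 40, the regulatory
#'   accessibility benchmark).
#' @param stratum label recorded in the result.
#' @return an [AccessMetrics-class].
#' @export
accessSummary <- function(minutes, demand, threshold = 40,
                          stratum = "overall") {
  pop <- if (is(demand, "DemandSet")) demand@points$population
         else as.numeric(demand)
  if (length(minutes) != length(pop))
    stop("minutes (", length(minutes), ") and populations (", length(pop),
         ") differ in length")
  wq <- weightedQuantile(minutes, pop, c(0.25, 0.5, 0.75))
  uq <- weightedQuantile(minutes, rep(1, length(minutes)),
                         c(0.25, 0.5, 0.75))
  above <- minutes > threshold
  new("AccessMetrics",
      weightedMean = sum(pop * minutes) / sum(pop),
      weightedMedian = wq[2L], weightedIqrLow = wq[1L],
      weightedIqrHigh = wq[3L],
      unweightedMean = mean(minutes),
      unweightedMedian = uq[2L], unweightedIqrLow = uq[1L],
      unweightedIqrHigh = uq[3L],
      propAboveThreshold = sum(pop[above]) / sum(pop),
      populationAboveThreshold = sum(pop[above]),
      populationTotal = sum(pop),
      thresholdMinutes = threshold, stratum = stratum,
      n = length(minutes))
}

#' Accessibility metrics per urbanization class
#'
#' Applies [accessSummary()] to each urbanization stratum and to the whole
#' set. Populations above threshold partition exactly: the class-level
#' numbers sum to the overall number.
#'
#' @param minutes per-demand-point travel times, aligned with `demand`.
#' @param demand a [DemandSet-class].
#' @param threshold threshold in minutes.
#' @return named list of [AccessMetrics-class] (`overall` plus one entry
#'   per class present); use `as.data.frame` on elements, or
#'   [metricsTable()] for the tidy table.
#' @export
stratifiedMetrics <- function(minutes, demand, threshold = 40) {
  stopifnot(is(demand, "DemandSet"))
  cls <- demand@points$urbanization
  bad <- setdiff(unique(cls), URBANIZATION_CLASSES)
  if (length(bad))
    stop("unknown urbanization class: ", paste(bad, collapse = ", "))
  out <- list(overall = accessSummary(minutes, demand, threshold,
                                      "overall"))
  for (cl in intersect(URBANIZATION_CLASSES, unique(cls))) {
    i <- cls == cl
    out[[cl]] <- accessSummary(minutes[i], demand@points$population[i],
                               threshold, cl)
  }
  out
}

#' Tidy table of stratified metrics
#'
#' @param metrics a list of [AccessMetrics-class] (as returned by
#'   [stratifiedMetrics()]), or a single object.
#' @return `data.frame`, one row per stratum.
#' @export
metricsTable <- function(metrics) {
  if (is(metrics, "AccessMetrics")) metrics <- list(metrics)
  do.call(rbind, lapply(metrics, as.data.frame))
}

#' Compare two travel-time distributions
#'
#' Two-sided Mann-Whitney U test with the tie-corrected normal
#' approximation, preceded by Shapiro-Wilk normality checks of each sample
#' (computed on evenly spaced order statistics when a sample exceeds 5000
#' points). Inputs are unweighted per-demand-point travel times. The U
#' statistic follows the first-sample convention: the number of pairs in
#' which the first sample exceeds the second, plus half the ties, so
#' complete separation below gives U = 0.
#'
#' @param times_a,times_b numeric samples of length >= 3.
#' @return a [ComparisonResult-class].
#' @export
compareDistributions <- function(times_a, times_b) {
  if (length(times_a) < 3L || length(times_b) < 3L)
    stop("both samples must hold at least 3 values")
  wt <- stats::wilcox.test(times_a, times_b, exact = FALSE,
                           correct = TRUE)
  new("ComparisonResult",
      statistic = unname(wt$statistic),
      pValue = wt$p.value,
      normalityPA = shapiroSub(times_a),
      normalityPB = shapiroSub(times_b))
}

# Shapiro-Wilk accepts 3..5000 observations; larger samples are thinned to
# 5000 evenly spaced order statistics (deterministic, shape-preserving).
shapiroSub <- function(x) {
  if (length(x) > 5000L) {
    x <- sort(x)[round(seq(1L, length(x), length.out = 5000L))]
  }
  if (stats::sd(x) == 0) return(NA_real_)   # degenerate: test undefined
  stats::shapiro.test(x)$p.value
}

#' Change report between two metric panels
#'
#' Emits, for every metric field, the baseline, the new value, the absolute
#' delta and the percent change; proportions additionally get their change
#' in percentage points. Zero baselines yield `NA` percent changes
#' (undefined, not infinite).
#'
#' @param before,after [AccessMetrics-class] panels of the same stratum.
#' @return `data.frame` with columns `metric`, `before`, `after`,
#'   `delta`, `pct_change`, `pp_change` (percentage points; `NA` for
#'   non-proportion rows).
#' @examples
#' # a proportion falling from 9.17% to 5.86% is a 3.31-point and a
#' # 36.1% relative reduction
#' @export
relativeChange <- function(before, after) {
  stopifnot(is(before, "AccessMetrics"), is(after, "AccessMetrics"))
  fields <- c(weighted_mean = "weightedMean",
              weighted_median = "weightedMedian",
              weighted_iqr_low = "weightedIqrLow",
              weighted_iqr_high = "weightedIqrHigh",
              unweighted_mean = "unweightedMean",
              unweighted_median = "unweightedMedian",
              unweighted_iqr_low = "unweightedIqrLow",
              unweighted_iqr_high = "unweightedIqrHigh",
              prop_above_threshold = "propAboveThreshold",
              population_above = "populationAboveThreshold")
  rows <- lapply(names(fields), function(nm) {
    b <- slot(before, fields[[nm]])
    a <- slot(after, fields[[nm]])
    data.frame(metric = nm, before = b, after = a, delta = a - b,
               pct_change = if (b != 0) 100 * (a - b) / b else NA_real_,
               pp_change = if (nm == "prop_above_threshold")
                 100 * (a - b) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
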