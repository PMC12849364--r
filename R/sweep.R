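#' Hospital-quantity sweep
#'
#' Re-optimizes the site selection over a grid of p values and evaluates
#' every solution on the evaluation grid, tracing how accessibility
#' responds to opening or closing facilities. The optimization objective is
#' provably non-increasing in p under the liberal scenario (a superset of
#' feasible site sets can only help) and this is asserted; evaluation-grid
#' means carry no such guarantee and are reported as observed.
#'
#' @param W the optimization-grid [WeightedMatrix-class].
#' @param p_values integer vector of site counts to try (within
#'   `[1, n]`), non-empty.
#' @param mode `"liberal"` or `"prioritized"`.
#' @param service_set current service site ids (prioritized mode).
#' @param tmat_eval evaluation-grid [TravelMatrix-class] (defaults to the
#'   travel matrix matching `W` if supplied via `tmat_opt`).
#' @param demand_eval evaluation-grid [DemandSet-class] aligned with
#'   `tmat_eval` rows.
#' @param linking linking formulation for the solver.
#' @param threshold travel-time threshold in minutes.
#' @param mip_gap,time_limit solver options.
#' @return a [SweepResult-class]; individual infeasible or failed p values
#'   are recorded in the `status` column, not fatal.
#' @export
runSweep <- function(W, p_values, mode = c("liberal", "prioritized"),
                     service_set = character(0), tmat_eval, demand_eval,
                     linking = c("per_pair", "big_m"), threshold = 40,
                     mip_gap = 1e-6, time_limit = NULL) {
  mode <- match.arg(mode)
  linking <- match.arg(linking)
  if (length(p_values) == 0L) stop("p_values must be non-empty")
  n <- ncol(W@values)
  if (any(p_values < 1L | p_values > n))
    stop("p_values must lie in [1, ", n, "]")
  p_values <- sort(unique(as.integer(p_values)))
  rows <- lapply(p_values, function(p) {
    sol <- tryCatch(
      solveScenario(W, p, mode, service_set, linking,
                    mip_gap = mip_gap, time_limit = time_limit),
      error = function(e) e)
    if (inherits(sol, "error"))
      return(data.frame(mode = mode, p = p, status = "failed",
                        n_open = NA_integer_, objective = NA_real_,
                        weighted_mean = NA_real_, unweighted_mean = NA_real_,
                        weighted_median = NA_real_,
                        prop_above_threshold = NA_real_,
                        population_above = NA_real_,
                        stringsAsFactors = FALSE))
    if (sol@status == "infeasible")
      return(data.frame(mode = mode, p = p, status = "infeasible",
                        n_open = NA_integer_, objective = NA_real_,
                        weighted_mean = NA_real_, unweighted_mean = NA_real_,
                        weighted_median = NA_real_,
                        prop_above_threshold = NA_real_,
                        population_above = NA_real_,
                        stringsAsFactors = FALSE))
    ev <- nearestAssignment(tmat_eval, openSites(sol))
    met <- accessSummary(ev$minutes, demand_eval, threshold)
    data.frame(mode = mode, p = p, status = "optimal",
               n_open = length(openSites(sol)),
               objective = objectiveValue(sol),
               weighted_mean = met@weightedMean,
               unweighted_mean = met@unweightedMean,
               weighted_median = met@weightedMedian,
               prop_above_threshold = met@propAboveThreshold,
               population_above = met@populationAboveThreshold,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (mode == "liberal") {
    ok <- tab$status == "optimal"
    z <- tab$objective[ok]
    if (length(z) > 1L && any(diff(z) > 1e-6 * pmax(1, abs(z[-length(z)]))))
      stop("liberal-mode objective increased with p; solver output ",
           "violates the p-median monotonicity guarantee")
  }
  new("SweepResult", table = tab)
}

sweepSchema <- c("mode", "p", "status", "n_open", "objective",
                 "weighted_mean", "unweighted_mean", "weighted_median",
                 "prop_above_threshold", "population_above")

#' Write / read a sweep table
#'
#' Tidy CSV, one row per (mode, p), fixed column schema; directly
#' plottable as the quantity-response panels (metrics vs number of
#' hospitals).
#'
#' @param sweep a [SweepResult-class] (or a list of them, row-bound).
#' @param path CSV path.
#' @return `readSweep` returns a [SweepResult-class]; `exportSweep` the
#'   path, invisibly.
#' @export
exportSweep <- function(sweep, path) {
  if (is(sweep, "SweepResult")) sweep <- list(sweep)
  tab <- do.call(rbind, lapply(sweep, sweepTable))
  utils::write.csv(tab[, sweepSchema], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname exportSweep
#' @export
readSweep <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(tab), sweepSchema))
    stop("sweep CSV does not match the expected schema")
  new("SweepResult", table = tab)
}
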