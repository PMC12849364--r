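#' Scenario configuration for site selection
#'
#' @param p number of sites to open.
#' @param mode `"liberal"` (any candidate may receive the service) or
#'   `"prioritized"` (existing service sites are retained when `p` exceeds
#'   their count, and selection is restricted to them when `p` is below it).
#' @param service_set character ids of current service sites; required in
#'   prioritized mode.
#' @param linking `"per_pair"` or `"big_m"` (see [ScenarioConfig-class]).
#' @param big_m Big-M constant; `NA` resolves to m, the number of demand
#'   points — the tightest valid constant for `sum_c x_ch <= M y_h`.
#' @return a [ScenarioConfig-class].
#' @export
scenarioConfig <- function(p, mode = c("liberal", "prioritized"),
                           service_set = character(0),
                           linking = c("per_pair", "big_m"),
                           big_m = NA_real_) {
  new("ScenarioConfig", p = as.integer(p), mode = match.arg(mode),
      serviceSet = as.character(service_set),
      linking = match.arg(linking), bigM = as.numeric(big_m))
}

scenarioEcho <- function(scenario) {
  list(p = scenario@p, mode = scenario@mode,
       service_set = scenario@serviceSet, linking = scenario@linking,
       big_m = scenario@bigM)
}

#' Assemble the p-median integer program
#'
#' Translates a weighted travel-time matrix and a policy scenario into the
#' explicit optimization model: objective `min sum x_ch w_ch`, one
#' assignment constraint per demand point, a linking family (per-pair
#' `x_ch <= y_h`, or aggregated Big-M `sum_c x_ch <= M y_h`), and the
#' scenario's cardinality structure on the open-site indicators:
#' \itemize{
#'   \item liberal: `sum_h y_h = p` over all candidates;
#'   \item prioritized, `p < |service_set|`: selection restricted to the
#'     service set (`y = 0` outside it), `sum y = p` within it;
#'   \item prioritized, `p = |service_set|`: every service site pinned
#'     open, everything else closed;
#'   \item prioritized, `p > |service_set|`: service sites pinned open,
#'     `sum_h y_h = p` over all candidates.
#' }
#'
#' @param W a [WeightedMatrix-class].
#' @param scenario a [scenarioConfig()].
#' @return a [PMedianModel-class].
#' @export
buildPMedianModel <- function(W, scenario) {
  stopifnot(is(W, "WeightedMatrix"), is(scenario, "ScenarioConfig"))
  ids <- colnames(W@values)
  m <- nrow(W@values)
  p <- scenario@p
  if (scenario@mode == "liberal") {
    cand <- ids; open0 <- character(0); closed <- character(0)
  } else {
    S <- scenario@serviceSet
    extra <- setdiff(S, ids)
    if (length(extra))
      stop("service set contains non-candidate sites: ",
           paste(extra, collapse = ", "))
    if (p < length(S)) {
      cand <- intersect(ids, S); open0 <- character(0)
      closed <- setdiff(ids, S)
    } else if (p == length(S)) {
      cand <- character(0); open0 <- intersect(ids, S)
      closed <- setdiff(ids, S)
    } else {
      open0 <- intersect(ids, S); cand <- setdiff(ids, S)
      closed <- character(0)
    }
  }
  bigM <- if (is.na(scenario@bigM)) as.numeric(m) else scenario@bigM
  nY <- length(cand) + length(open0)
  new("PMedianModel", W = W, candidates = cand, pinnedOpen = open0,
      pinnedClosed = closed, cardinality = p, linking = scenario@linking,
      bigM = bigM, scenario = scenario,
      nX = as.integer(m * nY), nY = as.integer(nY))
}

rowMinima <- function(v) {
  idx <- max.col(-v, ties.method = "first")
  list(idx = idx, min = v[cbind(seq_len(nrow(v)), idx)])
}

# Shared constructor: derive assignment and objective from an open set by
# the nearest-open rule in w (exact for the p-median objective, and the
# convention used for all reported travel times).
solutionFromOpen <- function(W, open, method, status, gap, scenario,
                             tmat = NULL) {
  v <- W@values[, open, drop = FALSE]
  rm <- rowMinima(v)
  minutes <- if (!is.null(tmat)) {
    tmat@values[cbind(seq_len(nrow(v)), match(open[rm$idx],
                                              colnames(tmat@values)))]
  } else {
    ifelse(W@densities > 0, rm$min / W@densities, NA_real_)
  }
  assignment <- data.frame(point_id = rownames(W@values),
                           hospital_id = open[rm$idx],
                           minutes = unname(minutes),
                           stringsAsFactors = FALSE)
  new("AllocationSolution", openSites = open, assignment = assignment,
      objective = sum(rm$min), status = status, gap = gap,
      method = method, scenario = scenario)
}

infeasibleSolution <- function(method, scenario) {
  new("AllocationSolution", openSites = character(0),
      assignment = data.frame(), objective = NA_real_,
      status = "infeasible", gap = NA_real_, method = method,
      scenario = scenario)
}

#' Solve a built p-median model exactly
#'
#' Delegates the integer program to the bundled HiGHS backend (assignment
#' variables continuous, site indicators binary — exact for this model),
#' then re-derives the assignment from the chosen sites by the nearest-open
#' rule in w and recomputes the objective independently of the solver.
#' Fully pinned models (cardinality equal to the number of openable sites)
#' are resolved directly without a solver call.
#'
#' @param model a [PMedianModel-class].
#' @param tmat optional [TravelMatrix-class] to express assignment minutes
#'   in travel time rather than weighted units.
#' @param mip_gap relative integrality gap demanded of the solver.
#' @param time_limit optional wall-clock limit in seconds.
#' @return an [AllocationSolution-class] with method `"milp"`; status
#'   `"infeasible"` when the scenario admits no feasible open set.
#' @export
solvePMedian <- function(model, tmat = NULL, mip_gap = 1e-6,
                         time_limit = NULL) {
  stopifnot(is(model, "PMedianModel"))
  echo <- scenarioEcho(model@scenario)
  openable <- c(model@pinnedOpen, model@candidates)
  if (model@cardinality > length(openable) ||
      model@cardinality < length(model@pinnedOpen))
    return(infeasibleSolution("milp", echo))
  if (model@cardinality == length(openable)) {
    open <- openable[order(match(openable, colnames(model@W@values)))]
    return(solutionFromOpen(model@W, open, "milp", "optimal", 0, echo,
                            tmat))
  }
  ids <- colnames(model@W@values)
  prob <- list(name = "model",
               columns = match(openable, ids),
               pinned_open = match(model@pinnedOpen, ids),
               cardinality = model@cardinality,
               linking = model@linking, big_m = model@bigM,
               mip_gap = mip_gap, time_limit = time_limit)
  res <- solveBackendBatch(model@W@values, list(prob))[["model"]]
  if (res$status == "infeasible") return(infeasibleSolution("milp", echo))
  if (res$status != "optimal")
    stop("MILP backend did not reach optimality: ",
         res$message %||% res$status)
  open <- ids[unlist(res$open) + 1L]
  solutionFromOpen(model@W, open, "milp", "optimal",
                   as.numeric(res$gap %||% 0), echo, tmat)
}

#' Exhaustive-enumeration oracle for the p-median scenarios
#'
#' Enumerates every feasible open set of the scenario, scores each as
#' `sum_c min_{h open} w_ch`, and returns the minimum; among ties the
#' lexicographically smallest site set (in column order) wins. Used as the
#' independent reference the exact solver is checked against.
#'
#' @param W a [WeightedMatrix-class].
#' @param scenario a [scenarioConfig()].
#' @param tmat optional [TravelMatrix-class] for assignment minutes.
#' @param cap refuse instances with more than this many candidate subsets
#'   (never silently sampled).
#' @return an [AllocationSolution-class] with method `"brute_force"`.
#' @export
bruteForcePMedian <- function(W, scenario, tmat = NULL, cap = 2e6) {
  stopifnot(is(W, "WeightedMatrix"), is(scenario, "ScenarioConfig"))
  model <- buildPMedianModel(W, scenario)
  echo <- scenarioEcho(scenario)
  free <- model@candidates
  k <- model@cardinality - length(model@pinnedOpen)
  if (k < 0 || k > length(free))
    return(infeasibleSolution("brute_force", echo))
  ids <- colnames(W@values)
  nsub <- choose(length(free), k)
  if (nsub > cap)
    stop("brute force refused: ", format(nsub), " candidate subsets ",
         "exceed the cap of ", format(cap))
  free <- free[order(match(free, ids))]   # lexicographic by column order
  subsets <- if (k == 0L) list(integer(0))
             else utils::combn(length(free), k, simplify = FALSE)
  best <- NULL
  bestZ <- Inf
  for (sub in subsets) {
    open <- c(model@pinnedOpen, free[sub])
    z <- sum(rowMinima(W@values[, open, drop = FALSE])$min)
    if (z < bestZ - 1e-12) {
      bestZ <- z
      best <- open
    }
  }
  open <- best[order(match(best, ids))]
  solutionFromOpen(W, open, "brute_force", "optimal", 0, echo, tmat)
}

#' Solve a policy scenario end to end
#'
#' Dispatches the liberal case and the three prioritized cases. When the
#' requested count equals the current service set's size in prioritized
#' mode, the current allocation is returned as-is — no optimization is
#' needed, since every service site is pinned open.
#'
#' @param W a [WeightedMatrix-class].
#' @param p number of sites to open.
#' @param mode `"liberal"` or `"prioritized"`.
#' @param service_set ids of current service sites.
#' @param linking `"per_pair"` or `"big_m"`.
#' @param tmat optional [TravelMatrix-class] for assignment minutes.
#' @param mip_gap,time_limit solver options, see [solvePMedian()].
#' @return an [AllocationSolution-class].
#' @export
solveScenario <- function(W, p, mode = c("liberal", "prioritized"),
                          service_set = character(0),
                          linking = c("per_pair", "big_m"), tmat = NULL,
                          mip_gap = 1e-6, time_limit = NULL) {
  mode <- match.arg(mode)
  linking <- match.arg(linking)
  scenario <- scenarioConfig(p, mode, service_set, linking)
  if (mode == "prioritized" && p == length(service_set)) {
    open <- intersect(colnames(W@values), service_set)
    if (length(open) < length(service_set))
      stop("service set contains non-candidate sites: ",
           paste(setdiff(service_set, open), collapse = ", "))
    return(solutionFromOpen(W, open, "fixed", "optimal", 0,
                            scenarioEcho(scenario), tmat))
  }
  solvePMedian(buildPMedianModel(W, scenario), tmat = tmat,
               mip_gap = mip_gap, time_limit = time_limit)
}

#' Evaluate a user-supplied site set
#'
#' Scores an arbitrary open set under the shared objective (nearest-open
#' weighted travel time), making it directly comparable with optimized
#' solutions — e.g. the current service configuration against the p-median
#' optimum of the same size.
#'
#' @param W a [WeightedMatrix-class].
#' @param open_set character ids of open sites (non-empty, all candidates).
#' @param tmat optional [TravelMatrix-class] for assignment minutes.
#' @return an [AllocationSolution-class] with method `"fixed"` and status
#'   `"heuristic"`.
#' @export
evaluateSiteSet <- function(W, open_set, tmat = NULL) {
  stopifnot(is(W, "WeightedMatrix"))
  if (length(open_set) == 0L) stop("open_set must be non-empty")
  missing <- setdiff(open_set, colnames(W@values))
  if (length(missing))
    stop("unknown sites: ", paste(missing, collapse = ", "))
  open <- colnames(W@values)[colnames(W@values) %in% open_set]
  solutionFromOpen(W, open, "fixed", "heuristic", 0,
                   list(p = length(open), mode = "fixed",
                        service_set = open, linking = NA, big_m = NA),
                   tmat)
}
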