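# End-to-end pipeline over the synthetic country: generate geography,
# build matrices, evaluate the current configuration, optimize (exact and
# k-means), compare, sweep. Every artifact is a deterministic function of
# the configuration and seeds; timestamps appear only in log lines.

logStage <- function(stage, config_hash, seed, t0) {
  message(sprintf("[%s] stage=%s config=%s seed=%s elapsed=%.2fs",
                  format(Sys.time(), "%H:%M:%S"), stage, config_hash,
                  seed, as.numeric(proc.time()[3L] - t0)))
}

configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA)
  substr(unname(tools::md5sum(f)), 1L, 8L)
}

#' Serialize / load an allocation solution as JSON
#'
#' The JSON artifact carries the open site ids, the per-demand assignment
#' (point id, hospital id, minutes), the objective, the scenario echo and
#' solver metadata, plus a schema version.
#'
#' @param sol an [AllocationSolution-class].
#' @param path JSON path.
#' @return `readSolution` returns an [AllocationSolution-class];
#'   `writeSolution` the path, invisibly.
#' @export
writeSolution <- function(sol, path) {
  stopifnot(is(sol, "AllocationSolution"))
  payload <- list(schema_version = 1L,
                  method = sol@method, status = sol@status,
                  objective = sol@objective, solver_gap = sol@gap,
                  scenario = sol@scenario,
                  open_sites = sol@openSites,
                  assignment = sol@assignment)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname writeSolution
#' @export
readSolution <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("AllocationSolution",
      openSites = as.character(x$open_sites),
      assignment = as.data.frame(x$assignment),
      objective = as.numeric(x$objective),
      status = x$status, gap = as.numeric(x$solver_gap %||% 0),
      method = x$method, scenario = as.list(x$scenario))
}

#' Run the full accessibility-optimization pipeline
#'
#' Generates (or accepts) a synthetic country, builds the travel and
#' weighted matrices, evaluates the current service configuration, solves
#' the exact p-median at `p` sites (liberal scenario), runs the k-means
#' allocation heuristic at the same k, writes stratified metrics and a
#' change report for each, and optionally sweeps over a grid of site
#' counts in both policy scenarios. All outputs land in `out_dir`.
#'
#' @param config a [syntheticCountryConfig()].
#' @param out_dir output directory (created if needed).
#' @param p number of sites to select (defaults to the configured number
#'   of current service sites, the paper-style like-for-like comparison).
#' @param threshold travel-time threshold in minutes.
#' @param sweep_p optional integer vector: run the quantity sweep over
#'   these site counts in both scenarios.
#' @param linking solver linking formulation.
#' @param travel_params a [syntheticTravelParams()].
#' @return invisibly, a list with the in-memory objects (`country`,
#'   `tmat`, `W`, `current`, `pmedian`, `kmeans`, `metrics`, `changes`,
#'   `sweep`) and `files` (the artifact paths).
#' @export
runPipeline <- function(config = syntheticCountryConfig(), out_dir,
                        p = config$n_service, threshold = 40,
                        sweep_p = NULL,
                        linking = c("per_pair", "big_m"),
                        travel_params = syntheticTravelParams()) {
  linking <- match.arg(linking)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[3L]
  h <- configHash(config)
  paths <- list()

  country <- generateSyntheticCountry(config)
  paths$demand_geojson <- file.path(out_dir, "demand.geojson")
  paths$demand_csv <- file.path(out_dir, "demand.csv")
  paths$hospitals_geojson <- file.path(out_dir, "hospitals.geojson")
  paths$hospitals_csv <- file.path(out_dir, "hospitals.csv")
  writeDemand(country$demand, paths$demand_geojson)
  writeDemand(country$demand, paths$demand_csv)
  writeHospitals(country$hospitals, paths$hospitals_geojson)
  writeHospitals(country$hospitals, paths$hospitals_csv)
  writeSidecar(paths$demand_geojson, config)
  writeSidecar(paths$hospitals_geojson, config)
  logStage("synth", h, config$seed, t0)

  tmat <- buildTravelMatrix(country$demand, country$hospitals,
                            travel_params)
  paths$travel_matrix <- file.path(out_dir, "travel_matrix.csv")
  writeTravelMatrix(tmat, paths$travel_matrix)
  W <- weightMatrix(tmat, country$demand)
  logStage("matrix", h, config$seed, t0)

  service <- serviceIds(country$hospitals)
  current <- evaluateSiteSet(W, service, tmat)
  pmed <- solveScenario(W, p, "liberal", service, linking, tmat = tmat)
  if (pmed@status == "infeasible")
    stop("optimization infeasible: p = ", p, " exceeds the ",
         ncol(W@values), " candidate sites")
  km <- kmeansAllocate(W, tmat, country$demand,
                       kMeansConfig(k = p, seed = config$seed))
  logStage("optimize", h, config$seed, t0)

  metricsOf <- function(sol)
    stratifiedMetrics(assignmentTable(sol)$minutes, country$demand,
                      threshold)
  mets <- list(current = metricsOf(current), pmedian = metricsOf(pmed),
               kmeans = metricsOf(km))
  tab <- do.call(rbind, lapply(names(mets), function(nm) {
    d <- metricsTable(mets[[nm]])
    cbind(model = nm, d, stringsAsFactors = FALSE)
  }))
  paths$metrics <- file.path(out_dir, "metrics.csv")
  utils::write.csv(tab, paths$metrics, row.names = FALSE, quote = FALSE)
  paths$solution_current <- file.path(out_dir, "solution_current.json")
  paths$solution_pmedian <- file.path(out_dir, "solution_pmedian.json")
  paths$solution_kmeans <- file.path(out_dir, "solution_kmeans.json")
  writeSolution(current, paths$solution_current)
  writeSolution(pmed, paths$solution_pmedian)
  writeSolution(km, paths$solution_kmeans)
  logStage("metrics", h, config$seed, t0)

  changes <- rbind(
    cbind(comparison = "pmedian_vs_current",
          relativeChange(mets$current$overall, mets$pmedian$overall),
          stringsAsFactors = FALSE),
    cbind(comparison = "kmeans_vs_current",
          relativeChange(mets$current$overall, mets$kmeans$overall),
          stringsAsFactors = FALSE))
  paths$changes <- file.path(out_dir, "change_report.csv")
  utils::write.csv(changes, paths$changes, row.names = FALSE, quote = FALSE)
  cmp <- compareDistributions(assignmentTable(current)$minutes,
                              assignmentTable(pmed)$minutes)
  paths$comparison <- file.path(out_dir, "comparison.json")
  jsonlite::write_json(
    list(schema_version = 1L, test = "mann_whitney_u",
         statistic = cmp@statistic, p_value = cmp@pValue,
         shapiro_p_current = cmp@normalityPA,
         shapiro_p_optimized = cmp@normalityPB),
    paths$comparison, auto_unbox = TRUE, digits = NA, pretty = TRUE,
    na = "null")
  logStage("compare", h, config$seed, t0)

  sweep <- NULL
  if (!is.null(sweep_p)) {
    sweeps <- list(
      runSweep(W, sweep_p, "liberal", service, tmat, country$demand,
               linking, threshold),
      runSweep(W, sweep_p, "prioritized", service, tmat, country$demand,
               linking, threshold))
    paths$sweep <- file.path(out_dir, "sweep.csv")
    exportSweep(sweeps, paths$sweep)
    sweep <- new("SweepResult",
                 table = do.call(rbind, lapply(sweeps, sweepTable)))
    logStage("sweep", h, config$seed, t0)
  }

  invisible(list(country = country, tmat = tmat, W = W, current = current,
                 pmedian = pmed, kmeans = km, metrics = mets,
                 changes = changes, comparison = cmp, sweep = sweep,
                 files = paths))
}
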