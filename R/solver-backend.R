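# Bridge to the bundled MILP backend (HiGHS via scipy.optimize.milp).
# The model itself is assembled in R (buildPMedianModel); this layer only
# ships the numbers to the solver process and reads the chosen sites back.

findPython <- function() {
  opt <- getOption("pmedAccess.python", NULL)
  if (!is.null(opt)) return(opt)
  for (cand in c("python3", "python")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(unname(p))
  }
  stop("MILP backend unavailable: no python interpreter on PATH ",
       "(set options(pmedAccess.python = ...) to point at one)")
}

backendScript <- function() {
  p <- system.file("python", "pmedian_milp.py", package = "pmedAccess")
  if (!nzchar(p)) stop("bundled solver script not found")
  p
}

# Solve a batch of site-selection problems over one weighted matrix in a
# single backend invocation. `problems` is a list of lists with fields
# name, columns (1-based indices of sites that may open), pinned_open
# (subset of columns fixed open), cardinality, linking, big_m, mip_gap,
# time_limit. Returns the parsed per-problem result list.
solveBackendBatch <- function(Wvals, problems) {
  dir <- tempfile("pmed")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  wcsv <- file.path(dir, "w.csv")
  utils::write.table(Wvals, wcsv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  outj <- file.path(dir, "out.json")
  probs <- lapply(problems, function(p) {
    list(name = p$name,
         columns = I(as.integer(p$columns) - 1L),
         pinned_open = I(as.integer(p$pinned_open %||% integer(0)) - 1L),
         cardinality = as.integer(p$cardinality),
         linking = p$linking %||% "per_pair",
         big_m = p$big_m,
         mip_gap = p$mip_gap %||% 1e-6,
         time_limit = p$time_limit)
  })
  jobj <- file.path(dir, "job.json")
  jsonlite::write_json(list(w_csv = wcsv, out = outj, problems = probs),
                       jobj, auto_unbox = TRUE, digits = NA, null = "null")
  status <- system2(findPython(), c(backendScript(), jobj),
                    stdout = file.path(dir, "log"), stderr = file.path(dir, "log"))
  if (status != 0L || !file.exists(outj))
    stop("MILP backend failed (exit ", status, "): ",
         paste(readLines(file.path(dir, "log"), warn = FALSE),
               collapse = "\n"))
  jsonlite::read_json(outj, simplifyVector = FALSE)
}
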