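#' @name pmedAccess-accessors
#' @title Accessors for pmedAccess classes
#' @description Small accessor layer over the S4 containers; user code
#'   should use these rather than reaching into slots.
#' @param x,object an object of the documented class.
#' @param ... unused.
NULL

#' @rdname pmedAccess-accessors
#' @export
setGeneric("demandPoints", function(x) standardGeneric("demandPoints"))
#' @rdname pmedAccess-accessors
#' @export
setGeneric("hospitalSites", function(x) standardGeneric("hospitalSites"))
#' @rdname pmedAccess-accessors
#' @export
setGeneric("coordMode", function(x) standardGeneric("coordMode"))
#' @rdname pmedAccess-accessors
#' @export
setGeneric("demandIds", function(x) standardGeneric("demandIds"))
#' @rdname pmedAccess-accessors
#' @export
setGeneric("hospitalIds", function(x) standardGeneric("hospitalIds"))
#' @rdname pmedAccess-accessors
#' @export
setGeneric("serviceIds", function(x) standardGeneric("serviceIds"))
#' @rdname pmedAccess-accessors
#' @export
setGeneric("timeValues", function(x) standardGeneric("timeValues"))
#' @rdname pmedAccess-accessors
#' @export
setGeneric("weightedValues", function(x) standardGeneric("weightedValues"))
#' @rdname pmedAccess-accessors
#' @export
setGeneric("openSites", function(x) standardGeneric("openSites"))
#' @rdname pmedAccess-accessors
#' @export
setGeneric("assignmentTable", function(x) standardGeneric("assignmentTable"))
#' @rdname pmedAccess-accessors
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))
#' @rdname pmedAccess-accessors
#' @export
setGeneric("solutionStatus", function(x) standardGeneric("solutionStatus"))
#' @rdname pmedAccess-accessors
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))
#' @rdname pmedAccess-accessors
#' @export
setGeneric("sweepTable", function(x) standardGeneric("sweepTable"))

#' @rdname pmedAccess-accessors
setMethod("demandPoints", "DemandSet", function(x) x@points)
#' @rdname pmedAccess-accessors
setMethod("hospitalSites", "HospitalSet", function(x) x@sites)
#' @rdname pmedAccess-accessors
setMethod("coordMode", "DemandSet", function(x) x@mode)
#' @rdname pmedAccess-accessors
setMethod("coordMode", "HospitalSet", function(x) x@mode)
#' @rdname pmedAccess-accessors
setMethod("demandIds", "DemandSet", function(x) x@points$point_id)
#' @rdname pmedAccess-accessors
setMethod("demandIds", "TravelMatrix", function(x) rownames(x@values))
#' @rdname pmedAccess-accessors
setMethod("demandIds", "WeightedMatrix", function(x) rownames(x@values))
#' @rdname pmedAccess-accessors
setMethod("hospitalIds", "HospitalSet", function(x) x@sites$hospital_id)
#' @rdname pmedAccess-accessors
setMethod("hospitalIds", "TravelMatrix", function(x) colnames(x@values))
#' @rdname pmedAccess-accessors
setMethod("hospitalIds", "WeightedMatrix", function(x) colnames(x@values))
#' @rdname pmedAccess-accessors
setMethod("serviceIds", "HospitalSet",
          function(x) x@sites$hospital_id[x@sites$service])
#' @rdname pmedAccess-accessors
setMethod("timeValues", "TravelMatrix", function(x) x@values)
#' @rdname pmedAccess-accessors
setMethod("weightedValues", "WeightedMatrix", function(x) x@values)
#' @rdname pmedAccess-accessors
setMethod("openSites", "AllocationSolution", function(x) x@openSites)
#' @rdname pmedAccess-accessors
setMethod("assignmentTable", "AllocationSolution", function(x) x@assignment)
#' @rdname pmedAccess-accessors
setMethod("objectiveValue", "AllocationSolution", function(x) x@objective)
#' @rdname pmedAccess-accessors
setMethod("solutionStatus", "AllocationSolution", function(x) x@status)
#' @rdname pmedAccess-accessors
setMethod("regionTable", "RegionSet", function(x) x@regions)
#' @rdname pmedAccess-accessors
setMethod("sweepTable", "SweepResult", function(x) x@table)

#' @rdname pmedAccess-accessors
#' @export
setMethod("show", "RegionSet", function(object) {
  df <- object@regions
  cat("RegionSet:", nrow(df), "regions tiling",
      paste(object@bbox, collapse = " x "), "km\n")
  cat("  classes:", paste(sprintf("%s=%d", URBANIZATION_CLASSES,
      tabulate(factor(df$urbanization, URBANIZATION_CLASSES), 3L)),
      collapse = ", "), "\n")
})

#' @rdname pmedAccess-accessors
#' @export
setMethod("show", "DemandSet", function(object) {
  df <- object@points
  cat("DemandSet:", nrow(df), "demand points (", object@mode, ")\n")
  cat("  total population:", format(round(sum(df$population))), "\n")
})

#' @rdname pmedAccess-accessors
#' @export
setMethod("show", "HospitalSet", function(object) {
  cat("HospitalSet:", nrow(object@sites), "candidate sites,",
      sum(object@sites$service), "service sites (", object@mode, ")\n")
})

#' @rdname pmedAccess-accessors
#' @export
setMethod("show", "TravelMatrix", function(object) {
  v <- object@values
  cat("TravelMatrix:", nrow(v), "demand points x", ncol(v), "hospitals,",
      "minutes in [", round(min(v), 2), ",", round(max(v), 2), "]\n")
})

#' @rdname pmedAccess-accessors
#' @export
setMethod("show", "WeightedMatrix", function(object) {
  v <- object@values
  cat("WeightedMatrix:", nrow(v), "x", ncol(v),
      "population-weighted travel times\n")
})

#' @rdname pmedAccess-accessors
#' @export
setMethod("show", "AllocationSolution", function(object) {
  cat("AllocationSolution (", object@method, "): status", object@status, "\n")
  if (object@status != "infeasible") {
    cat("  open sites:", length(object@openSites),
        " objective z =", format(object@objective), "\n")
  }
})

#' @rdname pmedAccess-accessors
#' @export
setMethod("show", "AccessMetrics", function(object) {
  cat(sprintf("AccessMetrics [%s], n = %d, threshold = %g min\n",
              object@stratum, object@n, object@thresholdMinutes))
  cat(sprintf("  weighted:   mean %.2f  median %.2f  IQR %.2f-%.2f\n",
              object@weightedMean, object@weightedMedian,
              object@weightedIqrLow, object@weightedIqrHigh))
  cat(sprintf("  unweighted: mean %.2f  median %.2f  IQR %.2f-%.2f\n",
              object@unweightedMean, object@unweightedMedian,
              object@unweightedIqrLow, object@unweightedIqrHigh))
  cat(sprintf("  population above threshold: %.1f (%.2f%%)\n",
              object@populationAboveThreshold,
              100 * object@propAboveThreshold))
})

#' @rdname pmedAccess-accessors
#' @export
setMethod("show", "SweepResult", function(object) {
  cat("SweepResult:", nrow(object@table), "rows, p in [",
      min(object@table$p), ",", max(object@table$p), "]\n")
})

#' Flatten accessibility metrics to a one-row data.frame
#'
#' @param x an [AccessMetrics-class].
#' @param row.names,optional,... passed for generic compatibility; unused.
#' @return one-row `data.frame` with snake_case metric columns.
#' @export
as.data.frame.AccessMetrics <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(stratum = x@stratum, n = x@n,
             weighted_mean = x@weightedMean,
             weighted_median = x@weightedMedian,
             weighted_iqr_low = x@weightedIqrLow,
             weighted_iqr_high = x@weightedIqrHigh,
             unweighted_mean = x@unweightedMean,
             unweighted_median = x@unweightedMedian,
             unweighted_iqr_low = x@unweightedIqrLow,
             unweighted_iqr_high = x@unweightedIqrHigh,
             prop_above_threshold = x@propAboveThreshold,
             population_above = x@populationAboveThreshold,
             population_total = x@populationTotal,
             threshold_minutes = x@thresholdMinutes,
             stringsAsFactors = FALSE)
}

setMethod("as.data.frame", "AccessMetrics", as.data.frame.AccessMetrics)
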