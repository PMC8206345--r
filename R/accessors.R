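#' Accessors for statepath classes
#'
#' `timePoints` returns the distinct observed time points, sorted;
#' `interpolationStep` the grid spacing; `interpolationGrid` all multiples
#' of the step spanning the observed range united with the observed points;
#' `nReplicates` the maximum replicate index; `exprsMatrix` the assay
#' matrix.
#'
#' @param x a [TimeSeriesExperiment-class] object.
#' @return `timePoints`, `interpolationGrid`: numeric vectors.
#'   `interpolationStep`: numeric(1). `nReplicates`: integer(1).
#'   `exprsMatrix`: numeric matrix.
#' @name tse-accessors
NULL

#' @rdname tse-accessors
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @rdname tse-accessors
#' @export
setMethod("timePoints", "TimeSeriesExperiment", function(x)
  sort(unique(SummarizedExperiment::colData(x)$time)))

#' @rdname tse-accessors
#' @export
setGeneric("interpolationStep", function(x)
  standardGeneric("interpolationStep"))

#' @rdname tse-accessors
#' @export
setMethod("interpolationStep", "TimeSeriesExperiment", function(x)
  x@interpolationStep)

#' @rdname tse-accessors
#' @export
setGeneric("interpolationGrid", function(x)
  standardGeneric("interpolationGrid"))

#' @rdname tse-accessors
#' @export
setMethod("interpolationGrid", "TimeSeriesExperiment", function(x)
  makeInterpolationGrid(timePoints(x), interpolationStep(x)))

#' @rdname tse-accessors
#' @export
setGeneric("nReplicates", function(x) standardGeneric("nReplicates"))

#' @rdname tse-accessors
#' @export
setMethod("nReplicates", "TimeSeriesExperiment", function(x)
  max(SummarizedExperiment::colData(x)$replicate))

#' @rdname tse-accessors
#' @export
setGeneric("exprsMatrix", function(x) standardGeneric("exprsMatrix"))

#' @rdname tse-accessors
#' @export
setMethod("exprsMatrix", "TimeSeriesExperiment", function(x)
  SummarizedExperiment::assay(x, "exprs"))

# interpolation grid: multiples of `step` spanning [min, max], union the
# observed points themselves
makeInterpolationGrid <- function(times, step) {
  lo <- min(times); hi <- max(times)
  mult <- seq(ceiling(lo / step), floor(hi / step)) * step
  sort(unique(c(mult, times)))
}

#' Accessors for Gaussian-process cluster fits
#'
#' @param x a [GPFit-class] object.
#' @return `gpMean`, `gpSd`, `gpGrid`: numeric vectors over the
#'   interpolation grid; `logMarginal`: numeric(1).
#' @name gpfit-accessors
NULL

#' @rdname gpfit-accessors
#' @export
setGeneric("gpMean", function(x) standardGeneric("gpMean"))
#' @rdname gpfit-accessors
#' @export
setMethod("gpMean", "GPFit", function(x) stats::setNames(x@mean, x@grid))

#' @rdname gpfit-accessors
#' @export
setGeneric("gpSd", function(x) standardGeneric("gpSd"))
#' @rdname gpfit-accessors
#' @export
setMethod("gpSd", "GPFit", function(x) stats::setNames(x@sd, x@grid))

#' @rdname gpfit-accessors
#' @export
setGeneric("gpGrid", function(x) standardGeneric("gpGrid"))
#' @rdname gpfit-accessors
#' @export
setMethod("gpGrid", "GPFit", function(x) x@grid)

#' @rdname gpfit-accessors
#' @export
setGeneric("logMarginal", function(x) standardGeneric("logMarginal"))
#' @rdname gpfit-accessors
#' @export
setMethod("logMarginal", "GPFit", function(x) x@logMarginal)

#' Accessors for gap-statistic scans
#'
#' `kOpt` returns the selected number of clusters, `gapCurve` the per-k
#' statistic table, and `clusterLabels` the gene labels for a given k
#' (default: the selected k).
#'
#' @param x a [GapScan-class] object.
#' @param k integer(1), which k's assignment to return.
#' @return `kOpt`: integer(1). `gapCurve`: data.frame. `clusterLabels`:
#'   named integer vector (gene -> cluster in 1..k).
#' @name gapscan-accessors
NULL

#' @rdname gapscan-accessors
#' @export
setGeneric("kOpt", function(x) standardGeneric("kOpt"))
#' @rdname gapscan-accessors
#' @export
setMethod("kOpt", "GapScan", function(x) x@kOpt)

#' @rdname gapscan-accessors
#' @export
setGeneric("gapCurve", function(x) standardGeneric("gapCurve"))
#' @rdname gapscan-accessors
#' @export
setMethod("gapCurve", "GapScan", function(x) x@statistic)

#' @rdname gapscan-accessors
#' @export
setGeneric("clusterLabels", function(x, k) standardGeneric("clusterLabels"))
#' @rdname gapscan-accessors
#' @export
setMethod("clusterLabels", "GapScan", function(x, k) {
  if (missing(k)) k <- x@kOpt
  lab <- x@assignments[[as.character(k)]]
  if (is.null(lab))
    stop(sprintf("no assignment stored for k = %d", k))
  lab
})

#' Accessors for cluster networks
#'
#' @param x a [ClusterNetwork-class] object.
#' @return `clusterOrder`: integer vector of cluster ids in temporal order.
#'   `networkNodes`/`networkEdges`: lists of node/edge records.
#' @name network-accessors
NULL

#' @rdname network-accessors
#' @export
setGeneric("clusterOrder", function(x) standardGeneric("clusterOrder"))
#' @rdname network-accessors
#' @export
setMethod("clusterOrder", "ClusterNetwork", function(x) x@order)

#' @rdname network-accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname network-accessors
#' @export
setMethod("networkNodes", "ClusterNetwork", function(x) x@nodes)

#' @rdname network-accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname network-accessors
#' @export
setMethod("networkEdges", "ClusterNetwork", function(x) x@edges)

#' @describeIn TimeSeriesExperiment-class compact display
#' @param object object to display
#' @export
setMethod("show", "TimeSeriesExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf(
    "TimeSeriesExperiment: %d genes, %d time points, %d replicate(s)\n",
    nrow(object), length(unique(cd$time)), max(cd$replicate)))
  tp <- sort(unique(cd$time))
  cat("  time points:", paste(utils::head(tp, 8), collapse = ", "),
      if (length(tp) > 8) "...\n" else "\n")
  cat(sprintf("  interpolation step: %g\n", object@interpolationStep))
})

#' @describeIn GPFit-class compact display
#' @param object object to display
#' @export
setMethod("show", "GPFit", function(object) {
  cat(sprintf(
    "GPFit: %d profile(s) on %d time points | l = %.4g, noise sd = %.4g\n",
    object@nProfiles, length(object@trainTimes), object@lengthScale,
    object@noiseSd))
  cat(sprintf("  joint log marginal likelihood: %.4f\n",
              object@logMarginal))
})

#' @describeIn GapScan-class compact display
#' @param object object to display
#' @export
setMethod("show", "GapScan", function(object) {
  cat(sprintf("GapScan (%s mode, %s, B = %d): k in [%d, %d] -> kOpt = %d\n",
              object@mode, object@method, object@B, min(object@kRange),
              max(object@kRange), object@kOpt))
})

#' @describeIn ClusterNetwork-class compact display
#' @param object object to display
#' @export
setMethod("show", "ClusterNetwork", function(object) {
  cat(sprintf("ClusterNetwork: %d state(s), %d edge(s)\n",
              length(object@order), length(object@edges)))
  if (length(object@order) > 1L)
    cat("  order:", paste(object@order, collapse = " -> "), "\n")
  nAnn <- sum(vapply(object@edges,
                     function(e) nrow(e$annotations), integer(1)))
  cat(sprintf("  annotated pathway-edge pairs: %d\n", nAnn))
})
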