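#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay colData SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats kmeans hclust cutree dist runif rnorm optim phyper
#'   sd approx ave setNames
#' @importFrom utils read.table write.table combn head
NULL

#' TimeSeriesExperiment: a genes x (time x replicate) expression container
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a per-column
#' time annotation (`colData(x)$time`), a per-column replicate index
#' (`colData(x)$replicate`) and an interpolation step used when evaluating
#' Gaussian-process summaries between observed time points. Columns are
#' measurements; rows are genes. Missing replicate values may be encoded as
#' `NA` and are ignored by replicate averaging.
#'
#' @slot interpolationStep numeric(1), spacing of the interpolation grid
#'   (same units as `time`, default 1).
#'
#' @seealso [TimeSeriesExperiment()] (constructor), [timePoints()],
#'   [interpolationGrid()], [averageReplicates()], [logZNormalize()]
#' @export
setClass("TimeSeriesExperiment",
  contains = "SummarizedExperiment",
  slots = c(interpolationStep = "numeric")
)

setValidity("TimeSeriesExperiment", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("time", "replicate") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'time' and 'replicate' columns")
  else {
    tm <- cd$time
    if (!is.numeric(tm) || anyNA(tm))
      msg <- c(msg, "'time' must be numeric and non-missing")
    else if (length(unique(tm)) < 2L)
      msg <- c(msg, "at least 2 distinct time points are required")
  }
  if (length(object@interpolationStep) != 1L ||
      !is.finite(object@interpolationStep) || object@interpolationStep <= 0)
    msg <- c(msg, "'interpolationStep' must be a single positive number")
  rn <- rownames(object)
  if (is.null(rn))
    msg <- c(msg, "gene identifiers (rownames) are required")
  else if (anyDuplicated(rn))
    msg <- c(msg, sprintf("duplicated gene ids: %s",
                          paste(unique(rn[duplicated(rn)]), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a TimeSeriesExperiment
#'
#' @param values numeric matrix, genes x measurements, with gene ids as
#'   rownames. Columns map to `(time, replicate)` pairs.
#' @param times numeric vector. Either one time per column
#'   (`length(times) == ncol(values)`) or the distinct time grid, in which
#'   case `nRep` replicates per time point are assumed with columns in
#'   time-major order (t1 r1, t1 r2, ..., t2 r1, ...).
#' @param nRep integer(1), replicates per time point when `times` is the
#'   distinct grid. Default 1.
#' @param replicates optional integer vector, one replicate index per
#'   column; overrides `nRep`.
#' @param interpolationStep numeric(1), spacing of the interpolation grid.
#'
#' @return A [TimeSeriesExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(c("g1", "g2", "g3"), NULL))
#' tse <- TimeSeriesExperiment(m, times = c(0, 2, 4, 6))
#' timePoints(tse)
#' @export
TimeSeriesExperiment <- function(values, times, nRep = 1L, replicates = NULL,
                                 interpolationStep = 1) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("'values' must be numeric")
  if (length(times) == ncol(values)) {
    colTimes <- as.numeric(times)
    if (is.null(replicates))
      replicates <- stats::ave(colTimes, colTimes, FUN = seq_along)
  } else {
    nRep <- as.integer(nRep)
    if (length(times) * nRep != ncol(values))
      stop(sprintf(
        "grid mismatch: %d time points x %d replicates != %d columns",
        length(times), nRep, ncol(values)))
    colTimes <- rep(as.numeric(times), each = nRep)
    replicates <- rep(seq_len(nRep), times = length(times))
  }
  cd <- S4Vectors::DataFrame(time = colTimes,
                             replicate = as.integer(replicates))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values), colData = cd)
  new("TimeSeriesExperiment", se, interpolationStep = interpolationStep)
}

#' Gaussian-process fit for one gene cluster
#'
#' Posterior summary of a Gaussian-process regression over all member
#' expression profiles of a cluster, with an RBF kernel over time plus white
#' observation noise. The posterior mean and standard deviation are
#' evaluated on the interpolation grid (observed time points united with all
#' multiples of the interpolation step spanning the observed range).
#'
#' @slot lengthScale numeric(1), fitted RBF length scale (time units).
#' @slot noiseSd numeric(1), fitted white-noise standard deviation.
#' @slot bounds list with elements `lengthScale` and `noiseSd`, the box
#'   constraints used during optimisation.
#' @slot trainTimes numeric, distinct observed time points.
#' @slot grid numeric, interpolation grid on which `mean`/`sd` live.
#' @slot mean numeric, posterior mean on `grid`.
#' @slot sd numeric, posterior standard deviation on `grid` (includes the
#'   white-noise term, so it is strictly positive whenever `noiseSd > 0`).
#' @slot muObs numeric, posterior mean at `trainTimes` (used by the
#'   per-profile marginal likelihood).
#' @slot covObs matrix, posterior covariance of the latent process at
#'   `trainTimes`; with the white-noise variance added to its diagonal it
#'   is the predictive covariance of a member profile.
#' @slot logMarginal numeric(1), joint log marginal likelihood of the
#'   training data at the fitted hyperparameters.
#' @slot nProfiles integer(1), number of member profiles used in the fit.
#' @export
setClass("GPFit", slots = c(
  lengthScale = "numeric", noiseSd = "numeric", bounds = "list",
  trainTimes = "numeric", grid = "numeric", mean = "numeric",
  sd = "numeric", muObs = "numeric", covObs = "matrix",
  logMarginal = "numeric", nProfiles = "integer"))

setValidity("GPFit", function(object) {
  msg <- character()
  if (object@lengthScale <= 0) msg <- c(msg, "lengthScale must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(object@mean) != length(object@grid) ||
      length(object@sd) != length(object@grid))
    msg <- c(msg, "mean/sd must match the grid length")
  if (object@noiseSd > 0 && any(object@sd <= 0))
    msg <- c(msg, "posterior sd must be positive when noiseSd > 0")
  if (length(msg)) msg else TRUE
})

#' Gap-statistic scan over candidate cluster numbers
#'
#' Result of scanning k over a range, clustering observed data and B
#' structureless reference draws at each k, and computing either the
#' classic Euclidean gap or the Gaussian-process likelihood gap.
#'
#' @slot kRange integer, candidate k values scanned.
#' @slot mode character(1), `"gp"` or `"euclidean"`.
#' @slot method character(1), `"kmeans"` or `"agglomerative"`.
#' @slot statistic data.frame, one row per k: observed dispersion, reference
#'   expectation, reference standard error and the gap.
#' @slot kOpt integer(1), selected number of clusters.
#' @slot assignments list, per-k integer label vectors (named by gene).
#' @slot B integer(1), number of reference draws.
#' @slot seed integer(1), seed that reproduces the scan.
#' @export
setClass("GapScan", slots = c(
  kRange = "integer", mode = "character", method = "character",
  statistic = "data.frame", kOpt = "integer", assignments = "list",
  B = "integer", seed = "integer"))

setValidity("GapScan", function(object) {
  msg <- character()
  if (!object@mode %in% c("gp", "euclidean"))
    msg <- c(msg, "mode must be 'gp' or 'euclidean'")
  if (length(object@kOpt) == 1L && !object@kOpt %in% object@kRange)
    msg <- c(msg, "kOpt must lie in kRange")
  if (length(msg)) msg else TRUE
})

#' Directed cluster network of inferred cell states
#'
#' A simple directed path over gene clusters. Each node is one inferred
#' transcriptomic state carrying its member genes and a Gaussian-process
#' summary (posterior mean and 95% confidence band on the interpolation
#' grid); each edge connects temporally consecutive states and carries the
#' pathways passing the two-group enrichment criterion.
#'
#' @slot order integer, cluster ids in inferred temporal order.
#' @slot nodes list, one element per cluster (in `order`): `cluster`,
#'   `genes`, `grid`, `mean`, `sd`, `ciLower`, `ciUpper`.
#' @slot edges list, one element per consecutive pair: `from`, `to`,
#'   `annotations` (data.frame with pathway, tailFrom, tailTo, tailUnion).
#' @export
setClass("ClusterNetwork", slots = c(
  order = "integer", nodes = "list", edges = "list"))

setValidity("ClusterNetwork", function(object) {
  msg <- character()
  k <- length(object@order)
  if (length(object@nodes) != k)
    msg <- c(msg, "one node per ordered cluster is required")
  if (k >= 1L && length(object@edges) != k - 1L)
    msg <- c(msg, sprintf("a %d-state path must have %d edges", k, k - 1L))
  if (length(msg)) msg else TRUE
})
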