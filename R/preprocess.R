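#' Log- and z-normalize expression values
#'
#' Applies `log(x + logOffset)` followed by per-gene z-scoring across all
#' time points and replicates jointly. Clustering compares temporal shapes,
#' so each gene's profile is centred and scaled as a whole rather than per
#' time point. Zero-variance (constant) genes become all-zero rows and are
#' flagged rather than dropped. The transform parameters are stored in
#' `metadata(x)$normalization` so that [inverseNormalize()] can recover the
#' input to numerical precision.
#'
#' @param x a [TimeSeriesExperiment-class] object.
#' @param logOffset numeric(1), offset added before the log (default 1,
#'   the log1p convention for normalized read counts).
#' @param alreadyLog logical(1); if `TRUE` the values are taken as already
#'   log-scale and only z-scoring is applied.
#' @return A [TimeSeriesExperiment-class] with normalized values and the
#'   normalization record in `metadata(x)$normalization`.
#' @examples
#' tse <- TimeSeriesExperiment(
#'   matrix(rexp(12), 3, 4, dimnames = list(paste0("g", 1:3), NULL)),
#'   times = 0:3)
#' norm <- logZNormalize(tse)
#' rowMeans(exprsMatrix(norm))  # ~0 per gene
#' @export
logZNormalize <- function(x, logOffset = 1, alreadyLog = FALSE) {
  stopIfNot(is(x, "TimeSeriesExperiment"),
            "'x' must be a TimeSeriesExperiment")
  m <- exprsMatrix(x)
  if (!alreadyLog) {
    if (any(m < 0, na.rm = TRUE))
      stop("negative expression values: use alreadyLog = TRUE for ",
           "log-scale input")
    m <- log(m + logOffset)
  }
  mu <- rowMeans(m, na.rm = TRUE)
  s <- apply(m, 1L, stats::sd, na.rm = TRUE)
  constant <- !is.finite(s) | s == 0
  s[constant] <- 0
  z <- (m - mu) / ifelse(constant, 1, s)
  z[constant, ] <- 0
  z[is.na(m)] <- NA
  out <- x
  SummarizedExperiment::assay(out, "exprs") <- z
  S4Vectors::metadata(out)$normalization <- list(
    mean = mu, sd = s, constant = constant,
    logOffset = logOffset, alreadyLog = alreadyLog)
  out
}

#' Invert a normalization
#'
#' Reverses [logZNormalize()] using the stored per-gene record; the result
#' matches the original input to numerical precision.
#'
#' @param x a normalized [TimeSeriesExperiment-class] carrying a
#'   `normalization` record in its metadata.
#' @return A [TimeSeriesExperiment-class] on the original scale.
#' @export
inverseNormalize <- function(x) {
  rec <- S4Vectors::metadata(x)$normalization
  if (is.null(rec))
    stop("no normalization record found in metadata(x)")
  z <- exprsMatrix(x)
  y <- z * rec$sd + rec$mean
  if (!rec$alreadyLog) y <- exp(y) - rec$logOffset
  out <- x
  SummarizedExperiment::assay(out, "exprs") <- y
  S4Vectors::metadata(out)$normalization <- NULL
  out
}

#' Average replicates at each time point
#'
#' Collapses the replicate dimension to per-time-point means, ignoring
#' missing (`NA`) replicate values. The result has one column per time
#' point, in increasing time order.
#'
#' @param x a [TimeSeriesExperiment-class] object.
#' @return A [TimeSeriesExperiment-class] with a single replicate per time
#'   point.
#' @export
averageReplicates <- function(x) {
  stopIfNot(is(x, "TimeSeriesExperiment"),
            "'x' must be a TimeSeriesExperiment")
  tp <- timePoints(x)
  cd <- SummarizedExperiment::colData(x)
  m <- exprsMatrix(x)
  avg <- vapply(tp, function(t) {
    cols <- which(cd$time == t)
    rowMeans(m[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(m)))
  if (nrow(m) == 1L) avg <- matrix(avg, nrow = 1L)
  dimnames(avg) <- list(rownames(m), NULL)
  bad <- which(!is.finite(avg), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(
      "no non-missing replicate for gene '%s' at time %g",
      rownames(m)[bad[1L, 1L]], tp[bad[1L, 2L]]))
  out <- TimeSeriesExperiment(avg, times = tp, nRep = 1L,
                              interpolationStep = interpolationStep(x))
  S4Vectors::metadata(out) <- S4Vectors::metadata(x)
  out
}

#' Drop genes observed in too few time points
#'
#' Removes genes whose expression is zero or entirely missing in more than
#' `maxBad` time points (default 4, matching the usual pre-filter for short
#' expression series); a warning reports how many genes were dropped.
#'
#' @param x a [TimeSeriesExperiment-class] object (raw scale).
#' @param maxBad integer(1), maximum tolerated number of zero/missing time
#'   points per gene.
#' @return A filtered [TimeSeriesExperiment-class].
#' @export
dropSparseGenes <- function(x, maxBad = 4L) {
  tp <- timePoints(x)
  cd <- SummarizedExperiment::colData(x)
  m <- exprsMatrix(x)
  badCount <- rowSums(vapply(tp, function(t) {
    cols <- which(cd$time == t)
    sub <- m[, cols, drop = FALSE]
    apply(sub, 1L, function(v) all(is.na(v) | v == 0))
  }, logical(nrow(m))))
  drop <- badCount > maxBad
  if (any(drop))
    warning(sprintf(
      "dropping %d gene(s) with zero/missing values in more than %d time points",
      sum(drop), maxBad))
  x[!drop, ]
}

#' Functional principal component scores of temporal profiles
#'
#' Discretized functional PCA on the observed time grid: the gene-mean
#' curve is removed, the sample covariance across the time grid is
#' eigen-decomposed, and each gene's curve is scored on the leading
#' eigenfunctions. Explained-variance ratios are reported in non-increasing
#' order.
#'
#' @param x a [TimeSeriesExperiment-class] (replicates are averaged first)
#'   or a genes x time-points numeric matrix.
#' @param nComponents integer(1), number of leading components (must be
#'   between 1 and the number of time points).
#' @return A list with `scores` (genes x `nComponents`), `varianceRatio`
#'   (length `nComponents`, non-increasing), `eigenfunctions` (time points
#'   x `nComponents`) and `meanCurve`.
#' @export
functionalPCA <- function(x, nComponents) {
  m <- if (is(x, "TimeSeriesExperiment")) {
    exprsMatrix(averageReplicates(x))
  } else as.matrix(x)
  nComponents <- as.integer(nComponents)
  stopIfNot(nComponents >= 1L, "'nComponents' must be >= 1")
  stopIfNot(nComponents <= ncol(m),
            "'nComponents' (%d) exceeds the number of time points (%d)",
            nComponents, ncol(m))
  meanCurve <- colMeans(m)
  centred <- sweep(m, 2L, meanCurve)
  covT <- crossprod(centred) / max(1L, nrow(m) - 1L)
  eig <- eigen(covT, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  ratio <- if (sum(vals) > 0) vals / sum(vals) else rep(0, length(vals))
  basis <- eig$vectors[, seq_len(nComponents), drop = FALSE]
  scores <- centred %*% basis
  rownames(scores) <- rownames(m)
  list(scores = scores,
       varianceRatio = ratio[seq_len(nComponents)],
       eigenfunctions = basis,
       meanCurve = meanCurve)
}
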