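# Cluster a genes x time matrix into k groups. Returns an integer vector
# of labels in 1..k, named by gene, with every cluster non-empty.
clusterProfiles <- function(m, k, method = c("kmeans", "agglomerative"),
                            seed = 1L) {
  method <- match.arg(method)
  stopIfNot(k >= 1L && k <= nrow(m),
            "k = %d outside [1, %d genes]", k, nrow(m))
  if (k == 1L)
    return(stats::setNames(rep(1L, nrow(m)), rownames(m)))
  if (k == nrow(m))                       # every point its own cluster
    return(stats::setNames(seq_len(nrow(m)), rownames(m)))
  lab <- if (method == "kmeans") {
    withLocalSeed(seed,
      stats::kmeans(m, centers = k, nstart = 10L, iter.max = 50L)$cluster)
  } else {
    stats::cutree(stats::hclust(stats::dist(m), method = "ward.D2"), k = k)
  }
  stats::setNames(as.integer(lab), rownames(m))
}

#' Within-cluster Euclidean dispersion
#'
#' The classic gap-statistic dispersion
#' \deqn{W_k = \sum_{r=1}^{k} \frac{1}{2 n_r} D_r, \qquad
#'   D_r = \sum_{i,j \in C_r} \|x_i - x_j\|^2,}
#' computed through the algebraically identical centroid form
#' \eqn{D_r = 2 n_r \sum_{i \in C_r} \|x_i - \mu_r\|^2} (so \eqn{W_k} is the
#' total within-cluster sum of squares). Profiles are the replicate-averaged
#' time courses.
#'
#' @param m a [TimeSeriesExperiment-class] (replicates averaged first) or a
#'   genes x time-points matrix.
#' @param labels integer vector of cluster labels, one per gene; every
#'   cluster must be non-empty.
#' @return numeric(1), the dispersion \eqn{W_k}.
#' @export
euclideanDispersion <- function(m, labels) {
  X <- if (is(m, "TimeSeriesExperiment"))
    exprsMatrix(averageReplicates(m)) else as.matrix(m)
  stopIfNot(length(labels) == nrow(X),
            "need one label per gene (%d labels, %d genes)",
            length(labels), nrow(X))
  total <- 0
  for (r in unique(labels)) {
    idx <- which(labels == r)
    stopIfNot(length(idx) > 0L, "empty cluster %s", r)
    sub <- X[idx, , drop = FALSE]
    mu <- colMeans(sub)
    total <- total + sum(sweep(sub, 2L, mu)^2)
  }
  total
}

#' Within-cluster Gaussian-process likelihood dispersion
#'
#' For each cluster, fits a Gaussian-process regression to all member
#' profiles ([fitClusterGP()]) and sums the log marginal likelihood of every
#' member profile under the fitted process
#' ([logMarginalLikelihood()]):
#' \deqn{W_k^{GP} = \sum_{r=1}^k L_r, \qquad
#'   L_r = \sum_{x \in C_r} \log P(x \mid \hat\mu, K + (\sigma^N)^2 I).}
#' A larger value indicates smaller within-cluster variance.
#'
#' @param m a [TimeSeriesExperiment-class] or a genes x time-points matrix
#'   of (replicate-level or averaged) profiles.
#' @param labels integer cluster labels, one per row/gene.
#' @param times numeric column times (taken from the object when `m` is a
#'   [TimeSeriesExperiment-class]).
#' @param interpolationStep numeric(1), grid spacing for the GP evaluation.
#' @param seed integer(1), seed for GP restarts (one child seed per
#'   cluster); the result is deterministic given the seed.
#' @param covariance member-likelihood covariance, `"posterior"` (default)
#'   or `"prior"`; see [logMarginalLikelihood()].
#' @param ... further arguments to [fitClusterGP()].
#' @return numeric(1), \eqn{W_k^{GP}}, with the per-cluster [GPFit-class]
#'   objects attached as attribute `"fits"` (named by cluster label).
#' @export
gpDispersion <- function(m, labels, times = NULL, interpolationStep = 1,
                         seed = 1L,
                         covariance = c("posterior", "prior"), ...) {
  covariance <- match.arg(covariance)
  if (is(m, "TimeSeriesExperiment")) {
    X <- replicateProfiles(m)
    prof <- attr(X, "gene")
    times <- attr(X, "times")
    interpolationStep <- interpolationStep(m)
    geneLabels <- labels[prof]
  } else {
    X <- as.matrix(m)
    stopIfNot(!is.null(times), "'times' is required for matrix input")
    geneLabels <- labels
  }
  stopIfNot(length(geneLabels) == nrow(X),
            "need one label per profile row")
  ids <- sort(unique(geneLabels))
  fits <- vector("list", length(ids))
  names(fits) <- as.character(ids)
  total <- 0
  for (i in seq_along(ids)) {
    idx <- which(geneLabels == ids[i])
    Y <- X[idx, , drop = FALSE]
    fit <- fitClusterGP(Y, times, interpolationStep = interpolationStep,
                        seed = childSeed(seed, i), ...)
    fits[[i]] <- fit
    total <- total + sum(apply(Y, 1L, logMarginalLikelihood, fit = fit,
                               covariance = covariance))
  }
  structure(total, fits = fits)
}

# Expand a TimeSeriesExperiment into one complete profile per (gene,
# replicate) over the shared time grid. Replicates with any missing value
# fall back to the gene's replicate-averaged profile for that row.
replicateProfiles <- function(x) {
  tp <- timePoints(x)
  cd <- SummarizedExperiment::colData(x)
  m <- exprsMatrix(x)
  avg <- exprsMatrix(averageReplicates(x))
  reps <- sort(unique(cd$replicate))
  rows <- list(); gene <- character()
  for (q in reps) {
    cols <- vapply(tp, function(t)
      which(cd$time == t & cd$replicate == q)[1L], integer(1))
    if (anyNA(cols)) next
    sub <- m[, cols, drop = FALSE]
    miss <- !stats::complete.cases(sub)
    sub[miss, ] <- avg[miss, , drop = FALSE]
    rows[[length(rows) + 1L]] <- sub
    gene <- c(gene, rownames(m))
  }
  out <- do.call(rbind, rows)
  structure(out, gene = gene, times = tp)
}

#' Draw a structureless reference data set
#'
#' Each time-point feature is drawn i.i.d. uniformly over the observed
#' range of that feature, producing data with the same marginal spans but
#' no clustering pattern — the null reference of the gap statistic.
#'
#' @param m a [TimeSeriesExperiment-class] (replicates averaged first) or a
#'   genes x time-points matrix.
#' @param seed integer(1); the draw is deterministic given the seed.
#' @return A matrix of the same dimensions (and dimnames) as the averaged
#'   input.
#' @export
sampleReference <- function(m, seed = 1L) {
  X <- if (is(m, "TimeSeriesExperiment"))
    exprsMatrix(averageReplicates(m)) else as.matrix(m)
  lo <- apply(X, 2L, min); hi <- apply(X, 2L, max)
  withLocalSeed(seed, {
    ref <- vapply(seq_len(ncol(X)),
                  function(j) stats::runif(nrow(X), lo[j], hi[j]),
                  numeric(nrow(X)))
    if (nrow(X) == 1L) ref <- matrix(ref, nrow = 1L)
    dimnames(ref) <- dimnames(X)
    ref
  })
}

#' Select the number of clusters by a gap-statistic scan
#'
#' For each candidate k, clusters the observed profiles and `B`
#' structureless reference draws with the same algorithm and compares
#' dispersions:
#' * `mode = "euclidean"`: classic gap,
#'   \eqn{Gap(k) = E^*[\log W_k^{ref}] - \log W_k^{obs}};
#' * `mode = "gp"`: likelihood gap,
#'   \eqn{Gap^{GP}(k) = W_k^{GP,obs} - E^*[W_k^{GP,ref}]}. The textbook
#'   form takes an outer log of \eqn{W_k^{GP}}, but a summed log-likelihood
#'   is typically negative, so the difference of likelihoods is used
#'   (monotone-equivalent where the log is defined); set
#'   `literalLog = TRUE` to force the logged form, which errors on
#'   non-positive dispersion.
#'
#' Three selection criteria are available. The default, `"se-max"`, picks
#' the smallest k whose gap lies within one reference standard error of
#' the global maximum gap — the usual guard against a gap curve that
#' plateaus beyond the true k, where reference sampling noise would push a
#' bare argmax towards the top of the range. `"argmax"` takes the literal
#' maximiser (ties towards the smallest k); `"tibshirani-se"` picks the
#' smallest k with \eqn{Gap(k) \ge Gap(k+1) - SE(k+1)}.
#'
#' @param m a [TimeSeriesExperiment-class] or genes x time-points matrix of
#'   normalized profiles.
#' @param kRange integer(2), inclusive candidate range (default `c(1, 20)`).
#' @param method clustering algorithm: `"kmeans"` (k-means++ style restarts
#'   via `nstart = 10`) or `"agglomerative"` (Ward linkage).
#' @param B integer(1), number of reference draws (default 10).
#' @param mode `"gp"` or `"euclidean"`.
#' @param gapCriterion `"se-max"` (default), `"argmax"` or
#'   `"tibshirani-se"`; see Details.
#' @param literalLog logical(1), see Details.
#' @param seed integer(1), master seed for clustering restarts, reference
#'   draws and GP restarts; the scan is fully reproducible given it.
#' @param times,interpolationStep time metadata for matrix input.
#' @param ... further arguments to [fitClusterGP()].
#' @return A [GapScan-class] object.
#' @examples
#' sim <- simulateTimeSeries(scrnaLikeSpec(seed = 7, genesPerCluster =
#'   rep(20, 3)))
#' scan <- gapScan(sim$tse, kRange = c(1, 4), B = 3, seed = 7)
#' kOpt(scan)
#' @export
gapScan <- function(m, kRange = c(1L, 20L),
                    method = c("kmeans", "agglomerative"), B = 10L,
                    mode = c("gp", "euclidean"),
                    gapCriterion = c("se-max", "argmax", "tibshirani-se"),
                    literalLog = FALSE, seed = 1L,
                    times = NULL, interpolationStep = 1, ...) {
  method <- match.arg(method); mode <- match.arg(mode)
  gapCriterion <- match.arg(gapCriterion)
  if (is(m, "TimeSeriesExperiment")) {
    X <- exprsMatrix(averageReplicates(m))
    times <- timePoints(m)
    interpolationStep <- interpolationStep(m)
  } else {
    X <- as.matrix(m)
    stopIfNot(!is.null(times) || mode == "euclidean",
              "'times' is required for matrix input in gp mode")
  }
  B <- as.integer(B)
  stopIfNot(B >= 1L, "'B' must be >= 1")
  ks <- seq(as.integer(kRange[1L]), as.integer(kRange[2L]))
  keep <- ks <= nrow(X)
  if (!all(keep)) {
    warning(sprintf("skipping k > %d (number of genes)", nrow(X)))
    ks <- ks[keep]
  }
  stopIfNot(length(ks) >= 1L, "empty k range")

  dispersion <- function(mat, labels, s) {
    if (mode == "euclidean") euclideanDispersion(mat, labels)
    else as.numeric(gpDispersion(mat, labels, times = times,
                                 interpolationStep = interpolationStep,
                                 seed = s, ...))
  }
  refs <- lapply(seq_len(B), function(b)
    sampleReference(X, seed = childSeed(seed, 100000L + b)))

  obs <- numeric(length(ks)); eRef <- numeric(length(ks))
  seRef <- numeric(length(ks)); gap <- numeric(length(ks))
  assignments <- vector("list", length(ks))
  names(assignments) <- as.character(ks)
  for (i in seq_along(ks)) {
    k <- ks[i]
    lab <- clusterProfiles(X, k, method, seed = childSeed(seed, k))
    assignments[[i]] <- lab
    wObs <- dispersion(X, lab, childSeed(seed, 1000L + k))
    wRef <- vapply(seq_len(B), function(b) {
      labR <- clusterProfiles(refs[[b]], k, method,
                              seed = childSeed(seed, 2000L + k * 101L + b))
      dispersion(refs[[b]], labR, childSeed(seed, 3000L + k * 101L + b))
    }, numeric(1))
    if (mode == "euclidean" || literalLog) {
      if (literalLog && mode == "gp" &&
          (wObs <= 0 || any(wRef <= 0)))
        stop("literal log form undefined: non-positive GP dispersion")
      lObs <- log(wObs); lRef <- log(wRef)
      obs[i] <- lObs
      eRef[i] <- mean(lRef)
      seRef[i] <- stats::sd(lRef) * sqrt(1 + 1 / B)
      gap[i] <- if (mode == "euclidean") eRef[i] - lObs
                else lObs - eRef[i]
    } else {
      obs[i] <- wObs
      eRef[i] <- mean(wRef)
      seRef[i] <- stats::sd(wRef) * sqrt(1 + 1 / B)
      gap[i] <- wObs - eRef[i]
    }
  }
  seRef[!is.finite(seRef)] <- 0

  kOpt <- switch(gapCriterion,
    "argmax" = ks[which.max(gap)],   # first maximum = smallest k on ties
    "se-max" = {
      iMax <- which.max(gap)
      thr <- gap[iMax] - seRef[iMax]
      ks[which(gap >= thr)[1L]]
    },
    "tibshirani-se" = {
      sel <- NA_integer_
      for (i in seq_along(ks)[-length(ks)]) {
        if (gap[i] >= gap[i + 1L] - seRef[i + 1L]) { sel <- ks[i]; break }
      }
      if (is.na(sel)) ks[length(ks)] else sel
    })
  stat <- data.frame(k = ks, observed = obs, referenceMean = eRef,
                     referenceSE = seRef, gap = gap)
  new("GapScan", kRange = ks, mode = mode, method = method,
      statistic = stat, kOpt = as.integer(kOpt),
      assignments = assignments, B = B, seed = as.integer(seed))
}
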