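#' Specify a synthetic time-series experiment with planted clusters
#'
#' Defines a simulation in which each cluster's genes are noisy copies of
#' one smooth base curve, temporally shifted per cluster so that the shift
#' order defines a ground-truth state sequence, with optional planted
#' pathway memberships for testing the enrichment criterion.
#'
#' @param kTrue integer(1), number of planted clusters.
#' @param genesPerCluster integer vector (recycled to `kTrue`), genes per
#'   cluster.
#' @param times numeric vector, the observed time grid.
#' @param family base-curve family: `"gp"` (a smooth draw from an RBF
#'   Gaussian process), `"sinusoid"`, `"impulse"` (Gaussian bump) or
#'   `"logistic"` (sigmoidal activation).
#' @param shifts numeric vector of per-cluster shifts in interpolation-grid
#'   steps; their sorted order is the ground-truth temporal order.
#' @param noiseSd numeric(1), i.i.d. Gaussian noise sd added per gene,
#'   time point and replicate (default 0.3 on the z scale).
#' @param nRep integer(1), replicates per time point.
#' @param interpolationStep numeric(1), grid step (shift unit).
#' @param period numeric(1), period of the sinusoid family (default: the
#'   grid span, one full cycle).
#' @param pathways optional list of planted pathways, each a list with
#'   `id`, `fractions` (per-cluster membership fractions) and `size`
#'   (total pathway genes drawn according to `fractions`).
#' @param seed integer(1), master seed.
#' @return A list of class `"SimulationSpec"`.
#' @seealso [simulateTimeSeries()], [emtLikeSpec()], [cellcycleLikeSpec()],
#'   [scrnaLikeSpec()]
#' @export
simulationSpec <- function(kTrue, genesPerCluster, times,
                           family = c("gp", "sinusoid", "impulse",
                                      "logistic"),
                           shifts = seq_len(kTrue) - 1,
                           noiseSd = 0.3, nRep = 1L,
                           interpolationStep = 1, period = NULL,
                           pathways = NULL, seed = 1L) {
  family <- match.arg(family)
  kTrue <- as.integer(kTrue)
  stopIfNot(kTrue >= 1L, "'kTrue' must be >= 1")
  stopIfNot(length(times) >= 2L && !is.unsorted(times, strictly = TRUE),
            "'times' must be strictly increasing with length >= 2")
  genesPerCluster <- rep_len(as.integer(genesPerCluster), kTrue)
  shifts <- rep_len(as.numeric(shifts), kTrue)
  span <- diff(range(times))
  stopIfNot(all(abs(shifts) * interpolationStep < span),
            "shift magnitude must be smaller than the grid span")
  structure(list(
    kTrue = kTrue, genesPerCluster = genesPerCluster, times = times,
    family = family, shifts = shifts, noiseSd = noiseSd,
    nRep = as.integer(nRep), interpolationStep = interpolationStep,
    period = if (is.null(period)) span else period,
    pathways = pathways, seed = as.integer(seed)),
    class = "SimulationSpec")
}

# Base curve of a family, evaluated at arbitrary times within [t0, t1].
baseCurve <- function(family, times, t0, t1, period, seed) {
  span <- t1 - t0
  switch(family,
    sinusoid = sin(2 * pi * (times - t0) / period),
    impulse = {
      centre <- t0 + span / 4
      width <- span / 8
      exp(-(times - centre)^2 / (2 * width^2))
    },
    logistic = {
      centre <- t0 + span / 4
      tau <- span / 12
      1 / (1 + exp(-(times - centre) / tau))
    },
    gp = {
      fine <- seq(t0 - span / 2, t1 + span / 2, length.out = 120L)
      l <- span / 4
      K <- rbfMatrix(fine, fine, l) + diag(1e-8, length(fine))
      z <- withLocalSeed(seed, as.numeric(t(chol(K)) %*% rnorm(length(fine))))
      stats::approx(fine, z, xout = times, rule = 2L)$y
    })
}

#' Simulate a time-series matrix with planted structure
#'
#' Draws one base curve per the spec's family, shifts it per cluster
#' (cluster r's curve is the base evaluated at `t - shift[r] * step`), adds
#' i.i.d. Gaussian noise per gene/time/replicate, and emits the matrix with
#' its ground truth. Identical seeds give byte-identical fixtures.
#'
#' @param spec a `"SimulationSpec"` from [simulationSpec()] or a preset.
#' @return list with `tse` (a [TimeSeriesExperiment-class]), `labels`
#'   (named integer vector of planted clusters), `order` (integer vector,
#'   cluster ids sorted by increasing shift = ground-truth temporal order,
#'   earliest first) and `geneSets` (named list, possibly empty).
#' @examples
#' sim <- simulateTimeSeries(simulationSpec(
#'   kTrue = 2, genesPerCluster = 5, times = 0:7, family = "impulse",
#'   shifts = c(0, 2), noiseSd = 0.1, seed = 42))
#' table(sim$labels)
#' @export
simulateTimeSeries <- function(spec) {
  stopIfNot(inherits(spec, "SimulationSpec"),
            "'spec' must come from simulationSpec()")
  times <- spec$times
  t0 <- min(times); t1 <- max(times)
  nGenes <- sum(spec$genesPerCluster)
  geneIds <- sprintf("g%04d", seq_len(nGenes))
  labels <- rep(seq_len(spec$kTrue), times = spec$genesPerCluster)
  names(labels) <- geneIds

  colTimes <- rep(times, each = spec$nRep)
  vals <- withLocalSeed(spec$seed, {
    m <- matrix(NA_real_, nGenes, length(colTimes))
    for (r in seq_len(spec$kTrue)) {
      shifted <- colTimes - spec$shifts[r] * spec$interpolationStep
      curve <- baseCurve(spec$family, shifted, t0, t1, spec$period,
                         seed = childSeed(spec$seed, 555L))
      rows <- which(labels == r)
      noise <- matrix(stats::rnorm(length(rows) * length(colTimes),
                                   sd = spec$noiseSd),
                      length(rows), length(colTimes))
      m[rows, ] <- matrix(curve, length(rows), length(colTimes),
                          byrow = TRUE) + noise
    }
    rownames(m) <- geneIds
    m
  })
  tse <- TimeSeriesExperiment(vals, times = times, nRep = spec$nRep,
                              interpolationStep = spec$interpolationStep)
  geneSets <- list()
  if (!is.null(spec$pathways)) {
    geneSets <- withLocalSeed(childSeed(spec$seed, 777L), {
      sets <- lapply(spec$pathways, function(p) {
        frac <- rep_len(p$fractions, spec$kTrue)
        counts <- round(frac * p$size)
        unlist(lapply(seq_len(spec$kTrue), function(r) {
          pool <- geneIds[labels == r]
          sample(pool, min(counts[r], length(pool)))
        }))
      })
      names(sets) <- vapply(spec$pathways, `[[`, character(1), "id")
      sets
    })
  }
  list(tse = tse, labels = labels,
       order = order(spec$shifts), geneSets = geneSets)
}

#' Preset: uneven developmental series (EMT-like archetype)
#'
#' Three sequential states observed at 0, 6, 12, 24, 36, 48, 72 and 96
#' hours — an unevenly sampled developmental design. States are
#' sequential logistic activations separated by 24- and 36-hour shifts.
#'
#' @param seed integer(1).
#' @param genesPerCluster integer vector, genes per state (default 544
#'   each, the scale of a typical post-DEG developmental set).
#' @param noiseSd numeric(1), noise level (default 0.3).
#' @return A `"SimulationSpec"`.
#' @export
emtLikeSpec <- function(seed = 1L, genesPerCluster = rep(544L, 3),
                        noiseSd = 0.3) {
  simulationSpec(
    kTrue = 3L, genesPerCluster = genesPerCluster,
    times = c(0, 6, 12, 24, 36, 48, 72, 96),
    family = "logistic", shifts = c(0, 24, 60), noiseSd = noiseSd,
    interpolationStep = 1, seed = seed)
}

#' Preset: cyclic series (cell-cycle-like archetype)
#'
#' Five phase clusters over 17 time points at 10-minute intervals covering
#' two full cycles: phase-shifted sinusoids with period 80 minutes and
#' cluster sizes 31, 81, 44, 31, 34 (the canonical phase-annotated gene
#' counts). Cyclic order is recoverable only up to rotation of the cycle.
#'
#' @inheritParams emtLikeSpec
#' @return A `"SimulationSpec"`.
#' @export
cellcycleLikeSpec <- function(seed = 1L,
                              genesPerCluster = c(31L, 81L, 44L, 31L, 34L),
                              noiseSd = 0.3) {
  simulationSpec(
    kTrue = 5L, genesPerCluster = genesPerCluster,
    times = seq(0, 160, by = 10),
    family = "sinusoid", shifts = c(0, 16, 32, 48, 64),
    noiseSd = noiseSd, interpolationStep = 1, period = 80, seed = seed)
}

#' Preset: short averaged pseudo-time series (scRNA-like archetype)
#'
#' Three states over five pseudo-time points (cell types averaged to one
#' profile each, a single replicate), 120 genes per state: sequential
#' Gaussian impulses one grid step apart.
#'
#' @inheritParams emtLikeSpec
#' @return A `"SimulationSpec"`.
#' @export
scrnaLikeSpec <- function(seed = 1L, genesPerCluster = rep(120L, 3),
                          noiseSd = 0.3) {
  simulationSpec(
    kTrue = 3L, genesPerCluster = genesPerCluster, times = 0:4,
    family = "impulse", shifts = c(0, 1, 2), noiseSd = noiseSd,
    interpolationStep = 1, seed = seed)
}
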