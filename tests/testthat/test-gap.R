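test_that("Euclidean dispersion: pair-sum and centroid routes agree", {
  # singletons have no pairs
  X1 <- matrix(rnorm(15), 5, 3, dimnames = list(paste0("g", 1:5), NULL))
  expect_equal(euclideanDispersion(X1, 1:5), 0)

  # one cluster of two 1-D points, both routes by hand
  X2 <- matrix(c(1, 4), 2, 1, dimnames = list(c("a", "b"), NULL))
  expect_equal(euclideanDispersion(X2, c(1, 1)),
               pairSumDispersion(X2, c(1, 1)))
  expect_equal(euclideanDispersion(X2, c(1, 1)), (4 - 1)^2 / 2)

  # random data, k = 3: identity to 1e-9
  set.seed(20)
  X <- matrix(rnorm(100), 20, 5, dimnames = list(paste0("g", 1:20), NULL))
  lab <- rep(1:3, length.out = 20)
  expect_equal(euclideanDispersion(X, lab), pairSumDispersion(X, lab),
               tolerance = 1e-9)
  expect_error(euclideanDispersion(X, lab[-1]), "label")
})

test_that("GP dispersion is additive and rewards the true split", {
  t <- 0:7
  sim <- simulateTimeSeries(simulationSpec(
    kTrue = 2, genesPerCluster = 10, times = t, family = "impulse",
    shifts = c(0, 3), noiseSd = 0.1, seed = 21))
  X <- exprsMatrix(sim$tse)

  # true split scores higher than one merged cluster
  wTrue <- as.numeric(gpDispersion(X, sim$labels, times = t, seed = 1))
  wOne <- as.numeric(gpDispersion(X, rep(1L, nrow(X)), times = t,
                                  seed = 1))
  expect_gt(wTrue, wOne)

  # Eq.-4 additivity: with a fixed fit, duplicating members doubles the sum
  fits <- attr(gpDispersion(X, sim$labels, times = t, seed = 1), "fits")
  f1 <- fits[["1"]]
  members <- X[sim$labels == 1L, ]
  s1 <- sum(apply(members, 1, logMarginalLikelihood, fit = f1))
  s2 <- sum(apply(rbind(members, members), 1, logMarginalLikelihood,
                  fit = f1))
  expect_equal(s2, 2 * s1, tolerance = 1e-10)

  # an arbitrary split of a homogeneous cluster gains less than the true
  # split of a genuine two-cluster mixture
  homo <- simulateTimeSeries(simulationSpec(
    kTrue = 1, genesPerCluster = 20, times = t, family = "impulse",
    noiseSd = 0.1, seed = 22))
  Xh <- exprsMatrix(homo$tse)
  arbitrary <- rep(1:2, each = 10)
  gainArb <- as.numeric(gpDispersion(Xh, arbitrary, times = t, seed = 2)) -
    as.numeric(gpDispersion(Xh, rep(1L, 20), times = t, seed = 2))
  gainTrue <- wTrue - wOne
  expect_lt(gainArb, gainTrue)
})

test_that("reference draws stay in range and respect the seed contract", {
  set.seed(23)
  X <- cbind(rnorm(30), rnorm(30, 5), rep(2, 30))
  rownames(X) <- paste0("g", 1:30)
  ref <- sampleReference(X, seed = 7)
  expect_equal(dim(ref), dim(X))
  # constant feature stays at its value; others stay inside observed range
  expect_true(all(ref[, 3] == 2))
  for (j in 1:2) {
    expect_gte(min(ref[, j]), min(X[, j]))
    expect_lte(max(ref[, j]), max(X[, j]))
  }
  expect_identical(ref, sampleReference(X, seed = 7))
  expect_false(identical(ref, sampleReference(X, seed = 8)))
})

test_that("gap scans are reproducible and respect the k range", {
  sim <- simulateTimeSeries(scrnaLikeSpec(
    seed = 24, genesPerCluster = rep(10L, 3), noiseSd = 0.15))
  s1 <- gapScan(sim$tse, kRange = c(1, 4), B = 3, mode = "gp", seed = 9)
  s2 <- gapScan(sim$tse, kRange = c(1, 4), B = 3, mode = "gp", seed = 9)
  expect_identical(gapCurve(s1), gapCurve(s2))
  expect_identical(s1@assignments, s2@assignments)
  expect_true(kOpt(s1) %in% 1:4)

  # forced single k
  sForced <- gapScan(sim$tse, kRange = c(1, 1), B = 2, mode = "euclidean",
                     seed = 1)
  expect_equal(kOpt(sForced), 1L)

  # k beyond the number of genes is skipped with a warning
  tiny <- makeTse(nGenes = 3, times = 0:4)
  expect_warning(sTiny <- gapScan(tiny, kRange = c(1, 5), B = 2,
                                  mode = "euclidean", seed = 1),
                 "skipping")
  expect_lte(kOpt(sTiny), 3L)
})

test_that("the literal logged GP gap errors on non-positive dispersion", {
  sim <- simulateTimeSeries(scrnaLikeSpec(
    seed = 25, genesPerCluster = rep(8L, 3), noiseSd = 0.15))
  expect_error(
    gapScan(sim$tse, kRange = c(1, 2), B = 2, mode = "gp",
            literalLog = TRUE, seed = 1),
    "non-positive")
})

test_that("Euclidean gap recovers planted structure in a plane mixture", {
  hits <- 0
  for (s in 1:5) {
    set.seed(s)
    X <- rbind(matrix(rnorm(40, 0, .2), 20, 2),
               matrix(rnorm(40, 3, .2), 20, 2),
               cbind(rnorm(20, 0, .2), rnorm(20, 3, .2)))
    rownames(X) <- sprintf("p%02d", 1:60)
    scan <- gapScan(X, kRange = c(1, 6), B = 20, mode = "euclidean",
                    seed = s)
    hits <- hits + (kOpt(scan) == 3L)
  }
  expect_gte(hits, 4)
})

test_that("GP mode tracks the true k better than Euclidean mode on
           shift-jittered clusters at uneven sampling", {
  # three sequential activations on an uneven grid; each gene's activation
  # time is jittered within its state, a within-cluster shift continuum
  # that Euclidean dispersion happily splits into extra clusters, while
  # the GP absorbs it into wider posterior bands
  t <- c(0, 6, 12, 24, 36, 48, 72, 96)
  mkJitter <- function(s, n = 20, tau = 10, noise = 0.12) {
    set.seed(s)
    ctr <- c(18, 42, 78)
    X <- do.call(rbind, lapply(1:3, function(r)
      t(sapply(seq_len(n), function(g) {
        d <- rnorm(1, 0, tau)
        1 / (1 + exp(-(t - ctr[r] - d) / 8)) + rnorm(8, 0, noise)
      }))))
    rownames(X) <- sprintf("g%03d", seq_len(3 * n))
    X
  }
  errG <- errE <- numeric(20)
  for (s in 1:20) {
    tse <- TimeSeriesExperiment(mkJitter(s), times = t)
    errG[s] <- abs(kOpt(gapScan(tse, kRange = c(1, 8), B = 6,
                                mode = "gp", seed = s)) - 3)
    errE[s] <- abs(kOpt(gapScan(tse, kRange = c(1, 8), B = 6,
                                mode = "euclidean", seed = s)) - 3)
  }
  expect_lt(mean(errG), mean(errE))
  p <- wilcox.test(errG, errE, paired = TRUE, alternative = "less",
                   exact = FALSE)$p.value
  expect_lt(p, 0.05)
})
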