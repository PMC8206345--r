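test_that("kernel entries follow the RBF-plus-white form", {
  # zero distance: RBF is 1 and the white term adds on equality
  expect_equal(kernelMatrix(2, 2, lengthScale = 5, noiseSd = 0.3)[1, 1],
               1 + 0.09)
  # far apart: decays to zero, no white contribution off-equality
  expect_lt(kernelMatrix(0, 1e4, lengthScale = 1, noiseSd = 2)[1, 1],
            1e-300)
  # worked value at unit length scale
  K <- kernelMatrix(c(0, 1, 2), c(0, 1, 2), lengthScale = 1, noiseSd = 0)
  expect_equal(K[1, 2], exp(-1 / 2), tolerance = 1e-12)
  expect_error(kernelMatrix(0:2, 0:2, lengthScale = 0), "positive")
})

test_that("kernel matrix equals brute-force elementwise evaluation", {
  set.seed(10)
  for (rep in 1:5) {
    ta <- sort(runif(4, 0, 10)); tb <- c(ta[2], runif(3, 0, 10))
    l <- runif(1, 0.5, 4); s <- runif(1, 0, 1)
    K <- kernelMatrix(ta, tb, l, s)
    for (i in seq_along(ta)) for (j in seq_along(tb)) {
      expected <- exp(-((ta[i] - tb[j]) / l)^2 / 2) +
        (ta[i] == tb[j]) * s^2
      expect_equal(K[i, j], expected, tolerance = 1e-12)
    }
    expect_true(isSymmetric(kernelMatrix(ta, ta, l, s)))
    ev <- eigen(kernelMatrix(ta, ta, l, s), only.values = TRUE)$values
    expect_true(all(ev > -1e-10))
  }
})

test_that("structured joint likelihood equals the dense-covariance oracle", {
  set.seed(11)
  t <- c(0, 1, 2, 4, 7)
  for (G in c(1, 3, 6)) {
    Y <- matrix(rnorm(G * 5), G, 5)
    l <- runif(1, 0.5, 3); s2 <- runif(1, 0.05, 1)
    fast <- statepath:::structuredLML(Y, outer(t, t, "-")^2, l, s2)
    R <- exp(-outer(t / l, t / l, "-")^2 / 2)
    Kfull <- kronecker(matrix(1, G, G), R) + diag(s2, G * 5)
    y <- as.numeric(t(Y))
    dense <- -0.5 * drop(t(y) %*% solve(Kfull, y)) -
      0.5 * as.numeric(determinant(Kfull)$modulus) -
      0.5 * G * 5 * log(2 * pi)
    expect_equal(fast, dense, tolerance = 1e-9)
  }
})

test_that("profile likelihood matches a direct multivariate-normal oracle", {
  set.seed(12)
  t5 <- c(0, 1, 3, 4, 6)
  for (rep in 1:5) {
    l <- runif(1, 0.5, 4); s <- runif(1, 0.1, 1)
    mu <- rnorm(5); x <- rnorm(5)
    Cov <- exp(-outer(t5 / l, t5 / l, "-")^2 / 2)
    fit <- new("GPFit", lengthScale = l, noiseSd = s, bounds = list(),
               trainTimes = t5, grid = t5, mean = mu, sd = rep(1, 5),
               muObs = mu, covObs = Cov, logMarginal = 0,
               nProfiles = 1L)
    got <- logMarginalLikelihood(x, fit)
    C <- exp(-outer(t5 / l, t5 / l, "-")^2 / 2) + diag(s^2, 5)
    r <- x - mu
    oracle <- -0.5 * drop(t(r) %*% solve(C) %*% r) -
      0.5 * log(det(C)) - 2.5 * log(2 * pi)
    expect_equal(got, oracle, tolerance = 1e-8)
  }
})

test_that("likelihood limiting cases behave as the Gaussian density", {
  # single time point, unit covariance, zero residual: standard normal at 0
  fit1 <- new("GPFit", lengthScale = 1, noiseSd = 0, bounds = list(),
              trainTimes = 0, grid = 0, mean = 0, sd = 1, muObs = 0,
              covObs = matrix(1), logMarginal = 0, nProfiles = 1L)
  expect_equal(logMarginalLikelihood(0, fit1), -0.5 * log(2 * pi),
               tolerance = 1e-12)

  # zero residual leaves only the determinant and constant terms
  t4 <- 0:3
  fit4 <- new("GPFit", lengthScale = 2, noiseSd = 0.5, bounds = list(),
              trainTimes = t4, grid = t4, mean = rep(1, 4), sd = rep(1, 4),
              muObs = rep(1, 4),
              covObs = exp(-outer(t4 / 2, t4 / 2, "-")^2 / 2),
              logMarginal = 0, nProfiles = 1L)
  C <- exp(-outer(t4 / 2, t4 / 2, "-")^2 / 2) + diag(0.25, 4)
  expect_equal(logMarginalLikelihood(rep(1, 4), fit4),
               -0.5 * log(det(C)) - 2 * log(2 * pi), tolerance = 1e-10)

  # doubling the residual quadruples the quadratic term
  base <- logMarginalLikelihood(rep(1, 4), fit4)
  r1 <- logMarginalLikelihood(rep(1, 4) + c(.1, 0, -.1, .2), fit4) - base
  r2 <- logMarginalLikelihood(rep(1, 4) + 2 * c(.1, 0, -.1, .2), fit4) -
    base
  expect_equal(r2, 4 * r1, tolerance = 1e-10)

  # duplicated times with a zero noise floor are singular
  fitDup <- new("GPFit", lengthScale = 1, noiseSd = 0, bounds = list(),
                trainTimes = c(0, 0), grid = c(0, 0), mean = c(0, 0),
                sd = c(1, 1), muObs = c(0, 0),
                covObs = matrix(1, 2, 2), logMarginal = 0,
                nProfiles = 1L)
  expect_error(logMarginalLikelihood(c(0, 0), fitDup), "noise")
})

test_that("GP regression recovers a noiseless linear trend", {
  t <- 0:9
  line <- 0.3 * t - 1
  Y <- rbind(line, line, line)
  fit <- fitClusterGP(Y, t, seed = 3)
  mu <- gpMean(fit)[as.character(t)]
  expect_lt(max(abs(mu - line)), 0.05)
})

test_that("a single training point shrinks towards zero as noise grows", {
  fit <- fitClusterGP(matrix(2, 1, 1), times = 3, seed = 1)
  muAt3 <- fit@mean[fit@grid == 3]
  s2 <- fit@noiseSd^2
  expect_lte(muAt3, 2 + 1e-8)
  expect_gte(muAt3, 2 / (1 + s2) - 1e-8)
})

test_that("posterior uncertainty grows away from the data", {
  t <- c(0, 1, 2, 10, 11, 12)
  set.seed(13)
  Y <- rbind(rnorm(6, sd = .1) + c(1, 1, 1, -1, -1, -1),
             rnorm(6, sd = .1) + c(1, 1, 1, -1, -1, -1))
  fit <- fitClusterGP(Y, t, seed = 4)
  sdMid <- fit@sd[which.min(abs(fit@grid - 6))]
  sdAtData <- fit@sd[fit@grid %in% t]
  expect_gt(sdMid, max(sdAtData))
})

test_that("flat clusters fit without error and hyperparameters stay bounded", {
  t <- 0:7
  fit <- fitClusterGP(matrix(1, 4, 8), t, seed = 2)
  expect_s4_class(fit, "GPFit")
  expect_true(all(abs(fit@muObs - fit@muObs[1]) < 0.2))
  expect_gte(fit@lengthScale, 1e-3 * max(t) - 1e-12)
  expect_lte(fit@lengthScale, max(t) + 1e-12)
  expect_gte(fit@noiseSd, 1e-5)
  # interpolation grid covers observed points and unit steps
  expect_true(all(t %in% fit@grid))
  expect_true(all(diff(fit@grid) <= 1 + 1e-12))
})

test_that("scattered (time, value) input agrees with the matrix path", {
  t <- 0:5
  Y <- rbind(sin(t), sin(t) + 0.1)
  fitM <- fitClusterGP(Y, t, seed = 9)
  fitS <- fitClusterGP(as.numeric(t(Y)), rep(t, 2), seed = 9)
  expect_equal(fitS@lengthScale, fitM@lengthScale, tolerance = 1e-4)
  expect_equal(fitS@mean, fitM@mean, tolerance = 1e-5)
})

test_that("fits are deterministic given a seed", {
  set.seed(14)
  Y <- matrix(rnorm(24), 3, 8)
  f1 <- fitClusterGP(Y, 0:7, seed = 42)
  f2 <- fitClusterGP(Y, 0:7, seed = 42)
  expect_identical(f1@lengthScale, f2@lengthScale)
  expect_identical(f1@mean, f2@mean)
})
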