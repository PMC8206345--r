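#' Evaluate the RBF-plus-white kernel between two sets of time points
#'
#' The covariance between times \eqn{t_i}{ti} and \eqn{t_j}{tj} is
#' \deqn{K(t_i, t_j) = \exp\!\left(-\tfrac{1}{2}\,\|t_i/l - t_j/l\|^2\right)
#'   + [t_i = t_j]\,(\sigma^N)^2,}
#' an RBF term with length scale \eqn{l} plus a white-noise term that
#' contributes only where the two times are exactly equal.
#'
#' @param timesA,timesB numeric vectors of time points.
#' @param lengthScale numeric(1), RBF length scale, must be positive.
#' @param noiseSd numeric(1), white-noise standard deviation
#'   \eqn{\sigma^N \ge 0}.
#' @return A `length(timesA)` x `length(timesB)` covariance matrix;
#'   symmetric positive semidefinite when `timesA == timesB`.
#' @examples
#' kernelMatrix(c(0, 1, 2), c(0, 1, 2), lengthScale = 1, noiseSd = 0)
#' @export
kernelMatrix <- function(timesA, timesB, lengthScale, noiseSd = 0) {
  stopIfNot(is.numeric(lengthScale) && length(lengthScale) == 1L &&
              lengthScale > 0, "'lengthScale' must be a single positive number")
  stopIfNot(noiseSd >= 0, "'noiseSd' must be >= 0")
  d <- outer(timesA / lengthScale, timesB / lengthScale, "-")
  k <- exp(-d^2 / 2)
  if (noiseSd > 0)
    k <- k + outer(timesA, timesB, "==") * noiseSd^2
  k
}

# RBF part only (no white term), used internally by the fitting routines.
rbfMatrix <- function(timesA, timesB, lengthScale) {
  d <- outer(timesA / lengthScale, timesB / lengthScale, "-")
  exp(-d^2 / 2)
}

# Joint log marginal likelihood of G complete profiles Y (G x Nt) observed
# at shared times under a zero-mean GP with RBF(l) + sigma^2 I noise.
#
# With points stacked gene-major the full covariance is
#   K = 1_{GxG} (x) R + sigma^2 I,
# whose eigenstructure splits into the replicated-mean direction (block
# G R + sigma^2 I) and G-1 pure-noise directions, so the likelihood costs
# O(Nt^3 + G Nt) rather than O((G Nt)^3). The identity is exercised against
# a dense-Cholesky oracle in the test suite.
structuredLML <- function(Y, d2, lengthScale, noiseVar) {
  G <- nrow(Y); Nt <- ncol(Y)
  R <- exp(-d2 / (2 * lengthScale^2))
  M <- G * R + diag(noiseVar, Nt)
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  ybar <- colMeans(Y)
  v <- backsolve(ch, forwardsolve(t(ch), ybar))    # M^{-1} ybar
  quadMean <- G * sum(ybar * v)                    # a' M^{-1} a with a = sqrt(G) ybar
  quadPerp <- (sum(Y^2) - G * sum(ybar^2)) / noiseVar
  logdet <- 2 * sum(log(diag(ch))) + (G - 1) * Nt * log(noiseVar)
  -0.5 * quadMean - 0.5 * quadPerp - 0.5 * logdet -
    0.5 * G * Nt * log(2 * pi)
}

# Dense-path log marginal likelihood for scattered (time, value) points.
denseLML <- function(times, values, lengthScale, noiseVar) {
  K <- rbfMatrix(times, times, lengthScale) +
    diag(noiseVar, length(times))
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  alpha <- backsolve(ch, forwardsolve(t(ch), values))
  -0.5 * sum(values * alpha) - sum(log(diag(ch))) -
    0.5 * length(values) * log(2 * pi)
}

#' Fit a Gaussian-process regression to one cluster
#'
#' Pools all member expression profiles of a cluster (every gene and
#' replicate contributes its full time profile) and fits a zero-mean GP
#' with an RBF kernel over time plus white observation noise. The length
#' scale and noise standard deviation are chosen by maximising the joint
#' log marginal likelihood with bounded quasi-Newton optimisation from
#' multiple seeded restarts. The posterior mean and standard deviation are
#' then evaluated on the interpolation grid, so unobserved time points are
#' interpolated as well as observed ones.
#'
#' @param y numeric matrix of profiles (rows = genes/replicates, columns =
#'   time points), or a numeric vector of values paired with `times` of the
#'   same length (scattered observations).
#' @param times numeric vector: column times when `y` is a matrix, or one
#'   time per value when `y` is a vector.
#' @param interpolationStep numeric(1), spacing of the evaluation grid
#'   (default 1).
#' @param lengthScaleFloorFrac numeric(1); the length-scale box is
#'   `[lengthScaleFloorFrac * max(times), max(times)]`. The nominal lower
#'   bound of 0 is degenerate, so a small positive floor is applied.
#' @param noiseBounds numeric(2), box for the noise standard deviation
#'   (default `c(1e-5, 10)`, bracketing unit variance on z-scored data).
#' @param restarts integer(1), number of random optimisation restarts
#'   (default 5).
#' @param seed integer(1), seed for the restart draws.
#' @return A [GPFit-class] object.
#' @examples
#' t <- 0:7
#' y <- rbind(sin(t / 2), sin(t / 2) + 0.05)
#' fit <- fitClusterGP(y, t, seed = 1)
#' fit
#' @export
fitClusterGP <- function(y, times, interpolationStep = 1,
                         lengthScaleFloorFrac = 1e-3,
                         noiseBounds = c(1e-5, 10),
                         restarts = 5L, seed = 1L) {
  if (is.matrix(y)) {
    stopIfNot(ncol(y) == length(times),
              "matrix 'y' needs one column per time point")
    Y <- y
    scattered <- FALSE
  } else {
    stopIfNot(length(y) == length(times),
              "'y' and 'times' must have equal length")
    # complete replicated profiles collapse to the fast structured path
    ord <- order(times)
    tu <- sort(unique(times))
    counts <- table(times)
    if (length(tu) >= 2L && length(unique(counts)) == 1L &&
        length(y) == length(tu) * counts[[1L]]) {
      G <- counts[[1L]]
      Y <- matrix(NA_real_, G, length(tu))
      for (j in seq_along(tu)) Y[, j] <- y[times == tu[j]]
      times <- tu
      scattered <- FALSE
    } else {
      scattered <- TRUE
      values <- y
    }
  }
  stopIfNot(length(times) >= 1L, "at least one observation is required")
  stopIfNot(all(is.finite(if (scattered) values else Y)),
            "non-finite expression values in cluster")
  tMax <- max(times)
  lBounds <- c(max(lengthScaleFloorFrac * tMax, 1e-8), tMax)
  span <- diff(range(times))
  if (span == 0) lBounds <- c(1e-3, 1)

  if (scattered) {
    negLML <- function(par)
      -denseLML(times, values, exp(par[1L]), exp(2 * par[2L]))
    negGrad <- NULL
  } else {
    d2 <- outer(times, times, "-")^2
    # value and analytic gradient w.r.t. (log l, log sigma) share the same
    # Cholesky; cached on the parameter vector because optim() calls the
    # objective and gradient separately
    cacheKey <- NULL; cacheVal <- NULL
    evalBoth <- function(par) {
      if (!is.null(cacheKey) && identical(par, cacheKey))
        return(cacheVal)
      G <- nrow(Y); Nt <- ncol(Y)
      l <- exp(par[1L]); s2 <- exp(2 * par[2L])
      R <- exp(-d2 / (2 * l^2))
      M <- G * R + diag(s2, Nt)
      ch <- tryCatch(chol(M), error = function(e) NULL)
      if (is.null(ch)) {
        cacheKey <<- par; cacheVal <<- list(value = Inf, grad = c(0, 0))
        return(cacheVal)
      }
      ybar <- colMeans(Y)
      v <- backsolve(ch, forwardsolve(t(ch), ybar))      # M^{-1} ybar
      quadMean <- G * sum(ybar * v)
      P <- sum(Y^2) - G * sum(ybar^2)
      quadPerp <- P / s2
      logdet <- 2 * sum(log(diag(ch))) + (G - 1) * Nt * log(s2)
      value <- 0.5 * quadMean + 0.5 * quadPerp + 0.5 * logdet +
        0.5 * G * Nt * log(2 * pi)
      Minv <- chol2inv(ch)
      u <- sqrt(G) * v                                   # M^{-1} a
      dRl <- G * R * (d2 / l^2)                          # dM/dlog l
      g1 <- 0.5 * sum(u * (dRl %*% u)) - 0.5 * sum(Minv * dRl)
      g2 <- s2 * sum(u^2) - s2 * sum(diag(Minv)) +
        quadPerp - (G - 1) * Nt
      cacheKey <<- par
      cacheVal <<- list(value = value, grad = -c(g1, g2))
      cacheVal
    }
    negLML <- function(par) evalBoth(par)$value
    negGrad <- function(par) evalBoth(par)$grad
  }

  lower <- log(c(lBounds[1L], noiseBounds[1L]))
  upper <- log(c(lBounds[2L], noiseBounds[2L]))
  starts <- withLocalSeed(seed, {
    s0 <- c(log(max(lBounds[1L], min(span / 2, lBounds[2L]))), log(0.5))
    extra <- matrix(stats::runif(2L * max(0L, restarts - 1L)),
                    ncol = 2L)
    rbind(s0, lower + extra %*% diag(upper - lower, 2L))
  })
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- pmin(pmax(starts[i, ], lower), upper)
    opt <- tryCatch(
      stats::optim(par0, negLML, gr = negGrad, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 200L)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value))
      best <- opt
  }
  if (is.null(best))
    stop("GP hyperparameter optimisation failed from every restart")
  # clamp away roundoff from exp(log(bound))
  l <- min(max(exp(best$par[1L]), lBounds[1L]), lBounds[2L])
  noiseSd <- min(max(exp(best$par[2L]), noiseBounds[1L]), noiseBounds[2L])
  noiseVar <- noiseSd^2

  grid <- makeInterpolationGrid(times, interpolationStep)
  if (scattered) {
    K <- rbfMatrix(times, times, l) + diag(noiseVar, length(times))
    ch <- chol(K)
    alpha <- backsolve(ch, forwardsolve(t(ch), values))
    ks <- rbfMatrix(grid, times, l)
    mu <- as.numeric(ks %*% alpha)
    w <- backsolve(ch, forwardsolve(t(ch), t(ks)))
    var <- pmax(1 + noiseVar - colSums(t(ks) * w), 1e-12)
    tu <- sort(unique(times))
    kso <- rbfMatrix(tu, times, l)
    muObs <- as.numeric(kso %*% alpha)
    wObs <- backsolve(ch, forwardsolve(t(ch), t(kso)))
    covObs <- rbfMatrix(tu, tu, l) - kso %*% wObs
    nProf <- 1L
  } else {
    G <- nrow(Y)
    R <- rbfMatrix(times, times, l)
    M <- G * R + diag(noiseVar, ncol(Y))
    ch <- chol(M)
    ybar <- colMeans(Y)
    v <- backsolve(ch, forwardsolve(t(ch), ybar))       # M^{-1} ybar
    ks <- rbfMatrix(grid, times, l)                     # n_s x Nt
    mu <- as.numeric(G * ks %*% v)
    w <- backsolve(ch, forwardsolve(t(ch), t(ks)))      # M^{-1} ks'
    var <- pmax(1 + noiseVar - G * colSums(t(ks) * w), 1e-12)
    wo <- backsolve(ch, forwardsolve(t(ch), R))
    muObs <- as.numeric(G * R %*% v)
    covObs <- R - G * R %*% wo
    nProf <- G
    tu <- times
  }
  covObs <- (covObs + t(covObs)) / 2          # symmetrise roundoff
  new("GPFit",
      lengthScale = l, noiseSd = noiseSd,
      bounds = list(lengthScale = lBounds, noiseSd = noiseBounds),
      trainTimes = as.numeric(tu), grid = as.numeric(grid),
      mean = mu, sd = sqrt(var), muObs = muObs, covObs = covObs,
      logMarginal = -best$value, nProfiles = as.integer(nProf))
}

#' Log marginal likelihood of a profile under a cluster GP
#'
#' Evaluates the Gaussian log density of one expression profile under the
#' cluster's fitted process,
#' \deqn{-\tfrac12 (x-\hat\mu)^\top (K + (\sigma^N)^2 I)^{-1} (x-\hat\mu)
#'   - \tfrac12 \log|K + (\sigma^N)^2 I| - \tfrac{N_t}{2}\log 2\pi,}
#' with mean \eqn{\hat\mu} the GP posterior mean at the observed time
#' points. By default \eqn{K} is the posterior covariance of the latent
#' process at those times (so \eqn{K + (\sigma^N)^2 I} is the predictive
#' covariance defined by the cluster's fitted mean and variance bands);
#' `covariance = "prior"` instead uses the prior RBF kernel, the more
#' literal reading of the dispersion formula. The posterior form is the
#' default because the member likelihood is meant to respond to the
#' cluster's fitted confidence band: a profile outside a tight band is
#' penalised, and a cluster that needs a wide band scores lower for all
#' its members. This is the quantity summed over cluster members by
#' [gpDispersion()].
#'
#' @param x numeric vector, one expression profile over the fit's observed
#'   time points.
#' @param fit a [GPFit-class] object.
#' @param covariance `"posterior"` (default) or `"prior"`, see Details.
#' @return numeric(1), the log density (finite whenever `noiseSd > 0`).
#' @export
logMarginalLikelihood <- function(x, fit,
                                  covariance = c("posterior", "prior")) {
  covariance <- match.arg(covariance)
  stopIfNot(is(fit, "GPFit"), "'fit' must be a GPFit")
  tt <- fit@trainTimes
  stopIfNot(length(x) == length(tt),
            "profile length %d does not match %d observed time points",
            length(x), length(tt))
  C <- (if (covariance == "posterior") fit@covObs
        else rbfMatrix(tt, tt, fit@lengthScale)) +
    diag(fit@noiseSd^2, length(tt))
  ch <- tryCatch(chol(C), error = function(e)
    stop("singular covariance: duplicated times with a zero noise floor; ",
         "increase 'noiseBounds[1]'"))
  r <- x - fit@muObs
  alpha <- backsolve(ch, forwardsolve(t(ch), r))
  -0.5 * sum(r * alpha) - sum(log(diag(ch))) -
    0.5 * length(x) * log(2 * pi)
}
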