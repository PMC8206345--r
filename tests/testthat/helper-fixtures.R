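# Shared fixture builders; everything is generated in code.

# Small expression object: nGenes x (times x nRep), optionally with planted
# row patterns supplied as a function(time) per gene index.
makeTse <- function(nGenes = 4, times = 0:4, nRep = 1, seed = 1,
                    noise = 0.1, pattern = function(i, t) sin(t + i)) {
  set.seed(seed)
  colTimes <- rep(times, each = nRep)
  m <- t(vapply(seq_len(nGenes),
                function(i) pattern(i, colTimes) +
                  rnorm(length(colTimes), sd = noise),
                numeric(length(colTimes))))
  rownames(m) <- sprintf("g%02d", seq_len(nGenes))
  TimeSeriesExperiment(m, times = times, nRep = nRep)
}

# Brute-force pair-sum within-cluster dispersion (Eq. W_k pair route):
# sum over clusters of (1 / 2 n_r) * sum of squared distances of all
# ordered pairs.
pairSumDispersion <- function(X, labels) {
  total <- 0
  for (r in unique(labels)) {
    idx <- which(labels == r)
    sub <- X[idx, , drop = FALSE]
    D <- 0
    for (i in seq_len(nrow(sub)))
      for (j in seq_len(nrow(sub)))
        D <- D + sum((sub[i, ] - sub[j, ])^2)
    total <- total + D / (2 * length(idx))
  }
  total
}

# Independent normalised cross-correlation oracle: explicit zero-padded
# vectors, one shift at a time.
sbdOracle <- function(a, b) {
  m <- length(a)
  shifts <- (1 - m):(m - 1)
  pad <- function(x, w) {
    # shift x left by w with zero padding, aligned to b's frame
    out <- numeric(m)
    for (i in seq_len(m)) {
      src <- i + w
      if (src >= 1 && src <= m) out[i] <- x[src]
    }
    out
  }
  ncc <- sapply(shifts, function(w) sum(pad(a, w) * b)) /
    sqrt(sum(a^2) * sum(b^2))
  list(shifts = shifts, ncc = ncc, sbd = 1 - max(ncc))
}

# Exhaustive hypergeometric upper tail: enumerate every possible draw of
# `drawn` genes out of `total` and count draws with >= q pathway genes.
hyperTailEnum <- function(total, white, drawn, q) {
  draws <- combn(total, drawn)
  isWhite <- seq_len(total) <= white
  hits <- apply(draws, 2, function(d) sum(isWhite[d]) >= q)
  mean(hits)
}

# O(n^2) pair-confusion oracle by explicit pair enumeration.
pairConfusionOracle <- function(truth, pred) {
  n <- length(truth)
  TP <- FP <- FN <- TN <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    st <- truth[i] == truth[j]; sp <- pred[i] == pred[j]
    if (st && sp) TP <- TP + 1
    else if (!st && sp) FP <- FP + 1
    else if (st && !sp) FN <- FN + 1
    else TN <- TN + 1
  }
  list(TP = TP, FP = FP, FN = FN, TN = TN)
}
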