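#' Pair confusion counts between two labelings
#'
#' Over all unordered pairs of genes: a pair co-clustered in both the truth
#' and the prediction is a true positive; co-clustered only in the
#' prediction, a false positive; only in the truth, a false negative;
#' in neither, a true negative. Computed in closed form from the
#' contingency table.
#'
#' @param truth,pred label vectors over the same genes (any atomic type).
#' @return list with integer-valued `TP`, `FP`, `FN`, `TN`; they always sum
#'   to `choose(n, 2)`.
#' @export
pairConfusion <- function(truth, pred) {
  stopIfNot(length(truth) == length(pred),
            "labelings must cover the same genes")
  n <- length(truth)
  tab <- table(truth, pred)
  TP <- sum(choose(tab, 2))
  samePred <- sum(choose(colSums(tab), 2))
  sameTruth <- sum(choose(rowSums(tab), 2))
  total <- choose(n, 2)
  list(TP = TP, FP = samePred - TP, FN = sameTruth - TP,
       TN = total - samePred - sameTruth + TP)
}

#' Pair-based F1 score of a clustering
#'
#' Harmonic mean of pair precision and recall computed from
#' [pairConfusion()]; invariant to cluster relabeling. Returns 0 when
#' precision and recall are both undefined or zero.
#'
#' @param truth,pred label vectors over the same genes.
#' @return numeric(1) in \[0, 1\].
#' @export
pairF1 <- function(truth, pred) {
  pc <- pairConfusion(truth, pred)
  prec <- if (pc$TP + pc$FP > 0) pc$TP / (pc$TP + pc$FP) else 0
  rec <- if (pc$TP + pc$FN > 0) pc$TP / (pc$TP + pc$FN) else 0
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

#' Rand index and adjusted Rand index
#'
#' `randIndex` is the fraction of gene pairs on which the two labelings
#' agree. `adjustedRand` corrects it for chance under the permutation
#' model, \eqn{ARI = (RI - E[RI]) / (1 - E[RI])}, evaluated through the
#' standard pair-count form; random labelings score near 0, identical
#' labelings exactly 1.
#'
#' @param truth,pred label vectors over the same genes.
#' @return numeric(1).
#' @export
randIndex <- function(truth, pred) {
  pc <- pairConfusion(truth, pred)
  (pc$TP + pc$TN) / (pc$TP + pc$FP + pc$FN + pc$TN)
}

#' @rdname randIndex
#' @export
adjustedRand <- function(truth, pred) {
  pc <- pairConfusion(truth, pred)
  n2 <- pc$TP + pc$FP + pc$FN + pc$TN
  sumT <- pc$TP + pc$FN       # co-clustered pairs in truth
  sumP <- pc$TP + pc$FP       # co-clustered pairs in prediction
  expected <- sumT * sumP / n2
  maxIndex <- (sumT + sumP) / 2
  if (maxIndex == expected) return(1)      # degenerate: single cluster both
  (pc$TP - expected) / (maxIndex - expected)
}

#' Mean silhouette score of a clustering
#'
#' For each gene, `a(i)` is its mean Euclidean distance to co-clustered
#' genes and `b(i)` the smallest mean distance to any other cluster;
#' \eqn{s(i) = (b(i) - a(i)) / \max(a(i), b(i))}. Genes in singleton
#' clusters score 0 by convention. Distances are taken between
#' replicate-averaged profiles.
#'
#' @param m a [TimeSeriesExperiment-class] or genes x time-points matrix.
#' @param pred label vector, one per gene; at least 2 clusters.
#' @return numeric(1), the mean silhouette over all genes.
#' @export
silhouetteScore <- function(m, pred) {
  X <- if (is(m, "TimeSeriesExperiment"))
    exprsMatrix(averageReplicates(m)) else as.matrix(m)
  stopIfNot(length(pred) == nrow(X), "need one label per gene")
  ids <- unique(pred)
  stopIfNot(length(ids) >= 2L, "silhouette requires at least 2 clusters")
  D <- as.matrix(stats::dist(X))
  s <- vapply(seq_len(nrow(X)), function(i) {
    own <- which(pred == pred[i])
    if (length(own) == 1L) return(0)       # singleton convention
    a <- sum(D[i, own]) / (length(own) - 1L)
    b <- min(vapply(setdiff(ids, pred[i]), function(cl)
      mean(D[i, pred == cl]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Completeness of a clustering against reference classes
#'
#' Entropy-based score of whether all members of each truth class land in
#' the same predicted cluster:
#' \eqn{1 - H(pred \mid truth) / H(pred)}, with natural-log entropies
#' (the base cancels). Defined as 1 when the prediction has zero entropy.
#'
#' @param truth,pred label vectors over the same genes.
#' @return numeric(1) in \[0, 1\].
#' @export
completenessScore <- function(truth, pred) {
  stopIfNot(length(truth) == length(pred),
            "labelings must cover the same genes")
  n <- length(truth)
  tab <- table(truth, pred)
  pPred <- colSums(tab) / n
  hPred <- -sum(ifelse(pPred > 0, pPred * log(pPred), 0))
  if (hPred == 0) return(1)
  joint <- tab / n
  pTruth <- rowSums(tab) / n
  hCond <- -sum(ifelse(joint > 0,
                       joint * log(sweep(joint, 1L, pTruth, "/")), 0))
  1 - hCond / hPred
}

#' Number of predefined short-time-series profiles
#'
#' Profile-enumeration clustering of short series predefines
#' \eqn{3^{N-1} - 1} candidate expression profiles for `N` time points
#' (each step up/constant/down relative to the previous point, excluding
#' the all-constant profile).
#'
#' @param nTimePoints integer(1), number of time points, at least 2.
#' @return numeric(1), the exact profile count.
#' @examples
#' stemProfileCount(8)  # 2186
#' @export
stemProfileCount <- function(nTimePoints) {
  stopIfNot(length(nTimePoints) == 1L &&
              nTimePoints == floor(nTimePoints) && nTimePoints >= 2,
            "'nTimePoints' must be an integer >= 2")
  3^(nTimePoints - 1) - 1
}
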