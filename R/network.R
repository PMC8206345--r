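#' Shape-based distance between two cluster mean curves
#'
#' Slides one series over the other across every integer shift
#' \eqn{w \in [1-m, m-1]} (out-of-range positions zero-padded), computes the
#' cross-correlation \eqn{CC_w(a, b) = \sum_i a_{i+w}\, b_i}, normalises by
#' the zero-shift autocorrelations
#' \eqn{\sqrt{CC_0(a,a)\, CC_0(b,b)}}, and returns
#' \deqn{SBD(a, b) = 1 - \max_w NCC_w} together with the maximising shift.
#' A negative optimal shift means `a` precedes `b` (series `b` is a delayed
#' copy of `a`); a positive shift the reverse; zero is a tie. Exact ties in
#' the maximal correlation are broken towards the smallest `|w|`, then the
#' negative shift.
#'
#' @param a,b numeric vectors of equal length `m >= 2` (cluster GP means on
#'   the interpolation grid).
#' @return A list of class `"SBDResult"` with elements `sbd` (in
#'   \[0, 2\]), `w` (integer shift), `direction` (`"a_before_b"`,
#'   `"b_before_a"` or `"tie"`) and `ncc` (the normalised
#'   cross-correlation profile, named by shift).
#' @examples
#' a <- c(0, 0, 1, 0, 0, 0, 0, 0)
#' b <- c(0, 0, 0, 0, 1, 0, 0, 0)  # a delayed by 2 -> a precedes b
#' shapeBasedDistance(a, b)$w
#' @export
shapeBasedDistance <- function(a, b) {
  m <- length(a)
  stopIfNot(length(b) == m, "series lengths differ (%d vs %d)",
            m, length(b))
  stopIfNot(m >= 2L, "series must have length >= 2")
  stopIfNot(all(is.finite(a)) && all(is.finite(b)),
            "series must be finite")
  na2 <- sum(a^2); nb2 <- sum(b^2)
  if (na2 == 0 || nb2 == 0)
    stop("degenerate cluster mean: zero-norm series")
  shifts <- seq(1L - m, m - 1L)
  cc <- vapply(shifts, function(w) {
    i <- seq_len(m)
    ia <- i + w
    ok <- ia >= 1L & ia <= m
    sum(a[ia[ok]] * b[i[ok]])
  }, numeric(1))
  ncc <- cc / sqrt(na2 * nb2)
  best <- max(ncc)
  cand <- which(ncc >= best - 1e-12)
  cand <- cand[order(abs(shifts[cand]), shifts[cand])]
  w <- shifts[cand[1L]]
  structure(list(
    sbd = 1 - best,
    w = as.integer(w),
    direction = if (w < 0) "a_before_b" else if (w > 0) "b_before_a"
                else "tie",
    ncc = stats::setNames(ncc, shifts)), class = "SBDResult")
}

#' Pairwise temporal orders between all cluster pairs
#'
#' Computes [shapeBasedDistance()] between the GP mean curves of every
#' unordered pair of clusters, yielding the cluster-cluster distance, the
#' optimal shift and the implied direction for each pair.
#'
#' @param fits named list of [GPFit-class] objects (names are cluster ids)
#'   or a clusters x grid-points matrix of mean curves with cluster ids as
#'   rownames.
#' @return data.frame with columns `a`, `b` (cluster ids, `a < b`), `sbd`,
#'   `w` and `direction`.
#' @export
pairwiseOrders <- function(fits) {
  means <- if (is.matrix(fits)) {
    stopIfNot(!is.null(rownames(fits)), "cluster ids (rownames) required")
    fits
  } else {
    stopIfNot(length(fits) >= 2L && !is.null(names(fits)),
              "a named list of >= 2 GPFit objects is required")
    do.call(rbind, lapply(fits, function(f) f@mean))
  }
  ids <- rownames(means)
  stopIfNot(nrow(means) >= 2L, "at least 2 clusters are required")
  pairs <- utils::combn(seq_len(nrow(means)), 2L)
  res <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    s <- shapeBasedDistance(means[i, ], means[j, ])
    data.frame(a = ids[i], b = ids[j], sbd = s$sbd, w = s$w,
               direction = s$direction, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Order clusters by the ranked-pairs (Tideman) algorithm
#'
#' Treats each directed pairwise comparison as a victory of the earlier
#' cluster over the later one with strength `1 - sbd`, sorts victories by
#' decreasing strength (ties: larger `|w|` first, then lexicographic
#' cluster ids), locks each in turn into a directed graph unless it would
#' create a cycle, and returns a topological order of the locked graph.
#' Pairs with zero optimal shift carry no direction and abstain. Remaining
#' ambiguities in the topological order are broken towards the
#' lexicographically smaller cluster id, so the result is deterministic.
#'
#' @param pairs data.frame as returned by [pairwiseOrders()].
#' @return character vector of cluster ids in inferred temporal order.
#' @examples
#' p <- data.frame(a = c("1", "2", "1"), b = c("2", "3", "3"),
#'                 sbd = c(0.1, 0.2, 0.3), w = c(-1L, -1L, -2L),
#'                 direction = "a_before_b")
#' rankedPairsOrder(p)
#' @export
rankedPairsOrder <- function(pairs) {
  stopIfNot(nrow(pairs) >= 1L, "at least one pair is required")
  ids <- sort(unique(c(pairs$a, pairs$b)))
  directed <- pairs[pairs$direction != "tie", , drop = FALSE]
  if (nrow(directed) == 0L)
    stop("no ordering signal: all pairwise shifts are zero")
  winner <- ifelse(directed$direction == "a_before_b",
                   directed$a, directed$b)
  loser <- ifelse(directed$direction == "a_before_b",
                  directed$b, directed$a)
  strength <- 1 - directed$sbd
  ord <- order(-strength, -abs(directed$w), winner, loser)
  winner <- winner[ord]; loser <- loser[ord]

  adj <- stats::setNames(vector("list", length(ids)), ids)
  reaches <- function(from, to) {
    seen <- character(); stack <- from
    while (length(stack)) {
      v <- stack[[1L]]; stack <- stack[-1L]
      if (v == to) return(TRUE)
      if (v %in% seen) next
      seen <- c(seen, v)
      stack <- c(adj[[v]], stack)
    }
    FALSE
  }
  for (e in seq_along(winner)) {
    if (!reaches(loser[e], winner[e]))       # lock unless it closes a cycle
      adj[[winner[e]]] <- union(adj[[winner[e]]], loser[e])
  }
  # Kahn topological sort, smallest id first among available nodes
  indeg <- stats::setNames(integer(length(ids)), ids)
  for (v in ids) for (u in adj[[v]]) indeg[u] <- indeg[u] + 1L
  out <- character()
  avail <- sort(ids[indeg == 0L])
  while (length(avail)) {
    v <- avail[1L]; avail <- avail[-1L]
    out <- c(out, v)
    for (u in adj[[v]]) {
      indeg[u] <- indeg[u] - 1L
      if (indeg[u] == 0L) avail <- sort(c(avail, u))
    }
  }
  out
}

#' Assemble the directed cluster network
#'
#' Builds the path graph over clusters in the given temporal order. Each
#' node carries its member genes and the GP posterior mean with a 95%
#' confidence band (mean ± 1.96 sd) on the interpolation grid; each
#' consecutive edge carries its two-group pathway annotations.
#'
#' @param labels named integer/character vector, gene -> cluster id.
#' @param fits named list of [GPFit-class] objects, one per cluster.
#' @param order vector of cluster ids in temporal order; must cover exactly
#'   the clusters present in `labels`.
#' @param annotations optional list of per-edge annotation data.frames (as
#'   from [edgeAnnotations()]), one per consecutive pair in `order`.
#' @return A [ClusterNetwork-class] object with `k - 1` edges.
#' @export
buildNetwork <- function(labels, fits, order, annotations = NULL) {
  order <- as.character(order)
  present <- sort(unique(as.character(labels)))
  if (!identical(sort(order), present))
    stop("'order' does not match the clusters in 'labels'")
  nodes <- lapply(order, function(cl) {
    f <- fits[[cl]]
    stopIfNot(!is.null(f), "missing GP fit for cluster %s", cl)
    list(cluster = cl,
         genes = names(labels)[as.character(labels) == cl],
         grid = f@grid, mean = f@mean, sd = f@sd,
         ciLower = f@mean - 1.96 * f@sd,
         ciUpper = f@mean + 1.96 * f@sd)
  })
  k <- length(order)
  edges <- if (k >= 2L) {
    lapply(seq_len(k - 1L), function(i) {
      ann <- if (!is.null(annotations) && length(annotations) >= i)
        annotations[[i]] else emptyAnnotations()
      list(from = order[i], to = order[i + 1L], annotations = ann)
    })
  } else list()
  ordInt <- suppressWarnings(as.integer(order))
  if (anyNA(ordInt)) ordInt <- seq_along(order)   # non-numeric cluster ids
  new("ClusterNetwork", order = ordInt, nodes = nodes, edges = edges)
}

emptyAnnotations <- function() {
  data.frame(pathway = character(), tailFrom = numeric(),
             tailTo = numeric(), tailUnion = numeric(),
             stringsAsFactors = FALSE)
}

#' Infer a cell-state network from a clustering
#'
#' Convenience pipeline over one clustering: fits a GP per cluster, derives
#' all pairwise shape-based orders, resolves them into a single temporal
#' order with ranked pairs, annotates consecutive edges with the two-group
#' pathway test (when gene sets are supplied) and assembles the
#' [ClusterNetwork-class].
#'
#' @param m a [TimeSeriesExperiment-class] of normalized profiles.
#' @param labels named integer vector, gene -> cluster (e.g. from
#'   [clusterLabels()]).
#' @param geneSets optional named list of pathway gene-id vectors (see
#'   [readGMT()]).
#' @param seed integer(1), seed for the GP restarts.
#' @param minPathwaySize integer(1), pathways with at most this many genes
#'   in the universe are skipped by edge annotation (default 10).
#' @param ... further arguments to [fitClusterGP()].
#' @return A [ClusterNetwork-class] object.
#' @export
buildClusterNetwork <- function(m, labels, geneSets = NULL, seed = 1L,
                                minPathwaySize = 10L, ...) {
  stopIfNot(is(m, "TimeSeriesExperiment"),
            "'m' must be a TimeSeriesExperiment")
  labels <- labels[rownames(m)]
  stopIfNot(!anyNA(labels), "labels must cover every gene in 'm'")
  w <- gpDispersion(m, labels, seed = seed, ...)
  fits <- attr(w, "fits")
  order <- if (length(fits) == 1L) names(fits)
           else rankedPairsOrder(pairwiseOrders(fits))
  annotations <- NULL
  if (!is.null(geneSets) && length(order) >= 2L) {
    universe <- rownames(m)
    annotations <- lapply(seq_len(length(order) - 1L), function(i) {
      gi <- names(labels)[as.character(labels) == order[i]]
      gj <- names(labels)[as.character(labels) == order[i + 1L]]
      edgeAnnotations(gi, gj, geneSets, universe,
                      minPathwaySize = minPathwaySize)
    })
  }
  buildNetwork(labels, fits, order, annotations)
}
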