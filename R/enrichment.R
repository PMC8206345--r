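#' Upper-tail hypergeometric probability
#'
#' Probability of observing at least `q` pathway genes in a cluster of
#' size `drawn` when `white` of the `total` universe genes belong to the
#' pathway:
#' \deqn{P(X \ge q) = \sum_{x=q}^{\min(white,\,drawn)}
#'   \frac{\binom{white}{x}\binom{total-white}{drawn-x}}
#'        {\binom{total}{drawn}}.}
#' Computed through `stats::phyper` (log-gamma based, exact to double
#' precision).
#'
#' @param total integer(1), universe size N.
#' @param white integer(1), pathway genes in the universe.
#' @param drawn integer(1), cluster size.
#' @param q integer(1), observed pathway genes in the cluster.
#' @return numeric(1) in (0, 1]; equals 1 when `q == 0`.
#' @examples
#' hypergeomTail(10, 5, 4, 4)  # 5/210
#' @export
hypergeomTail <- function(total, white, drawn, q) {
  stopIfNot(all(c(total, white, drawn, q) == floor(c(total, white, drawn, q))),
            "arguments must be integers")
  stopIfNot(q >= 0 && q <= drawn && drawn <= total && white <= total &&
              white >= 0, "invalid hypergeometric arguments")
  stats::phyper(q - 1, white, total - white, drawn, lower.tail = FALSE)
}

#' Filter clusters by enrichment in a pathway of interest
#'
#' Keeps only the clusters significantly enriched in the given pathway
#' (hypergeometric upper tail at most `threshold`); discarded clusters are
#' reported in a message with their p-values. The gene universe is the set
#' of clustered genes.
#'
#' @param labels named integer vector, gene -> cluster.
#' @param geneSets named list of pathway gene-id vectors.
#' @param pathway character(1), id of the pathway of interest.
#' @param threshold numeric(1), p-value cutoff (default 0.1).
#' @return The subset of `labels` belonging to enriched clusters, with the
#'   per-cluster p-value table attached as attribute `"pvalues"`.
#' @export
filterClusters <- function(labels, geneSets, pathway, threshold = 0.1) {
  if (!pathway %in% names(geneSets))
    stop(sprintf("unknown pathway id '%s'", pathway))
  universe <- names(labels)
  pGenes <- intersect(geneSets[[pathway]], universe)
  ids <- sort(unique(labels))
  pv <- vapply(ids, function(cl) {
    genes <- universe[labels == cl]
    hypergeomTail(length(universe), length(pGenes), length(genes),
                  length(intersect(genes, pGenes)))
  }, numeric(1))
  keep <- ids[pv <= threshold]
  dropped <- ids[pv > threshold]
  if (length(dropped))
    message(sprintf(
      "filtered out cluster(s) %s (p = %s) not enriched in %s",
      paste(dropped, collapse = ", "),
      paste(signif(pv[pv > threshold], 3), collapse = ", "), pathway))
  out <- labels[labels %in% keep]
  attr(out, "pvalues") <- data.frame(cluster = ids, p = pv,
                                     kept = ids %in% keep)
  out
}

#' Two-group pathway annotations for a network edge
#'
#' A pathway is assigned to the edge between two adjacent clusters when
#' merging the clusters makes the enrichment strictly appear: the
#' hypergeometric tail of the union is at most 0.05 while each single
#' cluster's tail exceeds 0.05, and the pathway has more than
#' `minPathwaySize` genes in the universe. Such a pathway is shared across
#' the state transition although neither state alone is enriched.
#'
#' @param genesI,genesJ character vectors, the (disjoint) gene sets of the
#'   two clusters.
#' @param geneSets named list of pathway gene-id vectors.
#' @param universe character vector of all analysed genes; pathway genes
#'   outside it are ignored.
#' @param alpha numeric(1), significance level of the criterion
#'   (default 0.05).
#' @param minPathwaySize integer(1); pathways with at most this many genes
#'   in the universe are skipped (default 10).
#' @return data.frame with one row per annotated pathway: `pathway`,
#'   `tailFrom`, `tailTo`, `tailUnion`.
#' @export
edgeAnnotations <- function(genesI, genesJ, geneSets, universe,
                            alpha = 0.05, minPathwaySize = 10L) {
  if (length(intersect(genesI, genesJ)))
    stop("cluster gene sets overlap; clusters must partition the genes")
  N <- length(universe)
  rows <- lapply(names(geneSets), function(p) {
    pg <- intersect(geneSets[[p]], universe)
    if (length(pg) <= minPathwaySize) return(NULL)
    ti <- hypergeomTail(N, length(pg), length(genesI),
                        length(intersect(genesI, pg)))
    tj <- hypergeomTail(N, length(pg), length(genesJ),
                        length(intersect(genesJ, pg)))
    un <- union(genesI, genesJ)
    tu <- hypergeomTail(N, length(pg), length(un),
                        length(intersect(un, pg)))
    if (tu <= alpha && alpha < min(ti, tj))
      data.frame(pathway = p, tailFrom = ti, tailTo = tj, tailUnion = tu,
                 stringsAsFactors = FALSE)
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) emptyAnnotations() else out
}
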