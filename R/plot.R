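#' Plot cluster GP summaries
#'
#' One panel per state, in network order: posterior mean (solid line) with
#' the 95% confidence band (shaded), over the interpolation grid.
#'
#' @param network a [ClusterNetwork-class].
#' @param col line colour.
#' @param band band colour.
#' @param ... further arguments to `plot`.
#' @return invisibly, `NULL`.
#' @export
plotClusterFits <- function(network, col = "red3",
                            band = grDevices::adjustcolor("red3", 0.25),
                            ...) {
  nodes <- networkNodes(network)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(nodes)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (nd in nodes) {
    ylim <- range(nd$ciLower, nd$ciUpper)
    plot(nd$grid, nd$mean, type = "n", ylim = ylim, xlab = "time",
         ylab = "expression (z)",
         main = sprintf("state %s (%d genes)", nd$cluster,
                        length(nd$genes)), ...)
    graphics::polygon(c(nd$grid, rev(nd$grid)),
                      c(nd$ciLower, rev(nd$ciUpper)),
                      col = band, border = NA)
    graphics::lines(nd$grid, nd$mean, col = col, lwd = 2)
  }
  invisible(NULL)
}

#' Plot the ordered state network
#'
#' Draws the directed path of states left to right; edges are labelled
#' with their annotated pathways.
#'
#' @param network a [ClusterNetwork-class].
#' @param ... further arguments to `plot.igraph`.
#' @return invisibly, `NULL`.
#' @export
plotStateNetwork <- function(network, ...) {
  nodes <- networkNodes(network)
  g <- igraph::make_empty_graph(n = length(nodes), directed = TRUE)
  igraph::V(g)$name <- vapply(nodes, `[[`, character(1), "cluster")
  for (e in networkEdges(network)) g <- igraph::add_edges(g, c(e$from, e$to))
  elab <- vapply(networkEdges(network), function(e)
    paste(e$annotations$pathway, collapse = "\n"), character(1))
  lay <- cbind(seq_along(nodes), 0)
  plot(g, layout = lay, edge.label = if (length(elab)) elab else NULL,
       vertex.size = 30, vertex.color = "grey90", ...)
  invisible(NULL)
}
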