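#' Read a delimited expression matrix into a TimeSeriesExperiment
#'
#' The file must be delimited text with gene ids in the first column and
#' one measurement per remaining column. The column-to-(time, replicate)
#' mapping is declared by `times`/`nRep` (never inferred from headers) and
#' recorded in the object, so it is reversible.
#'
#' @param path file path (TSV by default; `.csv` switches to commas, or
#'   pass `sep`).
#' @param times numeric vector: one time per data column, or the distinct
#'   time grid combined with `nRep` (columns then time-major:
#'   t1 r1, t1 r2, ..., t2 r1, ...).
#' @param nRep integer(1), replicates per time point.
#' @param sep field separator; default from the file extension.
#' @param interpolationStep numeric(1), grid step stored on the object.
#' @param header logical(1), whether the file has a header row.
#' @return A [TimeSeriesExperiment-class].
#' @export
readExpression <- function(path, times, nRep = 1L, sep = NULL,
                           interpolationStep = 1, header = TRUE) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = header, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  stopIfNot(ncol(df) >= 2L, "expected gene ids plus >= 1 data column")
  ids <- df[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop(sprintf("duplicated gene id(s): %s", paste(dup, collapse = ", ")))
  raw <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  isNA <- is.na(raw) | toupper(trimws(raw)) %in% c("NA", "NAN", "")
  bad <- which(is.na(num) & !isNA, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(
      "non-numeric value '%s' for gene '%s' in data column %d",
      raw[bad[1L, , drop = FALSE]], ids[bad[1L, 1L]], bad[1L, 2L]))
  rownames(num) <- ids
  tse <- TimeSeriesExperiment(num, times = times, nRep = nRep,
                              interpolationStep = interpolationStep)
  S4Vectors::metadata(tse)$columnMapping <- data.frame(
    column = if (header) colnames(df)[-1L] else
      paste0("V", seq_len(ncol(num))),
    time = SummarizedExperiment::colData(tse)$time,
    replicate = SummarizedExperiment::colData(tse)$replicate)
  tse
}

#' Write a TimeSeriesExperiment as delimited text
#'
#' @param x a [TimeSeriesExperiment-class].
#' @param path output path (`.csv` for commas, TSV otherwise).
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  cd <- SummarizedExperiment::colData(x)
  m <- exprsMatrix(x)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  colnames(df)[-1L] <- sprintf("t%g_r%d", cd$time, cd$replicate)
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated id, description,
#' then gene ids. Empty lines are skipped; sets may overlap.
#'
#' @param path file path.
#' @return Named list of character vectors (gene ids per set), with set
#'   descriptions in attribute `"description"`.
#' @export
readGMT <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  sets <- list(); desc <- character()
  for (i in keep) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need id, description and >= 1 gene",
                   i, length(fields)))
    sets[[fields[1L]]] <- unique(fields[-(1:2)])
    desc[fields[1L]] <- fields[2L]
  }
  structure(sets, description = desc)
}

#' Serialize a cluster network
#'
#' JSON is the canonical, lossless format ([readNetwork()] round-trips it);
#' GraphML and DOT exports are provided for graph tooling, with per-node
#' curve summaries JSON-encoded into attributes.
#'
#' @param network a [ClusterNetwork-class].
#' @param path output path.
#' @param format `"json"`, `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(network, path,
                         format = c("json", "graphml", "dot")) {
  format <- match.arg(format)
  stopIfNot(is(network, "ClusterNetwork"),
            "'network' must be a ClusterNetwork")
  methods::validObject(network)
  if (format == "json") {
    obj <- list(
      order = network@order,
      nodes = lapply(network@nodes, function(nd) list(
        cluster = nd$cluster, genes = as.list(nd$genes), grid = nd$grid,
        mean = nd$mean, sd = nd$sd, ciLower = nd$ciLower,
        ciUpper = nd$ciUpper)),
      edges = lapply(network@edges, function(e) list(
        from = e$from, to = e$to,
        annotations = lapply(seq_len(nrow(e$annotations)), function(i)
          as.list(e$annotations[i, ])))))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(path))
  }
  g <- igraph::make_empty_graph(n = length(network@nodes), directed = TRUE)
  igraph::V(g)$name <- vapply(network@nodes, `[[`, character(1), "cluster")
  igraph::V(g)$genes <- vapply(network@nodes, function(nd)
    paste(nd$genes, collapse = ";"), character(1))
  igraph::V(g)$curve <- vapply(network@nodes, function(nd)
    as.character(jsonlite::toJSON(list(grid = nd$grid, mean = nd$mean,
                                       sd = nd$sd), digits = NA)),
    character(1))
  for (e in network@edges) {
    g <- igraph::add_edges(g, c(e$from, e$to))
  }
  if (length(network@edges))
    igraph::E(g)$pathways <- vapply(network@edges, function(e)
      paste(e$annotations$pathway, collapse = ";"), character(1))
  igraph::write_graph(g, path,
                      format = if (format == "graphml") "graphml" else "dot")
  invisible(path)
}

#' Read a JSON cluster network
#'
#' @param path path to a JSON file written by [writeNetwork()].
#' @return A [ClusterNetwork-class].
#' @export
readNetwork <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  nodes <- lapply(obj$nodes, function(nd) list(
    cluster = as.character(nd$cluster),
    genes = as.character(unlist(nd$genes)),
    grid = as.numeric(unlist(nd$grid)),
    mean = as.numeric(unlist(nd$mean)),
    sd = as.numeric(unlist(nd$sd)),
    ciLower = as.numeric(unlist(nd$ciLower)),
    ciUpper = as.numeric(unlist(nd$ciUpper))))
  edges <- lapply(obj$edges, function(e) {
    ann <- if (length(e$annotations)) {
      do.call(rbind, lapply(e$annotations, function(a)
        data.frame(pathway = a$pathway, tailFrom = a$tailFrom,
                   tailTo = a$tailTo, tailUnion = a$tailUnion,
                   stringsAsFactors = FALSE)))
    } else emptyAnnotations()
    list(from = as.character(e$from), to = as.character(e$to),
         annotations = ann)
  })
  new("ClusterNetwork", order = as.integer(unlist(obj$order)),
      nodes = nodes, edges = edges)
}
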