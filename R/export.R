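#' Convert a CLAW graph to an igraph object
#'
#' Retained edges become directed edges with a \code{probability}
#' attribute; vertices carry the end probability and, when state statistics
#' are attached, the mean decision time (used as the node colour attribute
#' in DOT/GraphML exports).
#'
#' @param graph A \linkS4class{ClawGraph}.
#' @return An \code{igraph} directed graph.
#' @export
asIgraph <- function(graph) {
  edges <- clawEdges(graph)
  verts <- data.frame(name = as.character(clawStates(graph)))
  verts$end_probability <- graph@ends$probability[
    match(as.integer(verts$name), graph@ends$state)]
  verts$end_probability[is.na(verts$end_probability)] <- 0
  if (nrow(graph@stats)) {
    idx <- match(as.integer(verts$name), graph@stats$state)
    verts$mean_dt_ms <- graph@stats$mean_dt_ms[idx]
  }
  igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$from), to = as.character(edges$to),
               probability = edges$probability),
    directed = TRUE, vertices = verts)
}

#' Export a CLAW graph or zone partition to file
#'
#' JSON export is lossless (counts, probabilities, retained flags, end
#' probabilities, statistics) and round-trips through
#' \code{\link{importGraph}}; GraphML and DOT exports contain the retained
#' edges with probabilities as edge attributes.
#'
#' @param x A \linkS4class{ClawGraph} or \linkS4class{ZonePartition}.
#' @param file Output path.
#' @param format "json", "graphml" or "dot".
#' @return \code{file}, invisibly.
#' @export
exportGraph <- function(x, file, format = c("json", "graphml", "dot")) {
  format <- match.arg(format)
  if (is(x, "ZonePartition")) {
    if (format != "json")
      stop("zone partitions are exported as JSON only")
    jsonlite::write_json(list(kind = "ZonePartition",
                              map = as.list(x@map),
                              zoneEdges = x@zoneEdges,
                              zoneStay = x@zoneStay,
                              activation = x@activation),
                         file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(file))
  }
  if (!is(x, "ClawGraph")) stop("unsupported object")
  if (nrow(x@edges) == 0L && nrow(x@ends) == 0L) stop("graph is empty")
  if (format == "json") {
    jsonlite::write_json(list(kind = "ClawGraph", mode = x@mode, gap = x@gap,
                              edges = x@edges, ends = x@ends,
                              stats = x@stats),
                         file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    g <- asIgraph(x)
    igraph::write_graph(g, file, format = format)
  }
  invisible(file)
}

#' Import a CLAW graph or zone partition from JSON
#'
#' @param file Path written by \code{\link{exportGraph}}.
#' @return The reconstructed object.
#' @export
importGraph <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (identical(obj$kind, "ClawGraph")) {
    stats <- as.data.frame(obj$stats)
    return(new("ClawGraph", edges = as.data.frame(obj$edges),
               ends = as.data.frame(obj$ends), stats = stats,
               mode = obj$mode, gap = obj$gap))
  }
  if (identical(obj$kind, "ZonePartition")) {
    return(new("ZonePartition", map = unlist(obj$map),
               zoneEdges = as.data.frame(obj$zoneEdges),
               zoneStay = as.data.frame(obj$zoneStay),
               activation = as.data.frame(obj$activation)))
  }
  stop("unknown graph file kind")
}
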