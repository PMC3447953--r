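# Network import/export: GraphML (via igraph) and plain edge/node CSV.

#' Convert an SCN network to an igraph object
#'
#' @param network an `scn_network`.
#' @param weighted attach edge weights (`TRUE`) or treat all edges as unit.
#' @return An undirected `igraph` graph with vertex attributes `x`, `y`,
#'   `region`, `rhythmic` and edge attributes `weight`, `class`.
#' @export
as_igraph <- function(network, weighted = TRUE) {
  g <- igraph::graph_from_data_frame(
    d = network$edges[, c("i", "j", "weight", "class")],
    directed = FALSE,
    vertices = network$cells[, c("id", "x", "y", "region", "rhythmic")])
  if (!weighted) g <- igraph::delete_edge_attr(g, "weight")
  g
}

#' Write / read an SCN network as GraphML
#'
#' Positions, region labels, rhythmicity flags, edge weights and edge classes
#' are stored as GraphML attributes; the round trip is lossless.
#'
#' @param network an `scn_network`.
#' @param path file path.
#' @return `read_network_graphml()` returns an `scn_network` (without a
#'   construction `config`, which is not part of the on-disk format).
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  v <- igraph::as_data_frame(g, what = "vertices")
  e <- igraph::as_data_frame(g, what = "edges")
  cells <- data.frame(id = as.integer(v$name), x = v$x, y = v$y,
                      region = v$region, rhythmic = as.logical(v$rhythmic))
  o <- order(cells$id)
  cells <- cells[o, , drop = FALSE]
  rownames(cells) <- NULL
  edges <- data.frame(i = as.integer(e$from), j = as.integer(e$to),
                      weight = e$weight, class = e$class)
  ij <- cbind(pmin(edges$i, edges$j), pmax(edges$i, edges$j))
  edges$i <- ij[, 1L]; edges$j <- ij[, 2L]
  edges <- edges[order(edges$class != "short", edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  net <- structure(list(cells = cells, edges = edges, N = nrow(cells),
                        config = NULL),
                   class = "scn_network")
  net$degree <- network_degree(net)
  net
}

#' Write / read an SCN network as plain CSV
#'
#' Two files are written: `<stem>_nodes.csv` (`id, x, y, region, rhythmic`)
#' and `<stem>_edges.csv` (`i, j, weight, class`).
#'
#' @param network an `scn_network`.
#' @param stem path stem (without extension).
#' @return `read_network_csv()` returns an `scn_network`.
#' @export
write_network_csv <- function(network, stem) {
  utils::write.csv(network$cells, paste0(stem, "_nodes.csv"),
                   row.names = FALSE)
  utils::write.csv(network$edges, paste0(stem, "_edges.csv"),
                   row.names = FALSE)
  invisible(paste0(stem, c("_nodes.csv", "_edges.csv")))
}

#' @rdname write_network_csv
#' @export
read_network_csv <- function(stem) {
  cells <- utils::read.csv(paste0(stem, "_nodes.csv"))
  edges <- utils::read.csv(paste0(stem, "_edges.csv"))
  net <- structure(list(cells = cells, edges = edges, N = nrow(cells),
                        config = NULL),
                   class = "scn_network")
  net$degree <- network_degree(net)
  net
}
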