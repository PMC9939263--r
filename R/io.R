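#' Read a grooming network from edge-list and node-attribute CSVs
#'
#' The expected on-disk format is an undirected weighted edge list
#' (`id_a,id_b,weight`, one row per dyad with a positive grooming rate) and
#' an optional node attribute table whose first column is the node id
#' (typically `id,age,rank,matriline,group,year`).
#'
#' @param edge_csv Path to the edge-list CSV.
#' @param node_csv Optional path to the node attribute CSV.
#' @return An undirected weighted igraph graph (see [grooming_graph()]).
#' @export
read_grooming_network <- function(edge_csv, node_csv = NULL) {
  edges <- utils::read.csv(edge_csv, stringsAsFactors = FALSE)
  nodes <- if (!is.null(node_csv)) {
    utils::read.csv(node_csv, stringsAsFactors = FALSE)
  } else {
    NULL
  }
  grooming_graph(edges, nodes)
}

#' Write a grooming network to edge-list and node-attribute CSVs
#'
#' @param g An undirected igraph graph with a `weight` edge attribute.
#' @param edge_csv Path for the edge-list CSV.
#' @param node_csv Optional path for the node attribute CSV (written from the
#'   graph's vertex attributes).
#' @return Invisibly, the edge data frame written.
#' @export
write_grooming_network <- function(g, edge_csv, node_csv = NULL) {
  el <- igraph::as_edgelist(g, names = TRUE)
  edges <- data.frame(
    id_a = el[, 1], id_b = el[, 2],
    weight = if (graph_is_weighted(g)) igraph::E(g)$weight else
      rep(1, nrow(el))
  )
  utils::write.csv(edges, edge_csv, row.names = FALSE)
  if (!is.null(node_csv)) {
    attrs <- igraph::vertex_attr_names(g)
    nodes <- data.frame(id = igraph::V(g)$name)
    for (a in setdiff(attrs, "name")) {
      nodes[[a]] <- igraph::vertex_attr(g, a)
    }
    utils::write.csv(nodes, node_csv, row.names = FALSE)
  }
  invisible(edges)
}

#' GraphML round trip
#'
#' Thin wrappers over igraph's GraphML reader/writer, kept so networks with
#' `age_class`/`kin_group` (simulated) or `age`/`rank`/`matriline`
#' (grooming) node attributes survive a round trip to disk.
#'
#' @param g An igraph graph.
#' @param path File path.
#' @return `write_network_graphml` returns `path` invisibly;
#'   `read_network_graphml` returns the graph.
#' @export
write_network_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
read_network_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Write replicate-level ensemble results to CSV
#'
#' One row per simulated network: replicate index, `n_old`, proportion old,
#' global metrics, and the six realized dyad-type linking proportions.
#'
#' @param ensemble An `abm_ensemble`.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "abm_ensemble"))
  utils::write.csv(ensemble$replicates, path, row.names = FALSE)
  invisible(path)
}
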