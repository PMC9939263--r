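#' Convert an affinity edge weight to a geodesic length
#'
#' Shortest-path metrics on grooming networks need a cost per edge: a
#' strongly bonded dyad should be "close". The package convention is the
#' reciprocal of the grooming rate, strictly decreasing in the weight.
#'
#' @param w Positive edge weight(s) (e.g. grooming seconds per
#'   dyad-observation-hour).
#' @return `1 / w`.
#' @examples
#' weight_to_distance(2) # 0.5
#' @export
weight_to_distance <- function(w) {
  if (any(w <= 0)) {
    stop("edge weights must be strictly positive", call. = FALSE)
  }
  1 / w
}

#' Build an undirected weighted grooming network
#'
#' @param edges Data frame with columns `id_a`, `id_b`, `weight` (positive
#'   grooming rates). One row per dyad; absent dyads are non-edges.
#' @param nodes Optional data frame of node attributes whose first column is
#'   the node id (e.g. `id, age, rank, matriline, group, year`). Nodes listed
#'   here but absent from `edges` become isolates.
#' @return An undirected igraph graph with a `weight` edge attribute.
#' @export
grooming_graph <- function(edges, nodes = NULL) {
  stopifnot(all(c("id_a", "id_b", "weight") %in% names(edges)))
  if (any(edges$weight <= 0)) {
    stop("grooming networks require strictly positive edge weights",
         call. = FALSE)
  }
  if (any(as.character(edges$id_a) == as.character(edges$id_b))) {
    stop("self-loops are not allowed", call. = FALSE)
  }
  el <- data.frame(
    from = as.character(edges$id_a), to = as.character(edges$id_b),
    weight = edges$weight
  )
  if (!is.null(nodes)) {
    nodes[[1]] <- as.character(nodes[[1]])
  }
  igraph::graph_from_data_frame(el, directed = FALSE, vertices = nodes)
}

# Distance vector for shortest-path computations: reciprocal weights when
# the graph is weighted and weighted = TRUE, otherwise unit lengths (NA tells
# igraph to ignore any weight attribute).
edge_distances <- function(g, weighted) {
  if (weighted && "weight" %in% igraph::edge_attr_names(g)) {
    weight_to_distance(igraph::E(g)$weight)
  } else {
    NA
  }
}

graph_is_weighted <- function(g) {
  "weight" %in% igraph::edge_attr_names(g)
}

#' Node-level network metrics
#'
#' Computes, for every node, the four indirect-connectedness measures used
#' throughout the package together with degree and strength:
#' \describe{
#'   \item{eigenvector}{Leading-eigenvector score of the (weighted)
#'     adjacency, computed per connected component and scaled so each
#'     component's maximum is 1; isolates score 0.}
#'   \item{betweenness}{Shortest-path betweenness with fractional attribution
#'     among tied geodesics; weighted graphs use reciprocal-weight edge
#'     lengths.}
#'   \item{closeness}{Reachable-set closeness
#'     `((r-1)/(n-1)) * ((r-1) / sum of distances to reachable nodes)`, where
#'     `r` counts reachable nodes including the node itself. On weighted
#'     graphs the distances are first normalized by the network's smallest
#'     edge distance (its strongest tie), which makes closeness invariant to
#'     the unit of the grooming rate and bounds it in \[0, 1\]; 0 for
#'     isolates.}
#'   \item{clustering}{Binary local clustering coefficient (realized ties
#'     among neighbours over possible ties), ignoring weights; nodes of
#'     degree < 2 score 0 and are flagged.}
#' }
#'
#' @param g An undirected igraph graph, optionally with positive `weight`
#'   edge attribute.
#' @param weighted Use weights (where present) for eigenvector, betweenness
#'   and closeness. Clustering is always binary.
#' @return Data frame with one row per node: `id`, `degree`, `strength`,
#'   `eigenvector`, `betweenness`, `closeness`, `clustering`,
#'   `low_degree` (logical flag for the degree < 2 clustering policy).
#' @examples
#' g <- igraph::make_star(5, mode = "undirected")
#' node_metrics(g)
#' @export
node_metrics <- function(g, weighted = TRUE) {
  n <- igraph::vcount(g)
  ids <- igraph::V(g)$name
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n == 0L) {
    return(data.frame(
      id = character(), degree = integer(), strength = numeric(),
      eigenvector = numeric(), betweenness = numeric(),
      closeness = numeric(), clustering = numeric(), low_degree = logical()
    ))
  }
  use_w <- weighted && graph_is_weighted(g)
  deg <- igraph::degree(g)
  strength <- if (graph_is_weighted(g)) {
    igraph::strength(g, weights = igraph::E(g)$weight)
  } else {
    deg
  }
  dist_w <- edge_distances(g, weighted)

  # eigenvector per connected component, each scaled to max 1
  ev <- numeric(n)
  comps <- igraph::components(g)
  for (cid in seq_len(comps$no)) {
    members <- which(comps$membership == cid)
    if (length(members) < 2L) next # isolate -> 0
    sub <- igraph::induced_subgraph(g, members)
    w_sub <- if (use_w) igraph::E(sub)$weight else NA
    sc <- igraph::eigen_centrality(sub, weights = w_sub)
    ev[members] <- sc$vector # scaled so the component maximum is 1
  }

  btw <- igraph::betweenness(g, weights = dist_w)

  # reachable-set closeness from the full distance matrix; weighted
  # distances are normalized by the strongest tie so closeness stays in
  # [0, 1] whatever the rate units
  dmat <- igraph::distances(g, weights = dist_w)
  if (use_w && igraph::ecount(g) > 0L) dmat <- dmat / min(dist_w)
  cls <- vapply(seq_len(n), function(v) {
    d <- dmat[v, -v]
    finite <- is.finite(d)
    r <- sum(finite) + 1L
    if (r == 1L || n == 1L) return(0)
    ((r - 1) / (n - 1)) * ((r - 1) / sum(d[finite]))
  }, numeric(1))

  clu <- igraph::transitivity(g, type = "local", isolates = "zero")
  clu[deg < 2L] <- 0

  data.frame(
    id = ids, degree = as.integer(deg), strength = as.numeric(strength),
    eigenvector = ev, betweenness = as.numeric(btw), closeness = cls,
    clustering = clu, low_degree = deg < 2L,
    row.names = NULL
  )
}

#' Global network metrics
#'
#' @param g An undirected igraph graph (>= 2 nodes), optionally weighted.
#' @param weighted Use reciprocal-weight distances for the diameter where a
#'   `weight` attribute is present. Mean degree, transitivity and density are
#'   always binary.
#' @param old_threshold Age (years) above which a node counts as old, when
#'   the graph carries an `age` vertex attribute.
#' @return One-row data frame: `n_nodes`, `n_edges`, `mean_degree`,
#'   `diameter` (longest geodesic over connected pairs only; 0, flagged, for
#'   edgeless graphs), `transitivity` (global, 0 when no connected triples),
#'   `density`, `proportion_old` (NA when ages are unknown), `edgeless`
#'   (flag).
#' @examples
#' g <- igraph::make_full_graph(4)
#' global_metrics(g)
#' @export
global_metrics <- function(g, weighted = TRUE, old_threshold = 18) {
  n <- igraph::vcount(g)
  if (n < 2L) {
    stop("global metrics require a graph with at least 2 nodes",
         call. = FALSE)
  }
  m <- igraph::ecount(g)
  deg <- igraph::degree(g)
  dist_w <- edge_distances(g, weighted)
  if (m == 0L) {
    diam <- 0
    trans <- 0
  } else {
    diam <- igraph::diameter(g, weights = dist_w, unconnected = TRUE)
    trans <- igraph::transitivity(g, type = "global")
    if (is.nan(trans)) trans <- 0
  }
  prop_old <- NA_real_
  attrs <- igraph::vertex_attr_names(g)
  if ("age" %in% attrs) {
    prop_old <- mean(igraph::V(g)$age > old_threshold)
  } else if ("age_class" %in% attrs) {
    prop_old <- mean(igraph::V(g)$age_class == "old")
  }
  data.frame(
    n_nodes = n, n_edges = m,
    mean_degree = mean(deg),
    diameter = diam,
    transitivity = trans,
    density = 2 * m / (n * (n - 1)),
    proportion_old = prop_old,
    edgeless = m == 0L
  )
}

#' Node metrics for every network of a collection
#'
#' @param networks A `grooming_dataset` or list of igraph graphs. Graph
#'   attributes `group` and `year` and vertex attributes `age`, `rank` and
#'   `matriline` are carried through when present.
#' @param weighted Passed to [node_metrics()].
#' @return Data frame, one row per node per network.
#' @export
node_metric_table <- function(networks, weighted = TRUE) {
  graphs <- if (inherits(networks, "grooming_dataset")) {
    networks$networks
  } else {
    networks
  }
  rows <- lapply(seq_along(graphs), function(k) {
    g <- graphs[[k]]
    nm <- node_metrics(g, weighted = weighted)
    nm$network <- k
    for (ga in c("group", "year")) {
      nm[[ga]] <- if (ga %in% igraph::graph_attr_names(g)) {
        igraph::graph_attr(g, ga)
      } else {
        NA
      }
    }
    for (va in c("age", "rank", "matriline")) {
      nm[[va]] <- if (va %in% igraph::vertex_attr_names(g)) {
        igraph::vertex_attr(g, va)
      } else {
        NA
      }
    }
    nm
  })
  do.call(rbind, rows)
}

#' Global metrics for every network of a collection
#'
#' @inheritParams node_metric_table
#' @param old_threshold Passed to [global_metrics()].
#' @return Data frame, one row per network, including `average_relatedness`
#'   when carried as a graph attribute.
#' @export
global_metric_table <- function(networks, weighted = TRUE,
                                old_threshold = 18) {
  graphs <- if (inherits(networks, "grooming_dataset")) {
    networks$networks
  } else {
    networks
  }
  rows <- lapply(seq_along(graphs), function(k) {
    g <- graphs[[k]]
    gm <- global_metrics(g, weighted = weighted,
                         old_threshold = old_threshold)
    gm$network <- k
    for (ga in c("group", "year", "average_relatedness")) {
      gm[[ga]] <- if (ga %in% igraph::graph_attr_names(g)) {
        igraph::graph_attr(g, ga)
      } else {
        NA
      }
    }
    gm
  })
  do.call(rbind, rows)
}
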