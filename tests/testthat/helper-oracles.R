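# Brute-force network-metric oracles, independent of the package's igraph
# code paths: dense eigen-decomposition, Floyd-Warshall all-pairs distances,
# exhaustive shortest-path counting. Deliberately slow and simple.

# Weighted adjacency matrix (0 = no edge) and edge list from an igraph graph.
oracle_adjacency <- function(g, weighted = TRUE) {
  n <- igraph::vcount(g)
  W <- matrix(0, n, n)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- if (weighted && "weight" %in% igraph::edge_attr_names(g)) {
    igraph::E(g)$weight
  } else {
    rep(1, nrow(el))
  }
  for (e in seq_len(nrow(el))) {
    W[el[e, 1], el[e, 2]] <- w[e]
    W[el[e, 2], el[e, 1]] <- w[e]
  }
  W
}

# Floyd-Warshall on a cost matrix built from affinities (cost = 1/W).
oracle_distances <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[W > 0] <- 1 / W[W > 0]
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      nd <- D[i, k] + D[k, ]
      upd <- nd < D[i, ]
      D[i, upd] <- nd[upd]
    }
  }
  D
}

# Connected components by reachability.
oracle_components <- function(D) {
  n <- nrow(D)
  memb <- integer(n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (memb[v] == 0L) {
      cid <- cid + 1L
      memb[is.finite(D[v, ])] <- cid
    }
  }
  memb
}

# Per-component leading eigenvector of the weighted adjacency (dense eigen),
# absolute values, each component scaled to maximum 1; isolates 0.
oracle_eigenvector <- function(W) {
  n <- nrow(W)
  D <- oracle_distances(W)
  memb <- oracle_components(D)
  ev <- numeric(n)
  for (cid in unique(memb)) {
    members <- which(memb == cid)
    if (length(members) < 2L) next
    sub <- W[members, members, drop = FALSE]
    es <- eigen(sub, symmetric = TRUE)
    v <- abs(es$vectors[, which.max(es$values)])
    ev[members] <- v / max(v)
  }
  ev
}

# Reachable-set closeness; dmat must already be on the normalized scale.
oracle_closeness <- function(dmat) {
  n <- nrow(dmat)
  vapply(seq_len(n), function(v) {
    d <- dmat[v, -v]
    fin <- is.finite(d)
    r <- sum(fin) + 1L
    if (r == 1L) return(0)
    ((r - 1) / (n - 1)) * ((r - 1) / sum(d[fin]))
  }, numeric(1))
}

# Shortest-path betweenness with fractional attribution among tied
# geodesics, by explicit path counting over the distance matrix.
oracle_betweenness <- function(W, tol = 1e-10) {
  n <- nrow(W)
  cost <- matrix(Inf, n, n)
  cost[W > 0] <- 1 / W[W > 0]
  D <- oracle_distances(W)
  # sigma[s, v]: number of shortest s -> v paths
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    ord <- order(D[s, ])
    for (v in ord) {
      if (v == s || !is.finite(D[s, v])) next
      pred <- which(is.finite(cost[, v]) &
                      abs(D[s, ] + cost[, v] - D[s, v]) < tol)
      sigma[s, v] <- sum(sigma[s, pred])
    }
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      if (!is.finite(D[s, t]) || sigma[s, t] == 0) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            abs(D[s, v] + D[v, t] - D[s, t]) < tol) {
          btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  btw
}

# Binary local clustering by neighbour-pair counting.
oracle_clustering <- function(W) {
  A <- (W > 0) * 1
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    k <- length(nb)
    if (k < 2L) return(0)
    ties <- sum(A[nb, nb]) / 2
    ties / choose(k, 2)
  }, numeric(1))
}

oracle_global <- function(W, weighted = TRUE) {
  A <- (W > 0) * 1
  n <- nrow(A)
  deg <- rowSums(A)
  m <- sum(A) / 2
  D <- if (weighted) oracle_distances(W) else oracle_distances(A)
  finite_off <- D[upper.tri(D)][is.finite(D[upper.tri(D)])]
  diam <- if (m == 0) 0 else max(finite_off)
  tri3 <- sum(diag(A %*% A %*% A)) # 6 x triangles
  triples2 <- sum(deg * (deg - 1)) # 2 x connected triples
  trans <- if (triples2 == 0) 0 else tri3 / triples2
  c(
    mean_degree = mean(deg), diameter = diam, transitivity = trans,
    density = 2 * m / (n * (n - 1))
  )
}

# Random test graph: mixes sizes, densities, binary/weighted, and keeps
# occasional isolates and disconnected components.
random_test_graph <- function(n = NULL, weighted = NULL) {
  if (is.null(n)) n <- sample(5:30, 1)
  if (is.null(weighted)) weighted <- stats::runif(1) < 0.5
  p <- stats::runif(1, 0.08, 0.4)
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p) {
        w <- if (weighted) stats::runif(1, 0.2, 5) else 1
        W[i, j] <- W[j, i] <- w
      }
    }
  }
  g <- igraph::graph_from_adjacency_matrix(
    W, mode = "undirected", weighted = if (weighted) TRUE else NULL
  )
  list(g = g, W = W, weighted = weighted)
}
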