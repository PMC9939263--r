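test_that("weight-to-distance is the reciprocal convention", {
  expect_equal(weight_to_distance(2), 0.5)
  expect_equal(weight_to_distance(1), 1)
  w <- runif(20, 0.1, 10)
  expect_true(all(diff(weight_to_distance(sort(w))) < 0))
  expect_error(weight_to_distance(0), "positive")
  expect_error(weight_to_distance(-2), "positive")
})

test_that("grooming graph construction validates edges", {
  edges <- data.frame(id_a = c("a", "b"), id_b = c("b", "c"),
                      weight = c(2, 0.5))
  g <- grooming_graph(edges)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(sort(igraph::E(g)$weight), c(0.5, 2))
  expect_error(
    grooming_graph(data.frame(id_a = "a", id_b = "b", weight = 0)),
    "positive"
  )
  expect_error(
    grooming_graph(data.frame(id_a = "a", id_b = "a", weight = 1)),
    "loops"
  )
  # nodes table can add isolates
  g2 <- grooming_graph(edges, nodes = data.frame(id = c("a", "b", "c", "d")))
  expect_equal(igraph::vcount(g2), 4)
})

test_that("node metrics match closed forms on canonical small graphs", {
  # path a-b-c, unit weights
  path <- igraph::make_graph(~ a - b, b - c)
  nm <- node_metrics(path)
  expect_equal(nm$betweenness, c(0, 1, 0))
  expect_equal(nm$closeness[nm$id == "b"], 1)
  expect_equal(nm$clustering, c(0, 0, 0))

  # star: hub betweenness = choose(4,2), hub has max eigenvector, hub
  # clustering 0
  star <- igraph::make_star(5, mode = "undirected")
  nms <- node_metrics(star)
  expect_equal(nms$betweenness[1], 6)
  expect_equal(nms$eigenvector[1], 1)
  expect_true(all(nms$eigenvector[-1] < 1))
  expect_equal(nms$clustering[1], 0)
  expect_true(all(nms$low_degree[-1]))

  # k-regular (ring): all eigenvector scores equal
  ring <- igraph::make_ring(6)
  expect_equal(node_metrics(ring)$eigenvector, rep(1, 6))

  # triangle: clustering 1 everywhere
  tri <- igraph::make_full_graph(3)
  expect_equal(node_metrics(tri)$clustering, rep(1, 3))
})

test_that("eigenvector on a weighted toy graph matches a dense eigensolver", {
  set.seed(21)
  W <- matrix(0, 5, 5)
  W[1, 2] <- W[2, 1] <- 2.5
  W[2, 3] <- W[3, 2] <- 0.7
  W[3, 4] <- W[4, 3] <- 1.9
  W[4, 1] <- W[1, 4] <- 0.3
  W[2, 4] <- W[4, 2] <- 1.1 # node 5 isolated
  g <- igraph::graph_from_adjacency_matrix(W, "undirected", weighted = TRUE)
  nm <- node_metrics(g)
  expect_equal(nm$eigenvector, oracle_eigenvector(W), tolerance = 1e-8)
  expect_equal(nm$eigenvector[5], 0)
})

test_that("shortest-path metrics on a random weighted graph match brute force", {
  set.seed(22)
  rg <- random_test_graph(n = 12, weighted = TRUE)
  nm <- node_metrics(rg$g)
  expect_equal(nm$betweenness, oracle_betweenness(rg$W), tolerance = 1e-9)
  D <- oracle_distances(rg$W)
  dmin <- min(1 / rg$W[rg$W > 0])
  expect_equal(nm$closeness, oracle_closeness(D / dmin), tolerance = 1e-9)
})

test_that("global metrics match closed forms, including disconnected graphs", {
  k4 <- igraph::make_full_graph(4)
  gm <- global_metrics(k4)
  expect_equal(gm$mean_degree, 3)
  expect_equal(gm$diameter, 1)
  expect_equal(gm$transitivity, 1)
  expect_equal(gm$density, 1)

  path <- igraph::make_graph(~ a - b, b - c)
  gmp <- global_metrics(path)
  expect_equal(gmp$mean_degree, 4 / 3)
  expect_equal(gmp$diameter, 2)
  expect_equal(gmp$transitivity, 0)

  # two disjoint triangles: diameter over connected pairs only
  tt <- igraph::make_full_graph(3) + igraph::make_full_graph(3)
  gmt <- global_metrics(tt)
  expect_equal(gmt$diameter, 1)
  expect_equal(gmt$transitivity, 1)
  expect_equal(gmt$density, 6 / 15)

  # edgeless graph: diameter 0 with a flag
  e0 <- igraph::make_empty_graph(4, directed = FALSE)
  gme <- global_metrics(e0)
  expect_equal(gme$diameter, 0)
  expect_true(gme$edgeless)
  expect_error(global_metrics(igraph::make_empty_graph(1, directed = FALSE)),
               "at least 2")
})

test_that("weighted and binary code paths agree when all weights are 1", {
  set.seed(23)
  rg <- random_test_graph(n = 15, weighted = FALSE)
  g_w <- igraph::set_edge_attr(rg$g, "weight",
                               value = rep(1, igraph::ecount(rg$g)))
  nm_b <- node_metrics(rg$g, weighted = FALSE)
  nm_w <- node_metrics(g_w, weighted = TRUE)
  for (col in c("eigenvector", "betweenness", "closeness", "clustering")) {
    expect_equal(nm_w[[col]], nm_b[[col]], tolerance = 1e-10)
  }
  expect_equal(global_metrics(g_w)$diameter,
               global_metrics(rg$g)$diameter)
})

test_that("tree betweenness totals satisfy the path-length identity", {
  # on a tree the geodesic between each pair is unique, so total
  # betweenness equals the total number of intermediate nodes on all paths
  set.seed(24)
  for (rep in 1:5) {
    n <- sample(6:15, 1)
    g <- igraph::sample_tree(n)
    W <- oracle_adjacency(g, weighted = FALSE)
    D <- oracle_distances(W)
    nm <- node_metrics(g, weighted = FALSE)
    expected_total <- sum(D[upper.tri(D)] - 1) # intermediates per pair
    expect_equal(sum(nm$betweenness), expected_total, tolerance = 1e-9)
    expect_equal(nm$betweenness, oracle_betweenness(W), tolerance = 1e-9)
  }
})

test_that("metric outputs are permutation invariant", {
  set.seed(25)
  rg <- random_test_graph(n = 14, weighted = TRUE)
  g <- rg$g
  igraph::V(g)$name <- sprintf("v%02d", seq_len(14))
  perm <- sample(14)
  gp <- igraph::permute(g, perm)
  nm <- node_metrics(g)
  nmp <- node_metrics(gp)
  nmp <- nmp[match(nm$id, nmp$id), ]
  for (col in c("degree", "strength", "eigenvector", "betweenness",
                "closeness", "clustering")) {
    expect_equal(nmp[[col]], nm[[col]], tolerance = 1e-9)
  }
  gm <- global_metrics(g)
  gmp <- global_metrics(gp)
  expect_equal(gm$diameter, gmp$diameter)
  expect_equal(gm$transitivity, gmp$transitivity)
})

test_that("closeness and clustering stay in the unit interval on random graphs", {
  set.seed(26)
  for (rep in 1:10) {
    rg <- random_test_graph()
    nm <- node_metrics(rg$g)
    expect_true(all(nm$closeness >= 0 & nm$closeness <= 1 + 1e-12))
    expect_true(all(nm$clustering >= 0 & nm$clustering <= 1 + 1e-12))
    expect_true(all(nm$eigenvector >= 0))
    expect_true(all(nm$betweenness >= 0))
    gm <- global_metrics(rg$g)
    expect_true(gm$transitivity >= 0 && gm$transitivity <= 1)
  }
})

test_that("edge-list CSV and GraphML round trips preserve the network", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(synth_params(), n_networks = 2, seed = 31)
  g <- ds$networks[[1]]
  ecsv <- file.path(dir, "edges.csv")
  ncsv <- file.path(dir, "nodes.csv")
  write_grooming_network(g, ecsv, ncsv)
  g2 <- read_grooming_network(ecsv, ncsv)
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  nm1 <- node_metrics(g)
  nm2 <- node_metrics(g2)
  nm2 <- nm2[match(nm1$id, nm2$id), ]
  expect_equal(nm2$closeness, nm1$closeness, tolerance = 1e-12)

  gml <- file.path(dir, "net.graphml")
  write_network_graphml(g, gml)
  g3 <- read_network_graphml(gml)
  expect_equal(igraph::ecount(g3), igraph::ecount(g))
  # GraphML adds its own node-id attribute; every original attribute must
  # survive the round trip
  expect_true(all(igraph::vertex_attr_names(g) %in%
                    igraph::vertex_attr_names(g3)))
  expect_equal(sort(igraph::V(g3)$age), sort(igraph::V(g)$age))
})
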