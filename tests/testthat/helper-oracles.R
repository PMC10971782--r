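# Independent brute-force oracles and small graph builders used across tests.

# Triple-enumeration motif counter: every unordered node triple is classified
# by its number of internal edges (2 = wedge contributes to the open count
# via its centre, 3 = triangle). Deliberately naive and independent of the
# package's counting path.
brute_force_motifs <- function(graph) {
  n <- igraph::vcount(graph)
  adj <- as.matrix(igraph::as_adjacency_matrix(graph))
  wedges <- 0
  triangles <- 0
  if (n >= 3) {
    for (trip in utils::combn(n, 3, simplify = FALSE)) {
      i <- trip[1]; j <- trip[2]; k <- trip[3]
      m <- adj[i, j] + adj[i, k] + adj[j, k]
      if (m == 3) triangles <- triangles + 1
    }
  }
  # wedges counted per centre node: choose(degree, 2) sums open AND closed
  # triples, matching the transitivity denominator
  wedges <- sum(choose(igraph::degree(graph), 2))
  list(wedges = wedges, triangles = triangles,
       phi = if (wedges > 0) 3 * triangles / wedges else NA_real_)
}

brute_force_assortativity <- function(graph) {
  if (igraph::ecount(graph) < 2) return(NA_real_)
  deg <- igraph::degree(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  x <- c(deg[el[, 1]], deg[el[, 2]])
  y <- c(deg[el[, 2]], deg[el[, 1]])
  if (var(x) == 0) NA_real_ else stats::cor(x, y)
}

as_edge_matrix_for_test <- function(graph) {
  el <- igraph::as_edgelist(graph, names = FALSE) - 1L
  cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
}

random_connected_graph <- function(n, p = 0.4) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::ecount(g) >= 2 && igraph::is_connected(g)) return(g)
  }
}

# graph examples used repeatedly
k4 <- function() igraph::make_full_graph(4)
c5 <- function() igraph::make_ring(5)
star5 <- function() igraph::make_star(6, mode = "undirected")

path_graph <- function(n) igraph::make_ring(n, circular = FALSE)
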