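# Graph representation and motif/mixing metrics.
#
# Graphs are igraph objects: simple, undirected, unweighted. Node ids in all
# file formats and in the swap functions are 0-based contiguous integers
# (the edge-list convention); igraph's internal 1-based vertex ids are an
# implementation detail.

as_edge_matrix <- function(graph) {
  el <- igraph::as_edgelist(graph, names = FALSE) - 1L
  storage.mode(el) <- "integer"
  cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
}

graph_from_edges <- function(edges, n_nodes) {
  igraph::make_graph(as.vector(t(edges)) + 1L, n = n_nodes, directed = FALSE)
}

#' Validate a population graph
#'
#' Checks that a graph is a simple undirected igraph object (no self-loops,
#' no parallel edges) with at least one node, and optionally that it is
#' connected.
#'
#' @param graph An igraph object.
#' @param connected Logical; additionally require connectivity.
#' @return The graph, invisibly. Errors otherwise.
#' @export
validate_graph <- function(graph, connected = FALSE) {
  if (!igraph::is_igraph(graph)) stop("`graph` must be an igraph object")
  if (igraph::vcount(graph) == 0) stop("no nodes")
  if (igraph::is_directed(graph)) stop("graph must be undirected")
  if (any(igraph::which_loop(graph))) stop("graph contains self-loops")
  if (any(igraph::which_multiple(graph))) stop("graph contains parallel edges")
  if (connected && !igraph::is_connected(graph))
    stop("graph is not connected")
  invisible(graph)
}

#' Is a graph connected?
#'
#' Single-traversal connectivity check.
#'
#' @param graph An igraph object with at least one node.
#' @return `TRUE` iff every node is reachable from node 0.
#' @export
is_connected_graph <- function(graph) {
  if (igraph::vcount(graph) == 0) stop("no nodes")
  igraph::is_connected(graph)
}

#' Degree assortativity
#'
#' Pearson correlation coefficient of the degrees at the two ends of an
#' edge, computed symmetrically over both edge orientations.
#'
#' @param graph An igraph object.
#' @return The correlation in \[-1, 1\], or `NA_real_` when it is undefined
#'   (fewer than two edges, or zero degree variance across edge endpoints,
#'   as in any regular graph).
#' @export
graph_assortativity <- function(graph) {
  validate_graph(graph)
  if (igraph::ecount(graph) < 2) return(NA_real_)
  deg <- igraph::degree(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  x <- deg[el[, 1]]
  y <- deg[el[, 2]]
  if (var(c(x, y)) == 0) return(NA_real_)
  stats::cor(c(x, y), c(y, x))
}

#' Transitivity (global triangle fraction)
#'
#' The global ratio 3 * triangles / wedges, where a wedge is a path of two
#' edges (a connected triple). This is the graph-level quantity the pair
#' approximation uses, not the mean local clustering coefficient.
#'
#' @param graph An igraph object.
#' @return Transitivity in \[0, 1\], or `NA_real_` when the graph has no
#'   wedges.
#' @export
graph_transitivity <- function(graph) {
  validate_graph(graph)
  deg <- igraph::degree(graph)
  w <- sum(choose(deg, 2))
  if (w == 0) return(NA_real_)
  tri <- sum(igraph::count_triangles(graph)) / 3
  3 * tri / w
}

#' Count motifs up to dimension three
#'
#' Exact counts of the 0K-3K summary of a graph: edges, wedges (open
#' triples), triangles, global transitivity, degree assortativity, and the
#' joint degree matrix J with J(i, j) the number of edges linking a
#' degree-i node to a degree-j node (i <= j).
#'
#' @param graph An igraph object.
#' @return An object of class `motif_profile`.
#' @export
count_motifs <- function(graph) {
  validate_graph(graph)
  deg <- igraph::degree(graph)
  n_edges <- igraph::ecount(graph)
  wedges <- sum(choose(deg, 2))
  triangles <- sum(igraph::count_triangles(graph)) / 3
  phi <- if (wedges > 0) 3 * triangles / wedges else NA_real_
  ud <- sort(unique(deg))
  j_mat <- matrix(0L, length(ud), length(ud), dimnames = list(ud, ud))
  if (n_edges > 0) {
    el <- igraph::as_edgelist(graph, names = FALSE)
    di <- pmin(deg[el[, 1]], deg[el[, 2]])
    dj <- pmax(deg[el[, 1]], deg[el[, 2]])
    tab <- table(factor(di, ud), factor(dj, ud))
    j_mat[] <- as.integer(tab)
  }
  structure(
    list(
      n_nodes = igraph::vcount(graph), n_edges = n_edges, wedges = wedges,
      triangles = as.integer(round(triangles)), transitivity = phi,
      assortativity = graph_assortativity(graph), joint_degrees = j_mat
    ),
    class = "motif_profile"
  )
}

#' @export
print.motif_profile <- function(x, ...) {
  cat("Motif profile (0K-3K summary)\n")
  cat(sprintf("  nodes: %d  edges: %d\n", x$n_nodes, x$n_edges))
  cat(sprintf("  wedges: %d  triangles: %d\n", x$wedges, x$triangles))
  cat(sprintf(
    "  transitivity phi: %s  assortativity r: %s\n",
    format(x$transitivity, digits = 4), format(x$assortativity, digits = 4)
  ))
  cat("  joint degree matrix J(i, j), i <= j:\n")
  print(x$joint_degrees)
  invisible(x)
}

swap_rejected <- function(msg) {
  stop(structure(
    class = c("evomotif_swap_rejected", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_swap_edges <- function(graph, edge1, edge2) {
  stopifnot(length(edge1) == 2, length(edge2) == 2)
  n <- igraph::vcount(graph)
  ids <- c(edge1, edge2)
  if (any(ids < 0 | ids >= n)) stop("node id out of range")
  has_edge <- function(e) {
    length(igraph::get_edge_ids(graph, e + 1L, error = FALSE)) > 0 &&
      igraph::get_edge_ids(graph, e + 1L, error = FALSE) > 0
  }
  if (!has_edge(edge1) || !has_edge(edge2))
    stop("edge1 and edge2 must be existing edges")
  if (length(unique(ids)) < 4)
    swap_rejected("edges share an endpoint")
  invisible(has_edge)
}

#' Degree-preserving double edge swap
#'
#' Replaces edges (a,b) and (c,d) by (a,c),(b,d) (`orientation = "cross"`)
#' or (a,d),(b,c) (`orientation = "parallel"`). The degree of every node is
#' conserved. Proposals that would create a self-loop or a parallel edge
#' raise a condition of class `evomotif_swap_rejected`, signalling the
#' caller to re-propose.
#'
#' @param graph An igraph object.
#' @param edge1,edge2 Length-2 integer vectors of 0-based node ids naming
#'   existing edges with disjoint endpoints.
#' @param orientation `"cross"` or `"parallel"`.
#' @return The rewired graph.
#' @export
double_edge_swap <- function(graph, edge1, edge2,
                             orientation = c("cross", "parallel")) {
  orientation <- match.arg(orientation)
  validate_graph(graph)
  has_edge <- check_swap_edges(graph, edge1, edge2)
  a <- edge1[1]; b <- edge1[2]; c <- edge2[1]; d <- edge2[2]
  new1 <- if (orientation == "cross") c(a, c) else c(a, d)
  new2 <- if (orientation == "cross") c(b, d) else c(b, c)
  if (has_edge(new1) || has_edge(new2))
    swap_rejected("swap would create a parallel edge")
  g <- igraph::delete_edges(
    graph, igraph::get_edge_ids(graph, c(edge1, edge2) + 1L)
  )
  igraph::add_edges(g, c(new1, new2) + 1L)
}

#' 2K-preserving edge swap
#'
#' A double edge swap restricted to two edges of the same type (the same
#' unordered degree pair), rewired so that like-degree endpoints are
#' exchanged. The joint degree matrix J -- and with it the degree
#' distribution and assortativity -- is conserved exactly.
#'
#' @inheritParams double_edge_swap
#' @return The rewired graph.
#' @export
two_k_swap <- function(graph, edge1, edge2) {
  validate_graph(graph)
  # the type precondition is a hard error, checked before any rejection
  deg <- igraph::degree(graph)
  d1 <- sort(deg[edge1 + 1L])
  d2 <- sort(deg[edge2 + 1L])
  if (!identical(d1, d2)) stop("type mismatch: edges have different degree pairs")
  has_edge <- check_swap_edges(graph, edge1, edge2)
  # orient both edges high-degree end first so exchanged ends match degree
  if (deg[edge1[1] + 1L] < deg[edge1[2] + 1L]) edge1 <- rev(edge1)
  if (deg[edge2[1] + 1L] < deg[edge2[2] + 1L]) edge2 <- rev(edge2)
  a <- edge1[1]; b <- edge1[2]; c <- edge2[1]; d <- edge2[2]
  candidates <- list(list(c(a, d), c(c, b)))
  if (deg[a + 1L] == deg[b + 1L])
    candidates <- c(candidates, list(list(c(a, c), c(b, d))))
  for (cand in candidates) {
    if (!has_edge(cand[[1]]) && !has_edge(cand[[2]])) {
      g <- igraph::delete_edges(
        graph, igraph::get_edge_ids(graph, c(edge1, edge2) + 1L)
      )
      return(igraph::add_edges(g, c(cand[[1]], cand[[2]]) + 1L))
    }
  }
  swap_rejected("swap would create a parallel edge")
}
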