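# Random graph generation with annealed motif tuning.
#
# The generators hold lower-order dK levels fixed while moving the triangle
# fraction phi (and, for degree-heterogeneous graphs, the assortativity r)
# toward a target: degree-preserving double edge swaps accepted by a
# Metropolis-Hastings rule with a Gaussian density of mean phi_target and
# growing width sigma (regular graphs), and 2K-preserving swaps accepted
# greedily toward the target, or with probability gamma away from it
# (degree-heterogeneous graphs).

#' Annealing schedule configuration
#'
#' @param sigma0 Initial width of the Gaussian acceptance density.
#' @param sigma_growth Multiplicative growth factor, applied every
#'   `sigma_interval` proposals (default N * k, resolved at call time).
#' @param sigma_interval Proposals between sigma updates; `NULL` resolves to
#'   N * k of the graph being tuned.
#' @param budget Total number of valid proposals; `NULL` resolves to
#'   k * 1e6 (k the mean degree, rounded).
#' @param gamma0 Initial acceptance probability for away-from-target
#'   2K moves (1/gamma is the annealing temperature).
#' @param gamma_decay Multiplicative decay of gamma, applied every
#'   `gamma_interval` proposals (default N * mean degree).
#' @param gamma_interval Proposals between gamma updates; `NULL` as above.
#' @param stop_tol Stop early once the best-visited state is within this
#'   distance of the target; set to `NULL` to always run the full budget.
#' @return An object of class `anneal_config`.
#' @export
anneal_config <- function(sigma0 = 0.001, sigma_growth = 1.001,
                          sigma_interval = NULL, budget = NULL,
                          gamma0 = 0.5, gamma_decay = 0.99,
                          gamma_interval = NULL, stop_tol = 0.01) {
  stopifnot(sigma0 > 0, sigma_growth > 0, gamma0 > 0, gamma0 <= 1,
            gamma_decay > 0, gamma_decay <= 1)
  if (!is.null(budget)) stopifnot(budget >= 1)
  structure(
    list(
      sigma0 = sigma0, sigma_growth = sigma_growth,
      sigma_interval = sigma_interval, budget = budget, gamma0 = gamma0,
      gamma_decay = gamma_decay, gamma_interval = gamma_interval,
      stop_tol = if (is.null(stop_tol)) -1 else stop_tol
    ),
    class = "anneal_config"
  )
}

resolve_schedule <- function(config, n, k) {
  list(
    sigma_interval = if (is.null(config$sigma_interval)) n * k
                     else config$sigma_interval,
    gamma_interval = if (is.null(config$gamma_interval)) n * k
                     else config$gamma_interval,
    budget = if (is.null(config$budget)) round(k) * 1e6 else config$budget
  )
}

anneal_result <- function(graph, res, target, what, tol = 0.02) {
  attr(graph, "anneal") <- res[setdiff(names(res), "edges")]
  achieved <- if (what == "phi") res$phi else res$r
  if (isTRUE(res$stalled))
    warning("annealer stalled: no admissible swap found; returning best-found graph")
  else if (abs(achieved - target) > tol)
    warning(sprintf(
      "target %s = %g not reached within budget (achieved %.4f); returning best-found graph",
      what, target, achieved
    ))
  graph
}

#' Random regular graph
#'
#' A connected simple graph in which every node has degree exactly `k`.
#'
#' @param n Number of nodes.
#' @param k Common degree; `n * k` must be even and `k < n`.
#' @param seed Optional integer seed.
#' @param max_tries Resampling attempts to obtain a connected graph.
#' @return An igraph object.
#' @export
random_regular <- function(n, k, seed = NULL, max_tries = 100) {
  if (!is.null(seed)) set.seed(seed)
  if (k >= n) stop("degree k must be smaller than n")
  if ((n * k) %% 2 != 0) stop("infeasible degree sequence: n * k must be even")
  for (i in seq_len(max_tries)) {
    g <- igraph::sample_k_regular(n, k)
    if (igraph::is_connected(g)) return(g)
  }
  stop("failed to sample a connected regular graph")
}

#' Tune the triangle fraction of a regular graph
#'
#' Anneals a regular graph toward a target transitivity by double edge
#' swaps, accepted by the Metropolis-Hastings ratio of Gaussian densities
#' centred at `phi_target` with width sigma; moves toward the target are
#' always accepted and sigma is grown on its schedule. Accepted swaps that
#' disconnect the graph are reverted. The best-visited (closest-to-target)
#' connected state is returned; if the target is not reached within the
#' budget a warning is raised, never a silent miss.
#'
#' @param graph A connected regular igraph object.
#' @param phi_target Target transitivity in \[0, 1\].
#' @param config An [anneal_config()].
#' @param seed Optional integer seed.
#' @param trace_interval If positive, record the accepted-state phi every
#'   this many proposals (returned in `attr(result, "anneal")$trace`).
#' @return The tuned graph, with annealing diagnostics in `attr(, "anneal")`.
#' @export
tune_transitivity_regular <- function(graph, phi_target,
                                      config = anneal_config(), seed = NULL,
                                      trace_interval = 0) {
  if (!is.null(seed)) set.seed(seed)
  validate_graph(graph, connected = TRUE)
  stopifnot(phi_target >= 0, phi_target <= 1)
  deg <- igraph::degree(graph)
  if (var(deg) > 0) stop("graph is not regular; use tune_transitivity_2k()")
  n <- igraph::vcount(graph)
  k <- deg[1]
  sch <- resolve_schedule(config, n, k)
  res <- cpp_tune_phi(
    as_edge_matrix(graph), n, phi_target, config$sigma0, config$sigma_growth,
    sch$sigma_interval, sch$budget, config$stop_tol, trace_interval
  )
  anneal_result(graph_from_edges(res$edges, n), res, phi_target, "phi", max(0.02, config$stop_tol))
}

#' Tune degree assortativity
#'
#' Anneals a degree-heterogeneous graph toward a target assortativity
#' `r_target` by double edge swaps, with the same Gaussian
#' Metropolis-Hastings acceptance and connectivity handling as
#' [tune_transitivity_regular()]. The degree sequence is conserved exactly.
#'
#' @param graph A connected igraph object with nonzero degree variance.
#' @param r_target Target assortativity in \[-1, 1\].
#' @param config An [anneal_config()].
#' @param seed Optional integer seed.
#' @return The tuned graph, with diagnostics in `attr(, "anneal")`.
#' @export
tune_assortativity <- function(graph, r_target, config = anneal_config(),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_graph(graph, connected = TRUE)
  stopifnot(r_target >= -1, r_target <= 1)
  deg <- igraph::degree(graph)
  if (var(deg) == 0) stop("assortativity undefined for regular graphs")
  n <- igraph::vcount(graph)
  sch <- resolve_schedule(config, n, mean(deg))
  res <- cpp_tune_assort(
    as_edge_matrix(graph), n, r_target, config$sigma0, config$sigma_growth,
    sch$sigma_interval, sch$budget, config$stop_tol
  )
  anneal_result(graph_from_edges(res$edges, n), res, r_target, "r", max(0.02, config$stop_tol))
}

#' Tune the triangle fraction with 2K-preserving rewiring
#'
#' Moves the transitivity of a graph toward `phi_target` using swaps of two
#' same-type edges (the same unordered degree pair), which conserve the
#' joint degree matrix -- hence the degree distribution and the
#' assortativity -- exactly. Swaps toward the target are always accepted;
#' swaps away from it are accepted with probability gamma, decayed on its
#' schedule (1/gamma is the annealing temperature).
#'
#' @inheritParams tune_transitivity_regular
#' @return The tuned graph, with diagnostics in `attr(, "anneal")`.
#' @export
tune_transitivity_2k <- function(graph, phi_target, config = anneal_config(),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_graph(graph, connected = TRUE)
  stopifnot(phi_target >= 0, phi_target <= 1)
  n <- igraph::vcount(graph)
  kbar <- mean(igraph::degree(graph))
  sch <- resolve_schedule(config, n, kbar)
  res <- cpp_tune_phi_2k(
    as_edge_matrix(graph), n, phi_target, config$gamma0, config$gamma_decay,
    sch$gamma_interval, sch$budget, config$stop_tol
  )
  anneal_result(graph_from_edges(res$edges, n), res, phi_target, "phi", max(0.02, config$stop_tol))
}

#' Build a two-degree-class graph
#'
#' A connected graph with `n1` nodes of degree `k1` and `n2` nodes of
#' degree `k2`, initialised from a connected realisation of the degree
#' sequence and annealed to a target assortativity. With `k1 == k2` the
#' construction degenerates to a random regular graph.
#'
#' @param n1,k1,n2,k2 Class sizes and degrees; `n1*k1 + n2*k2` must be even
#'   and each degree smaller than the number of nodes.
#' @param r_target Target assortativity (ignored when `k1 == k2`); `NULL`
#'   skips assortativity tuning.
#' @param config An [anneal_config()] for the assortativity annealer.
#' @param seed Optional integer seed.
#' @return An igraph object.
#' @export
build_two_class_graph <- function(n1, k1, n2, k2, r_target = 0,
                                  config = anneal_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n1 + n2
  if ((n1 * k1 + n2 * k2) %% 2 != 0)
    stop("infeasible degree sequence: total degree must be even")
  if (max(k1, k2) >= n) stop("degrees must be smaller than the number of nodes")
  if (min(n1, n2, k1, k2) < 1) stop("class sizes and degrees must be positive")
  if (k1 == k2) return(random_regular(n, k1))
  degs <- rep(c(k1, k2), c(n1, n2))
  g <- igraph::sample_degseq(degs, method = "vl")
  if (!is.null(r_target)) g <- tune_assortativity(g, r_target, config)
  g
}
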