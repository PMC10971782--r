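# Brute-force configuration-space solver for small graphs.
#
# The full 2^N Markov chain over mutant configurations is built explicitly
# and the absorbing-chain linear systems are solved: h = fixation
# probability per configuration, and g with (I - Q) g = h, which gives the
# conditional mean fixation time t = g / h (a Doob h-transform identity).
# Serves as an independent oracle for the Monte Carlo engine.

#' Exact fixation probability and conditional time on a small graph
#'
#' Builds the transition matrix of the 2^N configuration chain of the
#' Moran process and solves the absorbing-chain linear systems for the
#' fixation probability and the conditional mean fixation time (in events)
#' from every single-mutant start.
#'
#' @param graph A connected igraph object with at most 14 nodes.
#' @param s Selection coefficient (mutant fitness 1 + s).
#' @param rule `"Bd"` or `"dB"`.
#' @return A list with `prob_by_node`, `prob_uniform` (uniform random
#'   single-mutant start), `time_by_node` and `time_uniform` (conditional
#'   mean events to fixation).
#' @export
exact_fixation <- function(graph, s, rule = c("Bd", "dB")) {
  rule <- match.arg(rule)
  validate_graph(graph, connected = TRUE)
  n <- igraph::vcount(graph)
  if (n > 14) stop("state space too big: exact solver requires N <= 14")
  stopifnot(1 + s > 0)

  adj <- igraph::as_adj_list(graph)
  adj <- lapply(adj, as.integer)
  deg <- lengths(adj)
  full <- bitwShiftL(1L, n) - 1L
  n_states <- full - 1L  # transient configurations 1 .. full-1
  bits <- bitwShiftL(1L, 0:(n - 1))

  trip_i <- vector("list", n_states)
  trip_j <- vector("list", n_states)
  trip_x <- vector("list", n_states)
  r_full <- numeric(n_states)

  for (x in seq_len(n_states)) {
    mut <- bitwAnd(x, bits) > 0
    f <- ifelse(mut, 1 + s, 1)
    js <- integer(0)
    ps <- numeric(0)
    if (rule == "Bd") {
      ftot <- sum(f)
      for (i in seq_len(n)) {
        pick <- f[i] / ftot / deg[i]
        for (j in adj[[i]]) {
          if (mut[i] != mut[j]) {
            y <- bitwXor(x, bits[j])
            js <- c(js, y)
            ps <- c(ps, pick)
          }
        }
      }
    } else {
      for (j in seq_len(n)) {
        nb <- adj[[j]]
        wsum <- sum(f[nb])
        for (i in nb) {
          if (mut[i] != mut[j]) {
            y <- bitwXor(x, bits[j])
            js <- c(js, y)
            ps <- c(ps, f[i] / wsum / n)
          }
        }
      }
    }
    moving <- sum(ps)
    # transitions to absorbing states feed r (fixation) or are dropped (loss)
    keep <- js != 0L & js != full
    r_full[x] <- sum(ps[js == full])
    trip_i[[x]] <- rep.int(x, sum(keep) + 1L)
    trip_j[[x]] <- c(js[keep], x)
    trip_x[[x]] <- c(ps[keep], 1 - moving)
  }

  q_mat <- Matrix::sparseMatrix(
    i = unlist(trip_i), j = unlist(trip_j), x = unlist(trip_x),
    dims = c(n_states, n_states)
  )
  a_mat <- Matrix::Diagonal(n_states) - q_mat
  h <- as.numeric(Matrix::solve(a_mat, r_full))
  g <- as.numeric(Matrix::solve(a_mat, h))

  singles <- as.integer(bits)
  prob_by_node <- h[singles]
  time_by_node <- g[singles] / prob_by_node
  list(
    prob_by_node = prob_by_node,
    prob_uniform = mean(prob_by_node),
    time_by_node = time_by_node,
    time_uniform = sum(g[singles]) / sum(h[singles])
  )
}
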