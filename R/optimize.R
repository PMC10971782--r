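# Evolutionary optimization on population graphs.
#
# Individuals carry a real-valued genotype vector mapped to an objective
# value; fitness is assigned by population rank (linear from 1+s for the
# best to 1-s for the worst, so mean fitness is exactly 1 and selection
# pressure is constant). Reproduction follows the Birth-death rule and
# every reproduction mutates either the parent or the offspring (fair
# coin) by a Gaussian noise vector.

#' Rank-selection fitness map
#'
#' The individual with the highest objective value gets fitness 1 + s,
#' decreasing linearly to 1 - s for the lowest; ties are broken by a
#' uniformly random permutation among the tied individuals. The mean
#' fitness is exactly 1.
#'
#' @param values Objective values (length >= 2).
#' @param s Selection strength in \[0, 1\]; s = 1 gives the worst
#'   individual fitness 0; s > 1 (negative fitness) is an error.
#' @return Fitness vector aligned with `values`.
#' @export
rank_fitness <- function(values, s) {
  n <- length(values)
  stopifnot(n >= 2)
  if (s < 0 || s > 1) stop("selection strength s must be in [0, 1]")
  j <- rank(-values, ties.method = "random") - 1
  (1 + s) - 2 * s * j / (n - 1)
}

#' Concave quadratic objective
#'
#' 1 - ||x - x*||^2: maximum value 1 at the optimum, depending on the
#' genotype only through its distance from x*.
#'
#' @param x Genotype vector, or a matrix with one genotype per row.
#' @param optimum Location of the maximum.
#' @return Objective value(s).
#' @export
quadratic_objective <- function(x, optimum = c(0, 0)) {
  if (is.matrix(x)) {
    1 - rowSums((x - rep(optimum, each = nrow(x)))^2)
  } else {
    1 - sum((x - optimum)^2)
  }
}

#' Inverted Rastrigin objective
#'
#' -(A d + sum(x_i^2 - A cos(2 pi x_i))) with A = 10: the standard rugged
#' multimodal benchmark, negated so the global maximum is 0 at the origin;
#' values are <= 0 everywhere.
#'
#' @param x Genotype vector, or a matrix with one genotype per row.
#' @return Objective value(s).
#' @export
rastrigin_objective <- function(x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1, byrow = TRUE)
  -(10 * ncol(x) + rowSums(x^2 - 10 * cos(2 * pi * x)))
}

#' Optimization problem specification
#'
#' Bundles the objective, genotype dimension, rank-selection strength,
#' Gaussian mutation scale and time-to-target threshold. Defaults follow
#' the two benchmark experiments: the smooth quadratic (mutation sd 0.012,
#' threshold 0.95) and the rugged inverted Rastrigin (mutation sd 0.12,
#' ten times larger). The common start genotype sits at distance 1 from
#' the quadratic optimum, and at (2, 2) — a few local peaks away from the
#' origin — for the Rastrigin problem.
#'
#' @param objective `"quadratic"` or `"rastrigin"`.
#' @param dim Genotype dimension.
#' @param s Rank-selection strength in \[0, 1\].
#' @param mutation_sd Per-component Gaussian mutation standard deviation.
#' @param theta Threshold for time-to-target (NA to disable stopping).
#' @param start Common initial genotype of all individuals.
#' @param optimum Location of the quadratic maximum (ignored for
#'   Rastrigin, whose maximum is pinned at the origin).
#' @return An object of class `opt_problem`.
#' @export
opt_problem <- function(objective = c("quadratic", "rastrigin"), dim = 2,
                        s = 1, mutation_sd = NULL, theta = NULL,
                        start = NULL, optimum = NULL) {
  objective <- match.arg(objective)
  stopifnot(dim >= 1)
  if (s < 0 || s > 1) stop("selection strength s must be in [0, 1]")
  if (is.null(mutation_sd))
    mutation_sd <- if (objective == "quadratic") 0.012 else 0.12
  stopifnot(mutation_sd > 0)
  if (is.null(optimum)) optimum <- rep(0, dim)
  if (is.null(start))
    start <- if (objective == "quadratic") optimum + c(1, rep(0, dim - 1))
             else rep(2, dim)
  if (is.null(theta)) theta <- if (objective == "quadratic") 0.95 else NA_real_
  max_attainable <- if (objective == "quadratic") 1 else 0
  if (!is.na(theta) && theta > max_attainable)
    stop("theta exceeds the objective's attainable range")
  stopifnot(length(start) == dim, length(optimum) == dim)
  structure(
    list(objective = objective, dim = dim, s = s, mutation_sd = mutation_sd,
         theta = theta, start = start, optimum = optimum),
    class = "opt_problem"
  )
}

#' Evolve a population on a graph
#'
#' Runs replicate rank-selection Birth-death optimization experiments on a
#' population graph: each event draws a reproducer fitness-proportionally
#' (fitness from [rank_fitness()], re-ranked after every replacement),
#' replaces a uniformly random neighbour with a copy, and mutates parent
#' or offspring with equal probability. The population mean objective
#' value is recorded every `cadence` events; a replicate stops at the
#' threshold crossing (if `stop_at_threshold`) or at the event cap, in
#' which case its time-to-threshold is censored (NA).
#'
#' @param graph A connected igraph object; one individual per node.
#' @param problem An [opt_problem()].
#' @param n_rep Number of replicate runs.
#' @param max_events Event cap per replicate.
#' @param cadence Events between records; `NULL` uses N.
#' @param record_trajectory Keep the recorded mean-value trajectories.
#' @param stop_at_threshold Stop each replicate at its first recorded
#'   crossing of `problem$theta`.
#' @param seed Optional integer seed.
#' @return An object of class `opt_result`: list with `times` (events to
#'   threshold per replicate, NA = censored), `time_axis` and `mean_value`
#'   (ensemble mean trajectory), `traj` (per-replicate matrix, if kept),
#'   and the problem.
#' @export
evolve_on_graph <- function(graph, problem = opt_problem(), n_rep = 100,
                            max_events = 1e6, cadence = NULL,
                            record_trajectory = FALSE,
                            stop_at_threshold = !record_trajectory,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_graph(graph, connected = TRUE)
  stopifnot(inherits(problem, "opt_problem"), n_rep >= 1)
  n <- igraph::vcount(graph)
  if (is.null(cadence)) cadence <- n
  res <- cpp_evolve(
    as_edge_matrix(graph), n,
    if (problem$objective == "quadratic") 0L else 1L, problem$dim,
    problem$start, problem$optimum, problem$s, problem$mutation_sd,
    problem$theta, cadence, max_events, n_rep,
    record_trajectory, stop_at_threshold
  )
  out <- list(
    times = res$times, n_rep = n_rep, n_censored = sum(is.na(res$times)),
    problem = problem, cadence = cadence, max_events = max_events
  )
  if (record_trajectory) {
    out$time_axis <- res$time_axis
    out$traj <- res$traj
    out$mean_value <- rowMeans(res$traj)
  }
  structure(out, class = "opt_result")
}

#' @export
print.opt_result <- function(x, ...) {
  cat(sprintf(
    "Rank-selection Bd optimization: %s objective, %d replicates\n",
    x$problem$objective, x$n_rep
  ))
  done <- !is.na(x$times)
  if (!is.na(x$problem$theta))
    cat(sprintf(
      "  time to mean value >= %g: %.0f events (mean over %d runs; %d censored)\n",
      x$problem$theta, mean(x$times[done]), sum(done), x$n_censored
    ))
  invisible(x)
}

#' Time to reach a mean-value threshold
#'
#' First recorded time at which the population mean objective value
#' reaches `theta`, per replicate; censored replicates give NA. Uses the
#' stored per-replicate times when `theta` matches the problem threshold,
#' otherwise recomputes from the recorded trajectories.
#'
#' @param result An [evolve_on_graph()] result.
#' @param theta Threshold; defaults to the problem's.
#' @return Vector of events-to-threshold, NA where censored.
#' @export
time_to_threshold <- function(result, theta = NULL) {
  stopifnot(inherits(result, "opt_result"))
  if (is.null(theta) || (!is.na(result$problem$theta) && theta == result$problem$theta))
    return(result$times)
  if (is.null(result$traj))
    stop("trajectories were not recorded; rerun with record_trajectory = TRUE")
  apply(result$traj, 2, function(v) {
    hit <- which(v >= theta)
    if (length(hit) == 0) NA_real_ else result$time_axis[hit[1]]
  })
}
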