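# Moran Birth-death / death-Birth simulation on graphs.
#
# A mutant carries fitness 1+s, the resident 1. One elementary event is one
# replacement attempt; a generation is N events. The engine keeps integer
# counts of mutants, of mixed (Aa) edges and of mutant degree, so the
# edge-frequency identities p_AA = (1 - p_a) - p_Aa and p_aa = p_a - p_Aa
# (p_Aa the ordered-pair frequency mixed/(2E)) hold exactly at every
# recorded step, with p_a read as the degree-weighted mutant frequency --
# identical to the node frequency on regular graphs.

#' Moran process configuration
#'
#' @param s Selection coefficient; mutant fitness is 1 + s (must be > -1).
#' @param rule Update rule: `"Bd"` (reproducer fitness-proportional over the
#'   whole population, victim a uniform neighbour) or `"dB"` (victim uniform
#'   over all nodes, parent fitness-proportional among its neighbours).
#' @param init_mutants Optional integer vector of 0-based node ids for an
#'   explicit initial mutant set. Default: a single mutant placed uniformly
#'   at random, independently per replicate.
#' @param init_frequency Optional initial mutant frequency; rounded to a
#'   whole number of nodes, placed uniformly at random per replicate.
#' @param cap Maximum number of events before a run is censored.
#' @return An object of class `moran_config`.
#' @export
moran_config <- function(s = 0.01, rule = c("Bd", "dB"), init_mutants = NULL,
                         init_frequency = NULL, cap = 1e8) {
  rule <- match.arg(rule)
  stopifnot(1 + s > 0, cap > 0)
  if (!is.null(init_mutants) && !is.null(init_frequency))
    stop("give at most one of init_mutants and init_frequency")
  structure(
    list(s = s, rule = rule, init_mutants = init_mutants,
         init_frequency = init_frequency, cap = cap),
    class = "moran_config"
  )
}

resolve_init <- function(config, n) {
  if (!is.null(config$init_mutants)) {
    ids <- as.integer(config$init_mutants)
    stopifnot(all(ids >= 0), all(ids < n), !anyDuplicated(ids))
    return(list(nodes = ids, count = length(ids)))
  }
  count <- if (is.null(config$init_frequency)) 1L
           else as.integer(round(config$init_frequency * n))
  stopifnot(count >= 0, count <= n)
  list(nodes = integer(0), count = count)
}

rule_code <- function(rule) if (rule == "Bd") 0L else 1L

#' Run one Moran replicate to absorption
#'
#' Iterates the chosen update rule until the mutant frequency reaches 0 or
#' 1, or the event cap is hit (outcome `"censored"`).
#'
#' @param graph A connected igraph object.
#' @param config A [moran_config()].
#' @param cadence Events between trajectory records; `NULL` records every N
#'   events. Set `record = FALSE` to skip recording.
#' @param record Logical; record the trajectory of node and edge
#'   frequencies.
#' @param seed Optional integer seed.
#' @param check_interval Internal audit: recount the mixed-edge count from
#'   scratch every this many events (0 = never) and abort on mismatch.
#' @return A list with `outcome` ("fixed", "lost" or "censored"), `events`,
#'   `generations`, and (if recorded) `trajectory`, a data frame with
#'   columns time, p_a, p_Aa, p_AA, p_aa.
#' @export
run_moran <- function(graph, config = moran_config(), cadence = NULL,
                      record = TRUE, seed = NULL, check_interval = 0) {
  if (!is.null(seed)) set.seed(seed)
  validate_graph(graph, connected = TRUE)
  n <- igraph::vcount(graph)
  n_edges <- igraph::ecount(graph)
  init <- resolve_init(config, n)
  if (is.null(cadence)) cadence <- n
  res <- cpp_moran_single(
    as_edge_matrix(graph), n, config$s, rule_code(config$rule), config$cap,
    init$nodes, init$count, if (record) cadence else 0, check_interval
  )
  out <- list(
    outcome = c("lost", "fixed", "censored")[res$outcome + 1L],
    events = res$events, generations = res$events / n
  )
  if (record) {
    p_a <- res$m / n
    p_Aa <- res$mixed / (2 * n_edges)
    # degree-weighted mutant frequency closes the edge-type identities
    # exactly on any graph; it equals p_a on regular graphs
    p_a_deg <- res$sdeg / (2 * n_edges)
    out$trajectory <- data.frame(
      time = res$time, p_a = p_a, p_Aa = p_Aa,
      p_AA = (1 - p_a_deg) - p_Aa, p_aa = p_a_deg - p_Aa
    )
  }
  out
}

#' Monte Carlo estimate of fixation probability and conditional time
#'
#' Runs `n_rep` independent replicates to absorption and aggregates the
#' fixation probability (with its binomial standard error,
#' sqrt(P(1-P)/n)) and the conditional mean fixation time, averaged over
#' fixing runs only, with its sampling error. Censored runs are counted
#' separately and excluded from both estimates.
#'
#' @param graph A connected igraph object.
#' @param config A [moran_config()].
#' @param n_rep Number of Monte Carlo replicates (>= 1).
#' @param seed Optional integer seed.
#' @return An object of class `fixation_estimate`.
#' @export
estimate_fixation <- function(graph, config = moran_config(), n_rep = 10000,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_graph(graph, connected = TRUE)
  stopifnot(n_rep >= 1)
  n <- igraph::vcount(graph)
  init <- resolve_init(config, n)
  res <- cpp_moran_ensemble(
    as_edge_matrix(graph), n, config$s, rule_code(config$rule), n_rep,
    config$cap, init$nodes, init$count
  )
  n_fixed <- length(res$fix_times)
  n_lost <- length(res$loss_times)
  n_done <- n_fixed + n_lost
  prob <- if (n_done > 0) n_fixed / n_done else NA_real_
  structure(
    list(
      n_rep = n_rep, n_fixed = n_fixed, n_lost = n_lost,
      n_censored = res$censored, usable = n_done > 0,
      prob = prob,
      prob_se = if (n_done > 0) mc_standard_error(prob, n_done) else NA_real_,
      time_events = if (n_fixed > 0) mean(res$fix_times) else NA_real_,
      time_se_events = if (n_fixed > 1) sd(res$fix_times) / sqrt(n_fixed)
                       else NA_real_,
      time_generations = if (n_fixed > 0) mean(res$fix_times) / n else NA_real_,
      n_nodes = n, s = config$s, rule = config$rule
    ),
    class = "fixation_estimate"
  )
}

#' @export
print.fixation_estimate <- function(x, ...) {
  cat(sprintf(
    "Moran %s fixation estimate (N = %d, s = %g, %d replicates)\n",
    x$rule, x$n_nodes, x$s, x$n_rep
  ))
  cat(sprintf("  fixed %d / lost %d / censored %d\n",
              x$n_fixed, x$n_lost, x$n_censored))
  cat(sprintf("  P(fix) = %.6f (SE %.6f)\n", x$prob, x$prob_se))
  if (!is.na(x$time_events))
    cat(sprintf(
      "  conditional fixation time = %.0f events = %.1f generations (SE %.0f events)\n",
      x$time_events, x$time_generations, x$time_se_events
    ))
  invisible(x)
}

#' Ensemble-mean frequency trajectories
#'
#' Means of the mutant node frequency p_a and mixed-edge frequency p_Aa
#' over replicates, by default conditioned on fixation, recorded on a fixed
#' event cadence, together with the mixed-edge ratio p_Aa/(p_A p_a)
#' aggregated by mutant count (whose mid-frequency plateau estimates the
#' pair-approximation acceleration factor 1 - F).
#'
#' @inheritParams estimate_fixation
#' @param cadence Events between records; `NULL` uses N.
#' @param condition_on_fixation Keep only replicates that fix.
#' @return An object of class `trajectory_record`: a list with `mean`, a
#'   data frame (time, p_a, p_Aa, p_AA, p_aa, n), and `ratio`, a data frame
#'   (p_a, ratio, n).
#' @export
record_mean_trajectories <- function(graph, config = moran_config(),
                                     n_rep = 1000, cadence = NULL,
                                     condition_on_fixation = TRUE,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_graph(graph, connected = TRUE)
  n <- igraph::vcount(graph)
  if (is.null(cadence)) cadence <- n
  res <- cpp_moran_trajectories(
    as_edge_matrix(graph), n, config$s, rule_code(config$rule), n_rep,
    config$cap, cadence, condition_on_fixation
  )
  mean_df <- data.frame(
    time = res$time, p_a = res$p_a, p_Aa = res$p_Aa,
    p_AA = (1 - res$p_a_deg) - res$p_Aa, p_aa = res$p_a_deg - res$p_Aa,
    n = res$n
  )
  m <- seq(0, n)
  keep <- !is.na(res$ratio_mean)
  ratio_df <- data.frame(
    p_a = m[keep] / n, ratio = res$ratio_mean[keep], n = res$ratio_n[keep]
  )
  structure(
    list(mean = mean_df, ratio = ratio_df, runs_used = res$runs_used,
         n_rep = n_rep, censored = res$censored,
         condition_on_fixation = condition_on_fixation),
    class = "trajectory_record"
  )
}

#' Mid-sweep mixed-edge ratio plateau
#'
#' Average of the conditioned ensemble ratio p_Aa/(p_A p_a) over the
#' mid-frequency band of a [record_mean_trajectories()] result; under the
#' pair approximation this plateaus at the acceleration factor 1 - F.
#'
#' @param record A `trajectory_record`.
#' @param band Inclusive p_a range to average over.
#' @return Weighted mean ratio across the band.
#' @export
ratio_plateau <- function(record, band = c(0.3, 0.7)) {
  stopifnot(inherits(record, "trajectory_record"))
  r <- record$ratio
  sel <- r$p_a >= band[1] & r$p_a <= band[2]
  if (!any(sel)) stop("no recorded points in the requested band")
  sum(r$ratio[sel] * r$n[sel]) / sum(r$n[sel])
}
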