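# Pair-approximation and diffusion theory.
#
# On a k-regular graph with triangle fraction phi, the mixed-edge frequency
# equilibrates at p_Aa* = (1 - F) p_A p_a with the inbreeding-like parameter
# F = 1/((k - 1)(1 - phi)). The diffusion solution for the fixation
# probability is the well-mixed one (regular graphs are isothermal), while
# the conditional fixation time is inflated by 1/(1 - F).

#' Inbreeding-like parameter F and acceleration factor
#'
#' F = 1 / ((k - 1)(1 - phi)). The acceleration factor 1 - F is the ratio
#' of the well-mixed conditional fixation time to the structured one; it
#' cannot exceed one on regular graphs, and F >= 1 marks the regime in
#' which the pair-approximation fixation time diverges (flagged, never
#' silent).
#'
#' @param k Node degree (>= 2).
#' @param phi Triangle fraction in \[0, 1); `phi = 1` is an error (the pair
#'   approximation is undefined).
#' @return A list with `F`, `acceleration` (1 - F) and `diverges`
#'   (TRUE when F >= 1). Vectorised over `k` and `phi`.
#' @export
inbreeding_F <- function(k, phi) {
  stopifnot(all(k >= 2), all(phi >= 0))
  if (any(phi >= 1)) stop("pair approximation undefined for phi = 1")
  f <- 1 / ((k - 1) * (1 - phi))
  list(F = f, acceleration = 1 - f, diverges = f >= 1)
}

#' Pair-approximation drift terms
#'
#' Expected one-generation changes of the mutant node frequency,
#' s/w * p_Aa with w = 1 + s p_a, and the leading (selection-independent)
#' term of the mixed-edge frequency drift,
#' (p_Aa/k) \[(k-1)(1-phi)(1 - p_Aa/(p_A p_a)) - 1\]. The O(s) remainder of
#' the edge drift is excluded by contract; its root at
#' p_Aa = (1 - F) p_A p_a is the quasi-equilibrium the timescale-separation
#' argument rests on.
#'
#' @param p_a Mutant frequency in \[0, 1\].
#' @param p_Aa Mixed-edge (ordered-pair) frequency; must be 0 at the
#'   absorbing boundaries.
#' @param k,phi Pair-approximation parameters, as in [inbreeding_F()].
#' @param s Selection coefficient.
#' @return A list with `dp_a` and `dp_Aa_leading`.
#' @export
drift_terms <- function(p_a, p_Aa, k, phi, s) {
  stopifnot(all(p_a >= 0), all(p_a <= 1), all(p_Aa >= 0))
  if (any(p_Aa > pmin(p_a, 1 - p_a) + 1e-12))
    stop("p_Aa must not exceed min(p_a, 1 - p_a)")
  len <- max(length(p_a), length(p_Aa))
  p_a <- rep_len(p_a, len)
  p_Aa <- rep_len(p_Aa, len)
  w <- 1 + s * p_a
  dp_a <- s / w * p_Aa
  interior <- p_Aa > 0
  edge <- numeric(len)
  if (any(interior)) {
    pa <- p_a[interior]
    paa <- p_Aa[interior]
    edge[interior] <- paa / k *
      ((k - 1) * (1 - phi) * (1 - paa / ((1 - pa) * pa)) - 1)
  }
  list(dp_a = dp_a, dp_Aa_leading = edge)
}

#' Diffusion fixation probability on a regular graph
#'
#' P(p0) = (1 - exp(-N s p0)) / (1 - exp(-N s)), the weak-selection
#' diffusion solution, identical to the well-mixed population (regular
#' graphs are isothermal); independent of the higher-order structure. The
#' s = 0 singularity is resolved analytically (limit p0).
#'
#' @param N Population size (>= 2).
#' @param s Selection coefficient.
#' @param p0 Initial mutant frequency in \[0, 1\]; default a single mutant.
#' @return Fixation probability.
#' @export
fixation_prob_regular <- function(N, s, p0 = 1 / N) {
  stopifnot(N >= 2, all(p0 >= 0), all(p0 <= 1))
  if (s == 0) return(p0 + 0 * N)
  expm1(-N * s * p0) / expm1(-N * s)
}

#' Diffusion fixation probability with an amplification factor
#'
#' P = (1 - exp(-alpha s)) / (1 - exp(-N alpha s)) for a single-mutant
#' start; alpha is the effective selection multiplier of a
#' degree-heterogeneous graph (alpha = 1 recovers the regular-graph
#' formula). For the death-Birth rule on graphs without triangles alpha is
#' given by [db_amplification()]; amplification factors derived elsewhere
#' can be plugged in directly.
#'
#' @param N Population size.
#' @param s Selection coefficient.
#' @param alpha Amplification factor (> 0).
#' @return Fixation probability of a single mutant.
#' @export
fixation_prob_amplified <- function(N, s, alpha = 1) {
  stopifnot(N >= 2, all(alpha > 0))
  if (s == 0) return(1 / N + 0 * alpha)
  expm1(-alpha * s) / expm1(-N * alpha * s)
}

#' death-Birth amplification factor from the degree distribution
#'
#' alpha = (E\[i\])^2 / E\[i^2\], the expectation over the node degree i.
#' Equals 1 for regular graphs and 0.8 for the half degree-12, half
#' degree-4 population.
#'
#' @param degrees Vector of node degrees (one entry per node), or an
#'   igraph object.
#' @return The amplification factor in (0, 1\].
#' @export
db_amplification <- function(degrees) {
  if (igraph::is_igraph(degrees)) degrees <- igraph::degree(degrees)
  stopifnot(length(degrees) > 0, all(degrees > 0))
  mean(degrees)^2 / mean(degrees^2)
}

#' Exact well-mixed conditional fixation time
#'
#' Conditional mean absorption time of the (N+1)-state well-mixed Moran
#' frequency chain, computed by the Doob h-transformed linear solve (not
#' the diffusion approximation). Time is counted in elementary Moran
#' events; divide by N for generations.
#'
#' @param N Population size (>= 2).
#' @param s Selection coefficient.
#' @param p0 Initial mutant frequency in (0, 1\]; `p0 * N` must be a whole
#'   number of mutants. Default a single mutant.
#' @param unit `"events"` or `"generations"`.
#' @return Conditional mean fixation time.
#' @export
wellmixed_conditional_time <- function(N, s, p0 = 1 / N,
                                       unit = c("events", "generations")) {
  unit <- match.arg(unit)
  stopifnot(N >= 2, 1 + s > 0)
  i0 <- p0 * N
  if (abs(i0 - round(i0)) > 1e-8 || round(i0) < 1 || round(i0) > N)
    stop("p0 must correspond to a whole number of mutants in (0, N]")
  i0 <- as.integer(round(i0))
  if (i0 == N) return(0)

  i <- seq_len(N - 1)
  # one-event transition probabilities of the frequency chain (complete graph)
  up <- (1 + s) * i * (N - i) / ((N + s * i) * (N - 1))
  dn <- i * (N - i) / ((N + s * i) * (N - 1))
  pi_i <- if (s == 0) i / N else expm1(-i * log1p(s)) / expm1(-N * log1p(s))
  pi_up <- c(pi_i[-1], 1)  # pi_{i+1}
  pi_dn <- c(0, pi_i[-(N - 1)])  # pi_{i-1}, with pi_0 = 0

  up_t <- up * pi_up / pi_i
  dn_t <- dn * pi_dn / pi_i
  a_mat <- diag(up_t + dn_t, N - 1)
  if (N > 2) {
    a_mat[cbind(i[-(N - 1)], i[-(N - 1)] + 1)] <- -up_t[-(N - 1)]
    a_mat[cbind(i[-1], i[-1] - 1)] <- -dn_t[-1]
  }
  t_vec <- solve(a_mat, rep(1, N - 1))
  out <- t_vec[i0]
  if (unit == "generations") out / N else out
}

#' Pair-approximation conditional fixation time on a regular graph
#'
#' T = T_wm / (1 - F): the exact well-mixed conditional time inflated by
#' the acceleration factor. Errors when F >= 1 (time divergence regime).
#'
#' @inheritParams wellmixed_conditional_time
#' @param k,phi Pair-approximation parameters, as in [inbreeding_F()].
#' @return Conditional mean fixation time.
#' @export
conditional_time_regular <- function(N, s, k, phi, p0 = 1 / N,
                                     unit = c("events", "generations")) {
  fa <- inbreeding_F(k, phi)
  if (any(fa$diverges))
    stop("F >= 1: pair-approximation fixation time diverges")
  wellmixed_conditional_time(N, s, p0, unit) / fa$acceleration
}

#' Binomial standard error of a Monte Carlo fixation probability
#'
#' sqrt(P (1 - P) / n), the standard error of an `n`-replicate Bernoulli
#' estimate.
#'
#' @param p_mc Estimated probability in \[0, 1\].
#' @param n_mc Number of Monte Carlo replicates (>= 1).
#' @return Standard error.
#' @export
mc_standard_error <- function(p_mc, n_mc) {
  stopifnot(all(p_mc >= 0), all(p_mc <= 1), all(n_mc >= 1))
  sqrt(p_mc * (1 - p_mc) / n_mc)
}
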