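test_that("inbreeding_F evaluates Eq-5 style cases and flags divergence", {
  fa <- inbreeding_F(5, 0)
  expect_equal(fa$F, 0.25)
  expect_equal(fa$acceleration, 0.75)
  expect_false(fa$diverges)

  fa <- inbreeding_F(5, 0.5)
  expect_equal(fa$F, 0.5)
  expect_equal(fa$acceleration, 0.5)

  fa <- inbreeding_F(2, 0)  # cycle graph: boundary of validity
  expect_equal(fa$F, 1)
  expect_true(fa$diverges)

  expect_error(inbreeding_F(5, 1), "undefined")
})

test_that("drift terms vanish at the pair-approximation fixed point", {
  # neutral: no node drift regardless of state
  d <- drift_terms(0.4, 0.2, k = 5, phi = 0.2, s = 0)
  expect_equal(d$dp_a, 0)

  # the leading edge drift is zero exactly at p_Aa = (1 - F) p_A p_a
  for (k in c(3, 5, 8)) for (phi in c(0, 0.3, 0.6)) {
    f <- inbreeding_F(k, phi)$F
    if (f >= 1) next  # divergent regime: no admissible fixed point
    for (pa in seq(0.05, 0.95, by = 0.09)) {
      paa <- (1 - f) * (1 - pa) * pa
      d <- drift_terms(pa, paa, k, phi, s = 0.01)
      expect_equal(d$dp_Aa_leading, 0, tolerance = 1e-12)
    }
  }

  # uncorrelated edges with k=5, phi=0 decay at rate 1/5
  pa <- 0.3
  paa <- (1 - pa) * pa
  d <- drift_terms(pa, paa, 5, 0, s = 0)
  expect_equal(d$dp_Aa_leading, -paa / 5)

  expect_error(drift_terms(1, 0.1, 5, 0, 0.01), "p_Aa")
})

test_that("regular-graph fixation probability has the right limits and values", {
  expect_equal(fixation_prob_regular(100, 0, 0.37), 0.37)
  expect_equal(fixation_prob_regular(100, 0.01, 1 / 100), 0.0157409,
               tolerance = 1e-5)
  expect_equal(fixation_prob_regular(50, 0.3, 1), 1)
  # strictly increasing in s and p0
  ps <- sapply(c(0.001, 0.01, 0.05, 0.2), fixation_prob_regular, N = 100,
               p0 = 0.01)
  expect_true(all(diff(ps) > 0))
  pp <- sapply(c(0.01, 0.1, 0.5, 0.9), function(p0)
    fixation_prob_regular(100, 0.02, p0))
  expect_true(all(diff(pp) > 0))
})

test_that("amplified fixation probability reduces and evaluates correctly", {
  expect_equal(fixation_prob_amplified(100, 0.01, 1),
               fixation_prob_regular(100, 0.01, 1 / 100))
  expect_equal(fixation_prob_amplified(100, 0.01, 0.8), 0.01446977,
               tolerance = 1e-6)
  expect_equal(fixation_prob_amplified(100, 0, 0.8), 1 / 100)
})

test_that("db_amplification follows the degree-moment formula", {
  expect_equal(db_amplification(rep(5, 40)), 1)
  expect_equal(db_amplification(rep(c(12, 4), each = 50)), 0.8)
  expect_equal(db_amplification(rep(7, 1)), 1)
  g <- build_two_class_graph(50, 12, 50, 4, r_target = NULL, seed = 91)
  expect_equal(db_amplification(g), 0.8)
})

test_that("well-mixed conditional time solves the h-transformed chain exactly", {
  expect_equal(wellmixed_conditional_time(3, 0, 1 / 3), 4, tolerance = 1e-12)
  expect_equal(wellmixed_conditional_time(10, 0.1, 1), 0)
  expect_error(wellmixed_conditional_time(10, 0.1, 0), "whole number")

  # independent construction: 2^N configuration-space solve on K_N
  for (n in c(4, 6, 8)) for (s in c(0, 0.1)) {
    ex <- exact_fixation(igraph::make_full_graph(n), s, "Bd")
    expect_equal(wellmixed_conditional_time(n, s, 1 / n), ex$time_uniform,
                 tolerance = 1e-8)
  }
  expect_equal(wellmixed_conditional_time(6, 0.05, 1 / 6, "generations"),
               wellmixed_conditional_time(6, 0.05, 1 / 6) / 6)
})

test_that("conditional time on regular graphs scales by 1/(1 - F)", {
  twm <- wellmixed_conditional_time(100, 0.01, 1 / 100)
  expect_equal(conditional_time_regular(100, 0.01, 5, 0), twm / 0.75)
  expect_equal(conditional_time_regular(100, 0.01, 3, 0), 2 * twm)
  # the phi-ratio is independent of (N, s, p0): k=5 gives 1.5 at phi 0 vs 0.5
  for (N in c(40, 100)) for (s in c(0.005, 0.05)) {
    r <- conditional_time_regular(N, s, 5, 0.5) /
      conditional_time_regular(N, s, 5, 0)
    expect_equal(r, 1.5, tolerance = 1e-12)
  }
  # strictly increasing in phi
  ts <- sapply(c(0, 0.2, 0.4, 0.6), function(phi)
    conditional_time_regular(100, 0.01, 5, phi))
  expect_true(all(diff(ts) > 0))
  expect_error(conditional_time_regular(100, 0.01, 2, 0.5), "diverges")
})

test_that("Monte Carlo standard error follows the Bernoulli formula", {
  expect_equal(mc_standard_error(0, 100), 0)
  expect_equal(mc_standard_error(1, 100), 0)
  expect_equal(mc_standard_error(0.5, 10000), 0.005)
  expect_equal(mc_standard_error(0.01574, 1e7),
               sqrt(0.01574 * 0.98426 / 1e7))
})
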