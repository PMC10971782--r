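test_that("absorbing starts terminate immediately", {
  g <- random_regular(10, 3, seed = 71)
  all_mut <- run_moran(g, moran_config(init_mutants = 0:9), seed = 72)
  expect_equal(all_mut$outcome, "fixed")
  expect_equal(all_mut$events, 0)
  none <- run_moran(g, moran_config(init_frequency = 0), seed = 73)
  expect_equal(none$outcome, "lost")
  expect_equal(none$events, 0)
})

test_that("strong selection on a two-node path fixes in one event", {
  g <- path_graph(2)
  r <- run_moran(g, moran_config(s = 1e9, rule = "Bd", init_mutants = 0),
                 seed = 74)
  expect_equal(r$outcome, "fixed")
  expect_lte(r$events, 2)
})

test_that("trajectory bookkeeping keeps the edge-frequency identities exact", {
  # on a regular graph the identities close with the node frequency itself
  g <- random_regular(12, 4, seed = 75)
  set.seed(175)
  # check_interval forces a from-scratch recount of the mixed-edge count
  r <- run_moran(g, moran_config(s = 0.1), cadence = 1, check_interval = 1)
  tr <- r$trajectory
  expect_equal(tr$p_AA, (1 - tr$p_a) - tr$p_Aa)
  expect_equal(tr$p_aa, tr$p_a - tr$p_Aa)
  expect_true(all(tr$p_AA >= -1e-12 & tr$p_aa >= -1e-12))
  expect_true(all(abs(diff(tr$p_a)) <= 1 / igraph::vcount(g) + 1e-12))
  # frequencies live on the 1/N lattice
  expect_true(all(abs(tr$p_a * igraph::vcount(g) -
                        round(tr$p_a * igraph::vcount(g))) < 1e-9))
  # mixed edges vanish at fixation
  if (r$outcome == "fixed") expect_equal(tr$p_Aa[nrow(tr)], 0)

  # on a heterogeneous graph the edge-type fractions stay well formed
  set.seed(76)
  gh <- random_connected_graph(12, 0.4)
  rh <- run_moran(gh, moran_config(s = 0.1), cadence = 1, check_interval = 1)
  th <- rh$trajectory
  expect_true(all(th$p_AA >= -1e-12 & th$p_aa >= -1e-12))
  expect_equal(th$p_AA + th$p_aa + 2 * th$p_Aa, rep(1, nrow(th)))
})

test_that("neutral fixation probability is 1/N on regular graphs, both rules", {
  g <- random_regular(50, 5, seed = 76)
  for (rule in c("Bd", "dB")) {
    est <- estimate_fixation(g, moran_config(s = 0, rule = rule),
                             n_rep = 20000, seed = 77)
    expect_lte(abs(est$prob - 1 / 50), 4 * est$prob_se)
  }
})

test_that("censored runs are reported separately, never folded in", {
  g <- random_regular(50, 5, seed = 78)
  est <- estimate_fixation(g, moran_config(s = 0, cap = 10), n_rep = 200,
                           seed = 79)
  expect_gt(est$n_censored, 0)
  expect_equal(est$n_fixed + est$n_lost + est$n_censored, 200)
  if (est$n_fixed + est$n_lost > 0)
    expect_equal(est$prob, est$n_fixed / (est$n_fixed + est$n_lost))
})

test_that("Bd and dB coincide on complete graphs at neutrality and stay
           close under selection", {
  # neutral one-step frequency-chain transitions agree exactly; under
  # selection the dB parent pool excludes the vacated node, an O(s/N)
  # difference that vanishes in the well-mixed limit
  exb <- exact_fixation(igraph::make_full_graph(5), 0, "Bd")
  exd <- exact_fixation(igraph::make_full_graph(5), 0, "dB")
  expect_equal(exb$prob_uniform, exd$prob_uniform, tolerance = 1e-10)
  expect_equal(exb$time_uniform, exd$time_uniform, tolerance = 1e-10)

  exb <- exact_fixation(igraph::make_full_graph(10), 0.1, "Bd")
  exd <- exact_fixation(igraph::make_full_graph(10), 0.1, "dB")
  expect_equal(exb$prob_uniform, exd$prob_uniform, tolerance = 0.05)
  expect_equal(exb$time_uniform, exd$time_uniform, tolerance = 0.05)
})

test_that("exact solver reproduces hand-solved values and the isothermal law", {
  ex <- exact_fixation(igraph::make_full_graph(3), 0, "Bd")
  expect_equal(ex$prob_uniform, 1 / 3, tolerance = 1e-12)
  expect_equal(ex$time_uniform, 4, tolerance = 1e-10)

  # uniform-start neutral probability is exactly 1/N on any connected graph
  set.seed(80)
  g <- random_connected_graph(7, 0.5)
  for (rule in c("Bd", "dB")) {
    ex <- exact_fixation(g, 0, rule)
    expect_equal(ex$prob_uniform, 1 / 7, tolerance = 1e-10)
  }
  # isothermal: regular graph, any s, equals the well-mixed probability
  g <- random_regular(8, 3, seed = 81)
  ex <- exact_fixation(g, 0.2, "Bd")
  rho <- expm1(-log1p(0.2)) / expm1(-8 * log1p(0.2))
  expect_equal(ex$prob_uniform, rho, tolerance = 1e-9)

  expect_error(exact_fixation(random_regular(16, 3), 0.1), "state space")
})

test_that("Monte Carlo matches the exact solver on random small graphs", {
  set.seed(82)
  svals <- c(0, 0.05, 0.2)
  for (i in 1:6) {
    g <- random_connected_graph(sample(5:8, 1), 0.45)
    s <- svals[(i %% 3) + 1]
    rule <- if (i %% 2 == 0) "Bd" else "dB"
    ex <- exact_fixation(g, s, rule)
    mc <- estimate_fixation(g, moran_config(s = s, rule = rule), n_rep = 20000)
    expect_lte(abs(mc$prob - ex$prob_uniform), 4 * mc$prob_se)
    expect_lte(abs(mc$time_events - ex$time_uniform), 4 * mc$time_se_events)
  }
})

test_that("mean trajectories condition on fixation and report the ratio curve", {
  g <- random_regular(30, 4, seed = 83)
  tr <- record_mean_trajectories(g, moran_config(s = 0.1), n_rep = 2000,
                                 seed = 84)
  expect_gt(tr$runs_used, 0)
  expect_lt(tr$runs_used, 2000)
  expect_equal(tr$mean$p_AA, (1 - tr$mean$p_a) - tr$mean$p_Aa)
  # conditioned trajectories end in fixation: p_a climbs toward 1
  expect_gt(max(tr$mean$p_a), 0.9)
  expect_true(all(tr$ratio$ratio >= 0))
  expect_true(all(tr$ratio$p_a > 0 & tr$ratio$p_a < 1))
})
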