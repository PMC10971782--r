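test_that("random_regular builds connected k-regular graphs and checks feasibility", {
  g <- random_regular(4, 3, seed = 1)
  expect_equal(igraph::ecount(g), 6)  # the unique 3-regular graph on 4 nodes
  expect_equal(unname(igraph::degree(g)), rep(3, 4))

  g <- random_regular(100, 5, seed = 2)
  expect_equal(unname(igraph::degree(g)), rep(5, 100))
  expect_true(is_connected_graph(g))

  expect_error(random_regular(5, 3), "even")
  expect_error(random_regular(4, 4), "smaller than n")
})

test_that("generators are reproducible from a seed", {
  g1 <- random_regular(60, 4, seed = 11)
  g2 <- random_regular(60, 4, seed = 11)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))

  t1 <- suppressWarnings(tune_transitivity_regular(g1, 0.2, seed = 12))
  t2 <- suppressWarnings(tune_transitivity_regular(g2, 0.2, seed = 12))
  expect_identical(igraph::as_edgelist(t1), igraph::as_edgelist(t2))
})

test_that("tune_transitivity_regular reaches the target and conserves structure", {
  g <- random_regular(100, 5, seed = 21)
  gt <- tune_transitivity_regular(g, 0.3, seed = 22)
  expect_lte(abs(graph_transitivity(gt) - 0.3), 0.02)
  expect_equal(unname(igraph::degree(gt)), rep(5, 100))
  expect_true(is_connected_graph(gt))

  # K4 admits no swap: phi stays 1, with a warning rather than silence
  expect_warning(tk4 <- tune_transitivity_regular(k4(), 0.2,
                                                  anneal_config(budget = 100)))
  expect_equal(graph_transitivity(tk4), 1)

  expect_error(tune_transitivity_regular(
    build_two_class_graph(10, 4, 10, 2, r_target = NULL, seed = 1), 0.2
  ), "not regular")
})

test_that("annealed chain concentrates at the target under a tight width
           and wanders under a loose one", {
  g <- random_regular(60, 4, seed = 31)
  cfg_tight <- anneal_config(sigma0 = 0.004, sigma_growth = 1,
                             budget = 3e5, stop_tol = NULL)
  set.seed(32)
  gt <- suppressWarnings(
    tune_transitivity_regular(g, 0.25, cfg_tight, trace_interval = 500)
  )
  tr_tight <- attr(gt, "anneal")$trace
  late <- tr_tight[seq(length(tr_tight) / 2, length(tr_tight))]
  expect_lt(mean(abs(late - 0.25)), 0.05)

  cfg_loose <- anneal_config(sigma0 = 5, sigma_growth = 1,
                             budget = 3e5, stop_tol = NULL)
  set.seed(33)
  gl <- suppressWarnings(
    tune_transitivity_regular(g, 0.25, cfg_loose, trace_interval = 500)
  )
  tr_loose <- attr(gl, "anneal")$trace
  # loose acceptance is a near-uniform walk: it hugs the entropic bulk at
  # low phi instead of the target
  expect_gt(mean(abs(tr_loose - 0.25)), mean(abs(late - 0.25)))
})

test_that("build_two_class_graph realises the degree histogram", {
  g <- build_two_class_graph(50, 12, 50, 4, r_target = 0, seed = 41)
  deg <- igraph::degree(g)
  expect_equal(sort(unique(deg)), c(4, 12))
  expect_equal(sum(deg == 12), 50)
  expect_equal(sum(deg == 4), 50)
  expect_equal(mean(deg), 8)
  expect_equal(sqrt(mean((deg - 8)^2)), 4)  # population sd over nodes
  expect_true(is_connected_graph(g))
  expect_lte(abs(graph_assortativity(g)), 0.02)

  # degenerate classes reduce to a regular graph
  g <- build_two_class_graph(50, 5, 50, 5, seed = 42)
  expect_equal(unname(igraph::degree(g)), rep(5, 100))

  expect_error(build_two_class_graph(3, 3, 4, 2), "even")
})

test_that("tune_assortativity spans targets and refuses regular graphs", {
  g <- build_two_class_graph(50, 12, 50, 4, r_target = NULL, seed = 51)
  deg0 <- sort(igraph::degree(g))
  for (rt in c(-0.3, 0, 0.5)) {
    gt <- tune_assortativity(g, rt, seed = 52)
    expect_lte(abs(graph_assortativity(gt) - rt), 0.02)
    expect_equal(sort(igraph::degree(gt)), deg0)
    expect_true(is_connected_graph(gt))
  }
  # pushing to the maximum drives cross-class edges to the feasible floor
  gmax <- suppressWarnings(
    tune_assortativity(g, 1, anneal_config(budget = 2e5, stop_tol = NULL),
                       seed = 53)
  )
  j <- count_motifs(gmax)$joint_degrees
  expect_lte(j["4", "12"], count_motifs(g)$joint_degrees["4", "12"])
  expect_gt(graph_assortativity(gmax), 0.8)

  expect_error(tune_assortativity(random_regular(20, 3), 0),
               "undefined for regular")
})

test_that("tune_transitivity_2k conserves J exactly while moving phi", {
  g <- build_two_class_graph(50, 12, 50, 4, r_target = 0, seed = 61)
  j0 <- count_motifs(g)$joint_degrees
  r0 <- graph_assortativity(g)
  gt <- tune_transitivity_2k(g, 0.25, seed = 62)
  expect_lte(abs(graph_transitivity(gt) - 0.25), 0.02)
  expect_identical(count_motifs(gt)$joint_degrees, j0)
  expect_equal(graph_assortativity(gt), r0)
  expect_true(is_connected_graph(gt))
})
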