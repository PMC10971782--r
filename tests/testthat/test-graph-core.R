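test_that("count_motifs matches hand-enumerated examples", {
  p <- count_motifs(k4())
  expect_equal(p$triangles, 4)
  expect_equal(p$wedges, 12)
  expect_equal(p$transitivity, 1)

  p <- count_motifs(c5())
  expect_equal(p$triangles, 0)
  expect_equal(p$transitivity, 0)

  # K4 minus one edge: two triangles survive, 8 wedges
  g <- igraph::delete_edges(k4(), 1)
  p <- count_motifs(g)
  expect_equal(p$triangles, 2)
  expect_equal(p$wedges, 8)
  expect_equal(p$transitivity, 0.75)

  expect_error(count_motifs(igraph::make_empty_graph(0, directed = FALSE)),
               "no nodes")
})

test_that("count_motifs agrees with brute-force triple enumeration", {
  set.seed(401)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.25, 0.8))
    p <- count_motifs(g)
    o <- brute_force_motifs(g)
    expect_equal(p$triangles, o$triangles)
    expect_equal(p$wedges, o$wedges)
    expect_equal(p$transitivity, o$phi)
    expect_equal(p$assortativity, brute_force_assortativity(g))
    # joint degree matrix sums to the edge count over i <= j
    expect_equal(sum(p$joint_degrees), p$n_edges)
  }
})

test_that("assortativity endpoints behave as defined", {
  expect_equal(graph_assortativity(star5()), -1)
  expect_true(is.na(graph_assortativity(c5())))  # regular: undefined, not 0
  expect_true(is.na(graph_assortativity(k4())))
  # perfectly assortative: only within-class edges
  g <- igraph::disjoint_union(k4(), c5())
  g <- igraph::add_edges(g, c(1, 5))  # connect so validity holds
  expect_gt(graph_assortativity(g), 0.4)
})

test_that("is_connected_graph distinguishes components", {
  expect_true(is_connected_graph(c5()))
  expect_true(is_connected_graph(path_graph(5)))
  expect_false(is_connected_graph(
    igraph::disjoint_union(igraph::make_full_graph(3), igraph::make_full_graph(3))
  ))
})

test_that("double_edge_swap conserves degrees and rejects invalid proposals", {
  set.seed(402)
  g <- random_connected_graph(10, 0.35)
  deg0 <- igraph::degree(g)
  el <- igraph::as_edgelist(g, names = FALSE) - 1L
  # find two endpoint-disjoint edges whose cross swap is admissible
  done <- FALSE
  for (i in seq_len(nrow(el) - 1)) {
    for (j in seq(i + 1, nrow(el))) {
      e1 <- el[i, ]; e2 <- el[j, ]
      if (length(unique(c(e1, e2))) < 4) next
      g2 <- tryCatch(double_edge_swap(g, e1, e2),
                     evomotif_swap_rejected = function(e) NULL)
      if (!is.null(g2)) {
        expect_equal(igraph::degree(g2), deg0)
        expect_equal(igraph::ecount(g2), igraph::ecount(g))
        expect_true(all(igraph::count_multiple(g2) == 1))
        done <- TRUE
        break
      }
    }
    if (done) break
  }
  expect_true(done)

  # complete graph admits no swap: every proposal makes a parallel edge
  expect_error(double_edge_swap(k4(), c(0, 1), c(2, 3)),
               class = "evomotif_swap_rejected")
  # shared endpoint is a rejection, not an error
  g <- c5()
  expect_error(double_edge_swap(g, c(0, 1), c(1, 2)),
               class = "evomotif_swap_rejected")
})

test_that("two_k_swap conserves the joint degree matrix and checks types", {
  set.seed(403)
  # half degree-3, half degree-1: star of 3 + pendant chain gives mixed types
  g <- build_two_class_graph(6, 4, 8, 2, r_target = NULL, seed = 403)
  j0 <- count_motifs(g)$joint_degrees
  deg <- igraph::degree(g)
  el <- igraph::as_edgelist(g, names = FALSE) - 1L
  types <- paste(pmin(deg[el[, 1] + 1], deg[el[, 2] + 1]),
                 pmax(deg[el[, 1] + 1], deg[el[, 2] + 1]))
  done <- FALSE
  for (i in seq_len(nrow(el) - 1)) {
    for (j in seq(i + 1, nrow(el))) {
      if (types[i] != types[j]) next
      if (length(unique(c(el[i, ], el[j, ]))) < 4) next
      g2 <- tryCatch(two_k_swap(g, el[i, ], el[j, ]),
                     evomotif_swap_rejected = function(e) NULL)
      if (!is.null(g2)) {
        expect_equal(count_motifs(g2)$joint_degrees, j0)
        expect_equal(sort(igraph::degree(g2)), sort(deg))
        done <- TRUE
        break
      }
    }
    if (done) break
  }
  expect_true(done)

  # edges of different type are a hard error, not a rejection
  j <- which(types != types[1])[1]
  expect_error(two_k_swap(g, el[1, ], el[j, ]), "type mismatch")
})

test_that("transitivity stays in [0,1] and J is conserved across long 2K runs", {
  set.seed(404)
  g <- build_two_class_graph(20, 6, 20, 3, r_target = 0,
                             config = anneal_config(budget = 2000))
  j0 <- count_motifs(g)$joint_degrees
  for (tgt in c(0.3, 0.05)) {
    g <- suppressWarnings(
      tune_transitivity_2k(g, tgt, anneal_config(budget = 3000))
    )
    phi <- graph_transitivity(g)
    expect_gte(phi, 0)
    expect_lte(phi, 1)
    expect_equal(count_motifs(g)$joint_degrees, j0)
  }
})
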