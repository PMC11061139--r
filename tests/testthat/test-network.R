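test_that("directed_network validates simplicity", {
  expect_error(directed_network(3, rbind(c(1, 1))), "self-loops")
  expect_error(directed_network(3, rbind(c(1, 2), c(1, 2))), "duplicate")
  expect_error(directed_network(3, rbind(c(1, 4))), "endpoints")
  net <- directed_network(3, rbind(c(1, 2), c(2, 3)))
  expect_equal(degree_sequences(net), list(out = c(1L, 1L, 0L),
                                           in_ = c(0L, 1L, 1L)))
})

test_that("unique stream keeps the first occurrence of each ordered pair in order", {
  ab3 <- edge_stream_fixture(rbind(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(nrow(unique_interaction_stream(ab3)), 1)
  both <- unique_interaction_stream(edge_stream_fixture(rbind(c(1, 2), c(2, 1))))
  expect_equal(both$interactor, c(1, 2))
  expect_equal(both$interactee, c(2, 1))
  empty <- unique_interaction_stream(edge_stream_fixture(matrix(0, 0, 2)))
  expect_equal(nrow(empty), 0)
  # order preserved, later repeats dropped
  st <- unique_interaction_stream(edge_stream_fixture(
    rbind(c(3, 4), c(1, 2), c(3, 4), c(2, 1), c(1, 2), c(5, 6))))
  expect_equal(st$interactor, c(3, 1, 2, 5))
  expect_equal(st$interactee, c(4, 2, 1, 6))
})

test_that("boxcar windows slide one unique edge at a time", {
  edges33 <- random_digraph_edges(12, 33)
  nets <- boxcar_networks(edge_stream_fixture(edges33), window_size = 33)
  expect_length(nets, 1)
  expect_equal(nrow(nets[[1]]$edges), 33)

  edges34 <- random_digraph_edges(12, 34)
  nets <- boxcar_networks(edge_stream_fixture(edges34), window_size = 33)
  expect_length(nets, 2)
  # the second iteration ignores the first unique interaction and adds the next
  expect_equal(nets[[2]]$edges, matrix(as.integer(edges34[2:34, ]), ncol = 2,
                                       dimnames = NULL))
  expect_warning(
    out <- boxcar_networks(edge_stream_fixture(random_digraph_edges(12, 10))),
    "too sparse")
  expect_length(out, 0)
})

test_that("betweenness matches hand values and the path-counting oracle", {
  path <- directed_network(3, rbind(c(1, 2), c(2, 3)))
  expect_equal(betweenness_centrality(path), c(0, 1, 0))

  # a node bridging two clusters is the gatekeeper with the highest BC
  clique <- function(ids) { g <- expand.grid(ids, ids); as.matrix(g[g[, 1] != g[, 2], ]) }
  bridge <- directed_network(9, rbind(clique(1:4), clique(6:9),
                                      c(4, 5), c(5, 4), c(5, 6), c(6, 5)))
  bc <- betweenness_centrality(bridge)
  expect_true(all(bc[5] > bc[-5]))

  set.seed(1234)
  for (rep in 1:40) {
    n <- sample(3:5, 1)
    m <- sample(2:(n * (n - 1)), 1)
    edges <- random_digraph_edges(n, m)
    net <- directed_network(n, edges)
    expect_equal(betweenness_centrality(net), bc_oracle(edges, n),
                 tolerance = 1e-12)
  }
})

test_that("auxiliary metrics match hand enumeration", {
  clique <- function(ids) { g <- expand.grid(ids, ids); as.matrix(g[g[, 1] != g[, 2], ]) }
  k4 <- directed_network(4, clique(1:4))
  expect_equal(global_efficiency(k4), 1)
  path <- directed_network(3, rbind(c(1, 2), c(2, 3)))
  # ordered pairs: 1->2 (1), 2->3 (1), 1->3 (1/2), others unreachable
  expect_equal(global_efficiency(path), (1 + 1 + 1 / 2) / 6)
  expect_equal(clustering_coefficient(path), 0)    # no triangles of any kind
  tri <- directed_network(3, rbind(c(1, 2), c(2, 3), c(3, 1)))
  expect_gt(clustering_coefficient(tri), 0)
  # out-degree of every source equals 3 in a complete digraph: zero variance
  expect_true(is.na(degree_assortativity(k4)))
  # hand-computed Pearson correlation over edges
  net <- directed_network(3, rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 1)))
  expect_equal(degree_assortativity(net),
               cor(c(2, 1, 2, 1), c(1, 2, 2, 1)))
})

test_that("movement and interaction rates follow their definitions", {
  still <- make_traj(10, 30, replicate(3, function(f) c(0, 0, 0),
                                       simplify = FALSE))
  expect_equal(movement_rate(still), 0)
  # one fly advancing 1 mm per frame at 30 Hz among 11 stationary flies
  movers <- c(list(function(f) c(f, 0, 0)),
              replicate(11, function(f) c(-10, 0, 0), simplify = FALSE))
  traj <- make_traj(10, 30, movers)
  expect_equal(movement_rate(traj), 30 / 12)

  traj150 <- make_traj(150 * 30, 30, replicate(12, function(f) c(0, 0, 0),
                                               simplify = FALSE))
  ev <- structure(data.frame(interactor = rep(1, 6), interactee = rep(2, 6)),
                  class = c("interaction_events", "data.frame"))
  expect_equal(interaction_rate(ev, traj150), 6 / 12 / 2.5)
})

test_that("every null sample preserves both degree sequences exactly", {
  set.seed(99)
  net <- directed_network(12, random_digraph_edges(12, 33))
  d0 <- degree_sequences(net)
  for (k in 1:25) {
    r <- randomize_degree_preserving(net)
    expect_identical(degree_sequences(r), d0)
    expect_false(any(r$edges[, 1] == r$edges[, 2]))
    key <- (r$edges[, 1] - 1) * 12 + r$edges[, 2]
    expect_false(anyDuplicated(key) > 0)
  }
})

test_that("null ensembles are seeded, and degenerate graphs are flagged", {
  net <- directed_network(12, random_digraph_edges(12, 33))
  a <- random_null(net, n_random = 50, rng_seed = 7)
  b <- random_null(net, n_random = 50, rng_seed = 7)
  expect_identical(a$samples, b$samples)

  clique <- function(ids) { g <- expand.grid(ids, ids); as.matrix(g[g[, 1] != g[, 2], ]) }
  k4 <- directed_network(4, clique(1:4))
  null <- random_null(k4, n_random = 30, rng_seed = 1)
  expect_true(null$degenerate)
  expect_equal(null$null_sd, 0)
  expect_equal(null$null_mean, null$observed)
  expect_error(random_null(directed_network(3, rbind(c(1, 2)))), ">= 2 edges")
})

test_that("the swap ensemble explores exactly the graphs allowed by the degree sequence", {
  # {a->b, c->b}: b's in-degree 2 forces both sources to point at b, so the
  # exhaustive set of simple digraphs with this degree sequence is a single
  # graph and every randomization must return it
  net <- directed_network(3, rbind(c(1, 2), c(3, 2)))
  d0 <- degree_sequences(net)
  allowed <- Filter(function(e) {
    g <- directed_network(3, e, validate = FALSE)
    identical(degree_sequences(g), d0) && nrow(unique(e)) == nrow(e) &&
      !any(e[, 1] == e[, 2])
  }, Filter(function(e) nrow(e) == 2, all_digraphs(3)))
  expect_length(allowed, 1)
  set.seed(5)
  for (k in 1:10) {
    r <- randomize_degree_preserving(net)
    expect_equal(r$edges[order(r$edges[, 1]), ], net$edges)
  }
})

test_that("zscore obeys its closed forms and affine invariance", {
  null <- structure(list(metric_name = "m", observed = 3, null_mean = 3,
                         null_sd = 0.5, n_random = 100, degenerate = FALSE,
                         samples = NULL), class = "null_distribution")
  expect_equal(zscore(3, null), 0)
  expect_equal(zscore(3.5, null), 1)
  expect_equal(zscore(5, null), 4)
  # affine rescaling applied jointly to observed and null leaves z unchanged
  scaled <- null; scaled$null_mean <- 7 * 3 + 2; scaled$null_sd <- 7 * 0.5
  expect_equal(zscore(7 * 5 + 2, scaled), zscore(5, null))
  degen <- null; degen$null_sd <- 0; degen$degenerate <- TRUE
  expect_equal(zscore(3, degen), 0)
  expect_true(is.na(zscore(4, degen)))
})

test_that("metric_series averages per-iteration z and drops undefined iterations", {
  clique <- function(ids) { g <- expand.grid(ids, ids); as.matrix(g[g[, 1] != g[, 2], ]) }
  k4 <- directed_network(4, clique(1:4))
  ser <- metric_series(list(k4, k4), metric = "bc", n_random = 20, rng_seed = 1)
  expect_equal(ser$per_iteration_z, c(0, 0))   # degenerate null at observed
  expect_equal(ser$mean_z, 0)

  set.seed(2)
  nets <- lapply(1:4, function(i) directed_network(12, random_digraph_edges(12, 33)))
  ser <- metric_series(nets, metric = "bc", n_random = 60, rng_seed = 3)
  expect_equal(ser$mean_z, mean(ser$per_iteration_z, na.rm = TRUE))
  expect_length(ser$per_iteration_z, 4)
  ser1 <- metric_series(nets[2], metric = "bc", n_random = 60, rng_seed = 3)
  expect_equal(ser1$mean_z, ser1$per_iteration_z[1])
  expect_error(metric_series(list(), metric = "bc"), "empty network series")
})
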