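wgraph <- function(from, to, w) {
  igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = sort(unique(c(from, to))),
                          stringsAsFactors = FALSE))
}

test_that("density, modularity and fitness match hand-derived values", {
  tri <- wgraph(c("a", "b", "a"), c("b", "c", "c"), c(1, 1, 1))
  cl <- new_cluster(tri, c("a", "b", "c"))
  expect_equal(cluster_density(cl), 1)
  expect_equal(cluster_modularity(cl), 1) # isolated: no external edges
  expect_equal(cluster_fitness(cl), 1)
  expect_equal(cluster_weight_avg(cl), 2)

  # unit triangle with one external unit edge
  trix <- wgraph(c("a", "b", "a", "c"), c("b", "c", "c", "x"),
                 c(1, 1, 1, 1))
  cl2 <- new_cluster(trix, c("a", "b", "c"))
  expect_equal(cluster_modularity(cl2), 0.75)
  d <- 1; m <- 0.75
  expect_equal(cluster_fitness(cl2), (d + m + sqrt(d * m)) / 3)
  expect_equal((1 + 0.75 + sqrt(0.75)) / 3, 0.872008, tolerance = 1e-6)

  # singleton: degenerate definitions
  cl3 <- new_cluster(trix, "x")
  expect_equal(cluster_density(cl3), 0)
  expect_equal(cluster_modularity(cl3), 0) # 0 / (0 + 1)
  expect_equal(cluster_fitness(cl3), 0)
  expect_equal(cluster_weight_avg(cl3), 0)
  expect_error(cluster_weight_avg(new_cluster(trix, character(0))), "empty")

  # 4-node path with weights 0.5 each: density 1.5/6
  p4 <- wgraph(c("a", "b", "c"), c("b", "c", "d"), c(0.5, 0.5, 0.5))
  expect_equal(cluster_density(new_cluster(p4, letters[1:4])), 0.25)

  # two nodes joined by weight 0.6
  e2 <- wgraph("a", "b", 0.6)
  expect_equal(cluster_weight_avg(new_cluster(e2, c("a", "b"))), 0.6)
})

test_that("fitness reduces to (D + M)/3 when either component is zero", {
  # two members with no internal edge but external edges: D > 0 is false
  g <- wgraph(c("a", "b"), c("x", "x"), c(0.4, 0.8))
  cl <- new_cluster(g, c("a", "b"))
  expect_equal(cluster_density(cl), 0)
  m <- cluster_modularity(cl)
  expect_equal(cluster_fitness(cl), m / 3)
})

test_that("incremental updates equal recomputation over random sequences", {
  set.seed(505)
  for (rep in 1:5) {
    g <- rand_weights(rand_raw_graph(sample(15:30, 1), p = 0.25))
    net <- as_weighted_igraph(g)
    adj <- ppicomplex:::wadj_list(net)
    start <- sample(g$nodes, 3)
    cl <- new_cluster(net, start)
    ref <- naive_cluster(g, start)
    expect_equal(cl$d_in, ref$d_in, tolerance = 1e-12)
    expect_equal(cl$d_out, ref$d_out, tolerance = 1e-12)
    for (step in 1:30) {
      outside <- setdiff(g$nodes, cl$members)
      go_add <- length(cl$members) == 0 ||
        (length(outside) > 0 && runif(1) < 0.6)
      if (go_add) {
        cl <- cluster_update(cl, sample(outside, 1), "add", adj)
      } else {
        cl <- cluster_update(cl, sample(cl$members, 1), "remove", adj)
      }
      if (length(cl$members)) {
        ref <- naive_cluster(g, cl$members)
        expect_equal(cl$d_in, ref$d_in, tolerance = 1e-12)
        expect_equal(cl$d_out, ref$d_out, tolerance = 1e-12)
      }
    }
  }
})

test_that("remove then re-add restores the cluster", {
  set.seed(42)
  g <- rand_weights(rand_raw_graph(12, p = 0.4))
  net <- as_weighted_igraph(g)
  cl <- new_cluster(net, sample(g$nodes, 4))
  v <- cl$members[2]
  back <- cluster_update(cluster_update(cl, v, "remove", net), v, "add", net)
  expect_identical(back$members, cl$members)
  expect_equal(back$d_in, cl$d_in, tolerance = 1e-12)
  expect_equal(back$d_out, cl$d_out, tolerance = 1e-12)
  expect_error(cluster_update(cl, cl$members[1], "add", net), "already")
  expect_error(cluster_update(cl, setdiff(g$nodes, cl$members)[1],
                              "remove", net), "not in cluster")
})

test_that("per-node weighted degrees conserve 2*d_in + d_out", {
  set.seed(606)
  for (rep in 1:5) {
    g <- rand_weights(rand_raw_graph(18, p = 0.3))
    net <- as_weighted_igraph(g)
    members <- sample(g$nodes, sample(3:8, 1))
    cl <- new_cluster(net, members)
    total <- sum(vapply(members, naive_dw, 0, g = g))
    expect_equal(total, 2 * cl$d_in + cl$d_out, tolerance = 1e-12)
  }
})

test_that("fitness is 1 exactly for an isolated unit-weight clique", {
  for (k in 3:6) {
    pr <- t(combn(sprintf("v%d", 1:k), 2))
    g <- wgraph(pr[, 1], pr[, 2], rep(1, nrow(pr)))
    expect_identical(cluster_fitness(new_cluster(g, sprintf("v%d", 1:k))), 1)
  }
})
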