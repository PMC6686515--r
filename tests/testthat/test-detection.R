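test_that("cluster boundary and inner-node sets match brute force", {
  fx <- toy_fixtures()
  w <- fx$k4_pendant$wnet
  cl <- new_cluster(w, c("a", "b", "c", "d"))
  expect_identical(neighbors_of_cluster(w, cl), "e")
  expect_identical(inner_nodes(w, cl), "d")
  iso <- new_cluster(fx$k4$wnet, c("a", "b", "c", "d"))
  expect_identical(neighbors_of_cluster(fx$k4$wnet, iso), character(0))
  expect_identical(inner_nodes(fx$k4$wnet, iso), character(0))

  set.seed(707)
  g <- rand_weights(rand_raw_graph(20, p = 0.25))
  net <- as_weighted_igraph(g)
  members <- sample(g$nodes, 5)
  cl2 <- new_cluster(net, members)
  nb_brute <- sort(setdiff(
    unique(unlist(lapply(members, naive_neighbors, g = g))), members))
  expect_identical(neighbors_of_cluster(net, cl2), nb_brute)
  inner_brute <- sort(members[vapply(members, function(v)
    length(setdiff(naive_neighbors(g, v), members)) > 0, TRUE)])
  expect_identical(inner_nodes(net, cl2), inner_brute)
})

test_that("growth from a clique seed recovers the clique and rejects pendants", {
  fx <- toy_fixtures()
  g1 <- grow_cluster(fx$k4$wnet, "a")
  expect_identical(g1$cluster$members, c("a", "b", "c", "d"))
  expect_identical(g1$fitness, 1)

  g2 <- grow_cluster(fx$k4_pendant$wnet, "b")
  expect_identical(g2$cluster$members, c("a", "b", "c", "d"))

  # brute force over all subsets containing the seed: the K4 maximises F
  df <- graph_as_df(fx$k4$wnet)
  others <- setdiff(df$nodes, "a")
  best <- -1; best_set <- NULL
  for (k in 0:length(others)) {
    sets <- if (k == 0) list(character(0)) else
      asplit(combn(others, k), 2)
    for (s in sets) {
      f <- naive_fitness(df, c("a", unlist(s)))
      if (f > best) { best <- f; best_set <- sort(c("a", unlist(s))) }
    }
  }
  expect_identical(best_set, g1$cluster$members)
  expect_equal(best, g1$fitness)
})

test_that("growth from the pendant seed still captures the clique", {
  fx <- toy_fixtures()
  g <- grow_cluster(fx$k4_pendant$wnet, "e")
  expect_true(all(c("a", "b", "c", "d") %in% g$cluster$members))
  expect_true(all(diff(c(0, g$f_trace)) > 0))
})

test_that("unknown seeds are rejected", {
  fx <- toy_fixtures()
  expect_error(grow_cluster(fx$k4$wnet, "zz"), "unknown seed")
})

test_that("detection separates disjoint cliques and allows overlaps", {
  fx <- toy_fixtures()
  dr <- detect_complexes(fx$two_k4$wnet)
  expect_equal(length(dr$complexes), 2L)
  expect_identical(dr$complexes$complexes,
                   list(c("a", "b", "c", "d"), c("w", "x", "y", "z")))
  expect_equal(dr$complexes$scores, c(1, 1))

  dr2 <- detect_complexes(fx$triangle_pendant$wnet)
  expect_identical(dr2$complexes$complexes, list(c("a", "b", "c")))

  dr3 <- detect_complexes(fx$empty$wnet)
  expect_equal(length(dr3$complexes), 0L)
})

test_that("all outputs satisfy size and pairwise-overlap constraints", {
  gen <- generate_planted_network(planted_network_spec(rng_seed = 9))
  wnet <- build_weighted_network(gen$network, gen$annotations)
  cfg <- detection_config()
  dr <- detect_complexes(wnet, cfg)
  cx <- dr$complexes$complexes
  expect_true(all(lengths(cx) >= cfg$min_size))
  if (length(cx) > 1) {
    for (i in seq_along(cx)) for (j in seq_len(i - 1)) {
      expect_lt(overlap_score(cx[[i]], cx[[j]]), cfg$redundancy_threshold)
    }
  }
  expect_false(any(dr$diagnostics$passes >= cfg$max_passes))
})

test_that("redundancy filtering keeps the fitter of overlapping complexes", {
  cs <- complex_set(list(c("a", "b", "c", "d"), c("a", "b", "c")),
                    scores = c(0.9, 0.8))
  both <- remove_redundant(cs, 0.8) # OS = 9/12 = 0.75 < 0.8
  expect_equal(length(both), 2L)
  one <- remove_redundant(cs, 0.7)
  expect_identical(one$complexes, list(c("a", "b", "c", "d")))

  dup <- complex_set(list(c("a", "b", "c"), c("a", "b", "c")),
                     scores = c(0.5, 0.5))
  expect_equal(length(remove_redundant(dup, 0.8)), 1L)

  disj <- complex_set(list(c("a", "b", "c"), c("x", "y", "z")),
                      scores = c(0.2, 0.9))
  expect_equal(length(remove_redundant(disj, 0.8)), 2L)
})

test_that("inverted removal connectivity is honoured", {
  fx <- toy_fixtures()
  cfg <- detection_config(removal_connectivity = "inverted")
  g <- grow_cluster(fx$k4$wnet, "a", cfg)
  expect_identical(g$cluster$members, c("a", "b", "c", "d"))
})

test_that("detection output is deterministic across input line orders", {
  gen <- generate_planted_network(planted_network_spec(rng_seed = 4))
  paths <- write_planted_network(gen, file.path(withr::local_tempdir(), "d"))
  net_lines <- readLines(paths[["network"]])
  ann_lines <- readLines(paths[["annotations"]])
  run <- function(nl, al) {
    net <- read_edge_list(nl)
    ann <- read_annotations(al)
    out <- withr::local_tempfile()
    dr <- detect_complexes(build_weighted_network(net, ann))
    write_complexes(dr$complexes, out)
    readLines(out)
  }
  base <- run(net_lines, ann_lines)
  set.seed(1)
  shuffled <- run(sample(net_lines), sample(ann_lines))
  expect_identical(shuffled, base)
})
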