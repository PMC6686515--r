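test_that("overlap score follows the squared-intersection formula", {
  eleven <- sprintf("P%02d", 1:11)
  expect_identical(overlap_score(eleven, eleven), 1)
  expect_identical(overlap_score(c("a", "b"), c("x", "y")), 0)
  p <- sprintf("p%d", 1:6)
  g <- c(p, sprintf("g%d", 1:5))
  expect_equal(overlap_score(p, g), 36 / 66)
  expect_identical(overlap_score(p, g), overlap_score(g, p))
  expect_error(overlap_score(character(0), "a"), "non-empty")
})

test_that("matching counts predictions and references independently", {
  one <- list(c("a", "b", "c"))
  m <- match_and_score(one, one)
  expect_equal(c(m$precision, m$recall, m$f_measure), c(1, 1, 1))

  pred <- list(c("a", "b", "c"), c("q", "r", "s"))
  ref <- list(c("a", "b", "c", "d"), c("x", "y", "z"))
  m2 <- match_and_score(pred, ref, omega = 0.2)
  expect_equal(m2$precision, 0.5)
  expect_equal(m2$recall, 0.5)
  expect_equal(m2$f_measure, 0.5)

  # OS exactly at omega counts as matched (inclusive threshold)
  big_ref <- list(sprintf("m%02d", 1:15))
  pred3 <- list(sprintf("m%02d", 1:3))
  expect_equal(overlap_score(pred3[[1]], big_ref[[1]]), 0.2)
  m3 <- match_and_score(pred3, big_ref, omega = 0.2)
  expect_equal(m3$ncp, 1L)
  expect_equal(m3$ncg, 1L)

  expect_warning(m4 <- match_and_score(list(), ref), "empty")
  expect_equal(m4$f_measure, 0)
})

test_that("matching metrics are invariant under complex order permutation", {
  set.seed(88)
  pred <- replicate(6, sample(letters, sample(3:6, 1)), simplify = FALSE)
  ref <- replicate(5, sample(letters, sample(3:6, 1)), simplify = FALSE)
  m1 <- match_and_score(pred, ref)
  m2 <- match_and_score(pred[sample(6)], ref[sample(5)])
  expect_equal(m1$f_measure, m2$f_measure)
  j1 <- jaccard_measures(pred, ref)
  j2 <- jaccard_measures(pred[sample(6)], ref[sample(5)])
  expect_equal(j1, j2)
})

test_that("size-weighted Jaccard measures match direct computation", {
  same <- list(c("a", "b", "c"))
  expect_equal(jaccard_measures(same, same),
               list(jaccard_i = 1, jaccard_s = 1, jaccard = 1))

  j <- jaccard_measures(list(c("a", "b", "c")), list(c("a", "b", "c", "d")))
  expect_equal(j$jaccard_i, 0.75)
  expect_equal(j$jaccard_s, 0.75)
  expect_equal(j$jaccard, 0.75)

  # weighted average: sizes 3 and 4 with best coefficients 0.75 and 0.5
  pred <- list(c("a", "b", "c"), c("x", "y", "z", "w"))
  ref <- list(c("a", "b", "c", "d"), c("x", "y", "z", "w",
                                       "u1", "u2", "u3", "u4"))
  j2 <- jaccard_measures(pred, ref)
  expect_equal(j2$jaccard_i, (3 * 0.75 + 4 * 0.5) / 7)
  # harmonic mean lies between its components
  expect_gte(j2$jaccard, min(j2$jaccard_i, j2$jaccard_s))
  expect_lte(j2$jaccard, max(j2$jaccard_i, j2$jaccard_s))
})

test_that("hypergeometric p-value matches closed-form corner cases", {
  expect_identical(enrichment_pvalue(0, 50, 10, 5), 1)
  expect_equal(enrichment_pvalue(5, 10, 5, 5), 1 / choose(10, 5),
               tolerance = 1e-12)
  expect_error(enrichment_pvalue(6, 10, 5, 5), "infeasible")
  expect_error(enrichment_pvalue(2, 10, 12, 5), "infeasible")
  # monotone decreasing in k for fixed (N, F, C)
  p <- enrichment_pvalue(0:4, 40, 8, 10)
  expect_true(all(diff(p) < 0))
})

test_that("complex enrichment assembles correct counts and correction", {
  ann <- structure(list(a = "T1", b = "T1", c = c("T1", "T2"), d = "T2",
                        e = "T3"),
                   class = "go_annotations")
  universe <- c(letters[1:5], "f", "g", "h") # 3 unannotated
  pred <- complex_set(list(c("a", "b", "c")))
  er <- enrich_complexes(pred, ann, universe, alpha = 0.05)
  t1 <- er$tests[er$tests$term == "T1", ]
  expect_equal(t1$k, 3L)
  expect_equal(t1$C, 3L)
  expect_equal(t1$F, 3L)
  expect_equal(t1$N, 8L)
  expect_equal(t1$p, enrichment_pvalue(3, 8, 3, 3), tolerance = 1e-12)
  # two tests for this complex (T1, T2) -> per-complex Bonferroni factor 2
  expect_equal(t1$p_adj, min(1, t1$p * 2), tolerance = 1e-12)
  expect_true(er$per_complex$significant[1])
  expect_equal(er$per_complex$best_term[1], "T1")

  # unannotated complex: no tests, not significant
  er2 <- enrich_complexes(complex_set(list(c("f", "g", "h"))), ann, universe)
  expect_equal(nrow(er2$tests), 0L)
  expect_false(any(er2$per_complex$significant))

  # identical complexes give identical rows
  er3 <- enrich_complexes(complex_set(list(c("a", "b", "c"),
                                           c("a", "b", "c"))),
                          ann, universe)
  r1 <- er3$tests[er3$tests$complex == 1, -1]
  r2 <- er3$tests[er3$tests$complex == 2, -1]
  rownames(r1) <- rownames(r2) <- NULL
  expect_identical(r1, r2)
})
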