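# The worked examples follow the five a-d paths of the toy network with
# H1 = (a,d), H2 = (a,c)(c,b)(b,d), H3 = (a,c)(c,e)(e,d),
# H4 = (a,c)(c,b)(b,e)(e,d), H5 = (a,c)(c,e)(e,b)(b,d).

toy_bip <- function(net = toy_network()) {
  path_edge_bipartite(enumerate_simple_paths(net, "a", "d"), net)
}

test_that("edge polynomials carry the containing paths and p + q = 1", {
  net <- toy_network()
  bip <- toy_bip(net)
  # edge-node for (a,c): its present term carries the four detour paths
  j_ac <- which(bip$edge_index == 4L)
  z <- edge_polynomial(bip, j_ac)
  expect_setequal(z$paths, which(bip$paths$length > 1L))
  expect_length(z$paths, 4L)
  expect_equal(z$p + z$q, 1)
  expect_equal(z$p, net$edges$p[4])

  # the direct edge lies on exactly one path, the length-1 one
  j_ad <- which(bip$edge_index == 1L)
  expect_identical(edge_polynomial(bip, j_ad)$paths,
                   which(bip$paths$length == 1L))

  # p = 1 edge degenerates: absent term has coefficient 0
  net1 <- toy_network(p = 1)
  z1 <- edge_polynomial(toy_bip(net1), 1)
  expect_equal(z1$q, 0)

  expect_error(edge_polynomial(bip, 99), class = "probnet_validation")
})

test_that("collapse replaces full exponents by length markers and drops the rest", {
  # term p1..p4 q5 q6 q7 x1 x2^3 x3 x4^2 x5^2 from the full product
  tm <- poly_term(0.01, c(`1` = 1, `2` = 3, `3` = 1, `4` = 2, `5` = 2))
  tm <- collapse_term(tm, 1, deg = 1, len = 1)
  tm <- collapse_term(tm, 2, deg = 3, len = 3)
  expect_identical(tm$t_markers, c(`1` = 1L, `3` = 1L))
  expect_identical(sort(names(tm$x_exponents)), c("3", "4", "5"))

  tm <- collapse_term(tm, 3, deg = 3, len = 3)
  tm <- collapse_term(tm, 4, deg = 4, len = 4)
  tm <- collapse_term(tm, 5, deg = 4, len = 4)
  expect_identical(tm$t_markers, c(`1` = 1L, `3` = 1L))
  expect_length(tm$x_exponents, 0)
  expect_equal(tm$coefficient, 0.01)

  # absent variable: no-op
  tm0 <- collapse_term(poly_term(0.5, c(`2` = 1)), 1, deg = 1)
  expect_identical(tm0$x_exponents, c(`2` = 1L))
  # exponent above degree is an internal inconsistency
  expect_error(collapse_term(poly_term(0.5, c(`1` = 3)), 1, deg = 2),
               class = "probnet_internal")
})

test_that("select keeps only the smallest-length marker", {
  tm <- select_term(poly_term(0.2, t_markers = c(`1` = 1, `3` = 1)))
  expect_identical(tm$y_exponent, 1L)
  expect_length(tm$t_markers, 0)

  tm2 <- select_term(poly_term(0.3, t_markers = c(`3` = 2)))
  expect_identical(tm2$y_exponent, 2L)

  tm3 <- select_term(poly_term(0.3, t_markers = c(`2` = 1, `5` = 3)))
  expect_identical(tm3$y_exponent, 1L)

  expect_error(select_term(poly_term(0.3)), class = "probnet_validation")
})

test_that("toy-network distribution has three terms summing to one", {
  d <- count_shortest_paths(toy_network(), "a", "d")
  expect_identical(d$support, 0:2)
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  expect_true(all(d$prob > 0))
})

test_that("hand-derived small distributions are reproduced", {
  # single edge: [1 - p, p]
  d1 <- count_shortest_paths(single_edge_network(0.3), "s", "t")
  expect_equal(d1$prob, c(0.7, 0.3))

  # triangle, all p = 0.5, pair (a, b): brute-forced over 8 instances
  d2 <- count_shortest_paths(triangle_network(0.5), "a", "b")
  expect_equal(d2$prob, c(0.375, 0.625))
  expect_equal(expected_count(d2), 0.625)
  expect_equal(connectivity_probability(d2), 0.625)

  # 0-path pair: point mass at zero
  disc <- prob_network(data.frame(from = "a", to = "b", p = 0.5), nodes = "z")
  d3 <- count_shortest_paths(disc, "a", "z")
  expect_equal(d3$prob, 1)
  expect_equal(expected_count(d3), 0)
  expect_equal(connectivity_probability(d3), 0)
})

test_that("deterministic limit reproduces BFS counts as a point mass", {
  set.seed(31)
  for (i in 1:8) {
    net <- random_small_network(sample(5:7, 1), sample(5:12, 1), p = 1)
    vs <- sample(net$nodes, 2)
    d <- count_shortest_paths(net, vs[1], vs[2])
    k <- deterministic_sp_count(binarize(net), vs[1], vs[2])
    expect_equal(sum(d$prob), 1, tolerance = 1e-12)
    expect_equal(d$prob[k + 1L], 1, tolerance = 1e-12)
  }
})

test_that("vanishing edge probabilities concentrate mass at zero", {
  for (eps in c(1e-2, 1e-4, 1e-6)) {
    d <- count_shortest_paths(toy_network(p = eps), "a", "d")
    expect_gt(d$prob[1], 1 - 8 * eps)
  }
})

test_that("fast, naive and oracle routes agree on random undirected networks", {
  set.seed(1234)
  for (i in 1:40) {
    net <- random_small_network(sample(4:7, 1), sample(4:10, 1))
    vs <- sample(net$nodes, 2)
    fast <- count_shortest_paths(net, vs[1], vs[2])
    naive <- naive_count_shortest_paths(net, vs[1], vs[2])
    oracle <- oracle_sp_distribution(net, vs[1], vs[2])
    expect_equal(fast$prob, oracle$prob, tolerance = 1e-9)
    expect_equal(naive$prob, oracle$prob, tolerance = 1e-9)
    expect_equal(sum(fast$prob), 1, tolerance = 1e-9)
    # support length is the max per-length multiplicity plus one
    paths <- enumerate_simple_paths(net, vs[1], vs[2])
    expected_len <- if (nrow(paths) == 0) 1L else max(tabulate(paths$length)) + 1L
    expect_length(fast$prob, expected_len)
  }
})

test_that("fast and oracle routes agree on random directed networks", {
  set.seed(4321)
  for (i in 1:15) {
    net <- random_small_network(sample(4:6, 1), sample(4:9, 1), directed = TRUE)
    vs <- sample(net$nodes, 2)
    fast <- count_shortest_paths(net, vs[1], vs[2])
    oracle <- oracle_sp_distribution(net, vs[1], vs[2])
    expect_equal(fast$prob, oracle$prob, tolerance = 1e-9)
  }
})

test_that("tidy, glance and JSON serialisation expose the distribution", {
  d <- count_shortest_paths(triangle_network(0.5), "a", "b")
  td <- tidy(d)
  expect_identical(td$k, 0:1)
  expect_equal(td$prob, c(0.375, 0.625))
  g <- glance(d)
  expect_equal(g$expected, 0.625)
  js <- jsonlite::fromJSON(sp_distribution_json(d))
  expect_equal(js$support, 0:1)
  expect_equal(js$expected, 0.625)
})
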