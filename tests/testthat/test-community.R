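test_that("deterministic modularity matches hand-derived values", {
  one <- single_edge_network(1)
  expect_equal(deterministic_modularity(binarize(one), c(s = 1, t = 1)), 0)

  two <- prob_network(data.frame(from = c("a", "c"), to = c("b", "d"), p = 1))
  expect_equal(
    deterministic_modularity(binarize(two), c(a = 1, b = 1, c = 2, d = 2)),
    0.5
  )
  empty <- det_instance(one, integer())
  expect_error(deterministic_modularity(empty, c(s = 1, t = 1)),
               class = "probnet_validation")
})

test_that("grouped modularity equals the pairwise adjacency form", {
  # pairwise reference: (1/2m) * sum_ij (A_ij - d_i d_j / 2m) delta(c_i, c_j)
  pairwise_q <- function(instance, memb) {
    nodes <- instance$nodes
    n <- length(nodes)
    A <- matrix(0, n, n, dimnames = list(nodes, nodes))
    for (k in seq_len(nrow(instance$edges))) {
      u <- instance$edges$from[k]; v <- instance$edges$to[k]
      A[u, v] <- A[u, v] + 1; A[v, u] <- A[v, u] + 1
    }
    d <- rowSums(A)
    m <- sum(A) / 2
    same <- outer(memb[nodes], memb[nodes], "==")
    sum((A - outer(d, d) / (2 * m)) * same) / (2 * m)
  }
  set.seed(61)
  for (i in 1:10) {
    net <- random_small_network(6, sample(5:12, 1), p = 1)
    inst <- binarize(net)
    memb <- setNames(sample(1:3, 6, replace = TRUE), net$nodes)
    expect_equal(deterministic_modularity(inst, memb), pairwise_q(inst, memb),
                 tolerance = 1e-12)
  }
})

test_that("expected modularity matches the hand-derived two-edge case", {
  net <- prob_network(data.frame(from = c("a", "b"), to = c("b", "c"),
                                 p = c(1, 0.5)))
  res <- expected_modularity(net, c(a = 1, b = 1, c = 2))
  expect_equal(res$Q, -0.0625)
  expect_equal(sum(res$communities$Q_c), res$Q)
})

test_that("expected modularity reduces to the deterministic value at p = 1", {
  set.seed(62)
  for (i in 1:6) {
    net <- random_small_network(6, sample(5:12, 1), p = 1)
    memb <- setNames(sample(1:3, 6, replace = TRUE), net$nodes)
    expect_equal(expected_modularity(net, memb)$Q,
                 deterministic_modularity(binarize(net), memb),
                 tolerance = 1e-12)
  }
})

test_that("expected modularity equals the enumeration average on random inputs", {
  set.seed(63)
  for (i in 1:10) {
    net <- random_small_network(sample(5:6, 1), sample(4:10, 1))
    memb <- setNames(sample(1:3, length(net$nodes), replace = TRUE), net$nodes)
    expect_equal(expected_modularity(net, memb)$Q,
                 oracle_expected_modularity(net, memb),
                 tolerance = 1e-9)
  }
})

test_that("per-class presence polynomials conserve mass and are Poisson-binomial", {
  set.seed(64)
  p <- runif(8)
  coef <- probnet:::presence_count_poly(p)
  expect_length(coef, 9)
  expect_equal(sum(coef), 1, tolerance = 1e-12)
  # against binomial when probabilities are equal
  coef2 <- probnet:::presence_count_poly(rep(0.3, 6))
  expect_equal(coef2, dbinom(0:6, 6, 0.3), tolerance = 1e-12)
  # quadratic construction stays cheap at benchmark scale
  expect_lt(system.time(probnet:::presence_count_poly(runif(400)))[["elapsed"]], 1)
})

test_that("partition errors are surfaced", {
  net <- path_network(0.5)
  expect_error(expected_modularity(net, c(a = 1, b = 1)),
               class = "probnet_validation")
})

test_that("divisive detection recovers two weakly bridged triangles", {
  res <- detect_communities(two_triangles_bridge())
  truth <- c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2)
  expect_equal(rand_index(res$partition, truth), 1)
  expect_identical(max(res$partition$community), 2L)
  # the weak bridge is the first removal
  first <- res$dendrogram[res$dendrogram$step == 1L, ]
  expect_setequal(c(first$removed_from, first$removed_to), c("c", "d"))
  # dendrogram covers every edge and the best level is the max
  expect_identical(nrow(res$dendrogram), 8L)
  expect_equal(res$Q, max(res$dendrogram$modularity))
})

test_that("single-edge network detection completes with a length-1 dendrogram", {
  res <- detect_communities(single_edge_network(0.5))
  expect_identical(nrow(res$dendrogram), 2L) # step 0 plus one removal
  expect_true(max(res$partition$community) %in% c(1L, 2L))
  expect_equal(rand_index(res$partition, res$partition), 1)
})

test_that("all-certain planted communities match the classical divisive result", {
  net <- three_cliques_network(p_in = 1, p_bridge = 1)
  res <- detect_communities(net)
  g <- as_igraph(net)
  ref <- igraph::cluster_edge_betweenness(g)
  ours <- setNames(res$partition$community, res$partition$node)
  theirs <- setNames(igraph::membership(ref), igraph::V(g)$name)
  expect_equal(rand_index(ours, theirs), 1)
  expect_identical(max(res$partition$community), 3L)
})

test_that("best level does not fall below the one-community baseline", {
  net <- two_triangles_bridge()
  base <- expected_modularity(net, setNames(rep(1, 6), net$nodes))$Q
  expect_gte(detect_communities(net)$Q, base)
})

test_that("rand index counts agreeing pairs", {
  expect_equal(rand_index(c(a = 1, b = 1, c = 2), c(a = 5, b = 5, c = 9)), 1)
  expect_equal(rand_index(c(a = 1, b = 1, c = 2), c(a = 1, b = 2, c = 3)), 2 / 3)
  expect_equal(rand_index(c(a = 1, b = 1), c(a = 1, b = 2)), 0)
  expect_error(rand_index(c(a = 1), c(b = 1)), class = "probnet_validation")
})

test_that("literature z-score standardises counts", {
  expect_equal(literature_zscore(3, 3, 1), 0)
  expect_equal(literature_zscore(5, 3, 1), 2)
  mu <- 4; sigma <- 1.5
  expect_equal(literature_zscore(mu + 2 * sigma, mu, sigma), 2)
  expect_error(literature_zscore(1, 0, 0), class = "probnet_validation")
})
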