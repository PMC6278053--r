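test_that("construction validates probabilities, loops and duplicates", {
  expect_s3_class(single_edge_network(), "prob_network")
  expect_error(prob_network(data.frame(from = "a", to = "b", p = 1.5)),
               class = "probnet_validation")
  expect_error(prob_network(data.frame(from = "a", to = "b", p = 0)),
               class = "probnet_validation")
  expect_error(prob_network(data.frame(from = "a", to = "a", p = 0.5)),
               class = "probnet_validation")
  # undirected duplicate in reversed orientation
  expect_error(prob_network(data.frame(from = c("a", "b"), to = c("b", "a"),
                                       p = 0.5)),
               class = "probnet_validation")
  # but fine when directed
  expect_silent(prob_network(data.frame(from = c("a", "b"), to = c("b", "a"),
                                        p = 0.5), directed = TRUE))
})

test_that("edge-list round trip preserves the network, comments and isolates", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  net <- prob_network(
    data.frame(from = c("a", "b"), to = c("b", "c"), p = c(0.123456789012345, 1)),
    nodes = c("lonely")
  )
  write_edgelist(net, tmp)
  back <- read_edgelist(tmp)
  expect_identical(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges)
})

test_that("edge-list reader surfaces parse and validation errors with line numbers", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t0.5", "a\tc\tnot_a_number"), tmp)
  expect_error(read_edgelist(tmp), "line 2", class = "probnet_parse")
  writeLines(c("a\tb\t1.5"), tmp)
  expect_error(read_edgelist(tmp), class = "probnet_validation")
  writeLines(c("# comment only", "#nodes:\tx"), tmp)
  net <- read_edgelist(tmp)
  expect_identical(net$nodes, "x")
  expect_identical(nrow(net$edges), 0L)
})

test_that("the bundled toy edge list loads with 5 nodes and 7 edges", {
  path <- system.file("extdata", "toy_network.tsv", package = "probnet")
  net <- read_edgelist(path)
  expect_length(net$nodes, 5)
  expect_identical(nrow(net$edges), 7L)
})

test_that("graphml round trip preserves topology and probabilities", {
  tmp <- withr::local_tempfile(fileext = ".graphml")
  net <- toy_network()
  write_graphml(net, tmp)
  back <- read_graphml(tmp)
  expect_setequal(back$nodes, net$nodes)
  key <- function(x) paste(pmin(x$edges$from, x$edges$to),
                           pmax(x$edges$from, x$edges$to))
  expect_equal(back$edges$p[order(key(back))], net$edges$p[order(key(net))])
})

test_that("instance probability follows the product rule", {
  net <- toy_network(p = 0.5)
  expect_equal(instance_probability(net, 1:7), 0.5^7)
  net1 <- toy_network(p = 1)
  expect_equal(instance_probability(net1, 1:7), 1)
  # invariant to subset ordering
  net2 <- toy_network()
  expect_equal(instance_probability(net2, c(3, 1, 5)),
               instance_probability(net2, c(5, 3, 1)))
  expect_error(instance_probability(net2, 9), class = "probnet_validation")
})

test_that("instance enumeration is complete and sums to one", {
  net <- toy_network()
  inst <- enumerate_instances(net)
  expect_identical(nrow(inst), 128L)
  expect_equal(sum(inst$probability), 1, tolerance = 1e-12)

  empty <- prob_network(NULL, nodes = "a")
  inst0 <- enumerate_instances(empty)
  expect_identical(nrow(inst0), 1L)
  expect_equal(inst0$probability, 1)

  two <- prob_network(data.frame(from = c("a", "b"), to = c("b", "c"), p = 0.5))
  inst2 <- enumerate_instances(two)
  expect_equal(inst2$probability, rep(0.25, 4))

  expect_error(enumerate_instances(net, max_edges = 3),
               "max_edges", class = "probnet_overflow")
})

test_that("enumeration mass is conserved on random networks", {
  set.seed(11)
  for (i in 1:10) {
    net <- random_small_network(sample(4:6, 1), sample(3:10, 1))
    expect_equal(sum(enumerate_instances(net)$probability), 1, tolerance = 1e-12)
  }
})

test_that("instance sampling is seeded, reproducible and calibrated", {
  net <- toy_network(p = 1)
  expect_identical(sample_instance(net)$edge_index, 1:7)

  net2 <- toy_network()
  a <- sample_instance(net2, seed = 7)
  b <- sample_instance(net2, seed = 7)
  expect_identical(a$edge_index, b$edge_index)

  se <- single_edge_network(0.5)
  n_draws <- 1e4
  set.seed(3)
  kept <- sum(vapply(seq_len(n_draws),
                     function(i) length(sample_instance(se)$edge_index), numeric(1)))
  band <- 3 * sqrt(n_draws * 0.25)
  expect_lt(abs(kept - n_draws * 0.5), band)
})

test_that("binarize and threshold transforms behave as specified", {
  net <- toy_network()
  expect_identical(binarize(net)$edge_index, 1:7)
  expect_identical(nrow(binarize(prob_network(NULL, nodes = "a"))$edges), 0L)

  tnet <- prob_network(data.frame(from = c("a", "a"), to = c("b", "c"),
                                  p = c(0.7, 0.3)))
  expect_identical(threshold_transform(tnet, 0.6)$edge_index, 1L)
  expect_identical(threshold_transform(net, 0)$edge_index, binarize(net)$edge_index)

  # strict comparison: identical p = 0.5 keeps all below, none above
  idn <- toy_network(p = 0.5)
  expect_identical(length(threshold_transform(idn, 0.4)$edge_index), 7L)
  expect_identical(length(threshold_transform(idn, 0.6)$edge_index), 0L)
  expect_identical(length(threshold_transform(idn, 0.5)$edge_index), 0L)
})
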