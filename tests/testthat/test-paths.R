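test_that("the toy network has exactly the five documented a-d paths", {
  net <- toy_network()
  paths <- enumerate_simple_paths(net, "a", "d")
  expect_identical(nrow(paths), 5L)
  seqs <- vapply(paths$nodes, paste, character(1), collapse = ">")
  expect_setequal(seqs, c(
    "a>d",
    "a>c>b>d",
    "a>c>e>d",
    "a>c>b>e>d",
    "a>c>e>b>d"
  ))
  expect_identical(sort(paths$length), c(1L, 3L, 3L, 4L, 4L))
})

test_that("small topologies enumerate correctly", {
  tri <- triangle_network()
  paths <- enumerate_simple_paths(tri, "a", "b")
  expect_identical(nrow(paths), 2L)
  expect_setequal(paths$length, c(1L, 2L))

  disc <- prob_network(data.frame(from = "a", to = "b", p = 0.5), nodes = "z")
  expect_identical(nrow(enumerate_simple_paths(disc, "a", "z")), 0L)

  expect_error(enumerate_simple_paths(tri, "a", "a"), class = "probnet_validation")
})

test_that("path enumeration respects caps with a hard error", {
  net <- toy_network()
  expect_error(enumerate_simple_paths(net, "a", "d", max_paths = 3),
               "max_paths", class = "probnet_overflow")
  capped <- enumerate_simple_paths(net, "a", "d", max_length = 3)
  expect_identical(nrow(capped), 3L)
})

test_that("undirected enumeration is symmetric and uses only real edges", {
  set.seed(21)
  for (i in 1:8) {
    net <- random_small_network(5, sample(4:9, 1))
    vs <- sample(net$nodes, 2)
    fwd <- enumerate_simple_paths(net, vs[1], vs[2])
    bwd <- enumerate_simple_paths(net, vs[2], vs[1])
    expect_identical(nrow(fwd), nrow(bwd))
    key <- function(p) sort(vapply(p$edges, function(e) paste(sort(e), collapse = "-"),
                                   character(1)))
    expect_identical(key(fwd), key(bwd))
    expect_true(all(unlist(fwd$edges) %in% seq_len(nrow(net$edges))))
  }
})

test_that("bipartite graph matches the documented toy structure", {
  net <- toy_network()
  paths <- enumerate_simple_paths(net, "a", "d")
  bip <- path_edge_bipartite(paths, net)
  expect_identical(nrow(bip$paths), 5L)
  expect_length(bip$edge_index, 7L)
  deg <- edge_node_degree(bip)
  expect_identical(unname(deg[["a--c"]]), 4L)
  # path-node degree equals path length; handshake identity
  expect_identical(lengths(bip$membership), paths$length)
  expect_identical(sum(lengths(bip$membership)), sum(edge_node_degree(bip)))
})

test_that("single path yields a degenerate bipartite graph", {
  net <- path_network(p = 0.5)
  paths <- enumerate_simple_paths(net, "a", "c")
  bip <- path_edge_bipartite(paths, net)
  expect_identical(nrow(bip$paths), 1L)
  expect_length(bip$edge_index, 2L)
  expect_true(all(edge_node_degree(bip) == 1L))
  expect_error(path_edge_bipartite(paths[0, ], net), class = "probnet_validation")
})

test_that("length groups are ascending and partition the path set", {
  net <- toy_network()
  bip <- path_edge_bipartite(enumerate_simple_paths(net, "a", "d"), net)
  groups <- group_by_length(bip)
  expect_identical(groups$length, c(1L, 3L, 4L))
  expect_identical(lengths(groups$paths), c(1L, 2L, 2L))
  expect_setequal(unlist(groups$paths), seq_len(5))

  # all-equal lengths collapse to a single group
  dia <- diamond_network()
  bip2 <- path_edge_bipartite(enumerate_simple_paths(dia, "a", "d"), dia)
  expect_identical(nrow(group_by_length(bip2)), 1L)
})

test_that("membership dump has one row per membership edge", {
  net <- toy_network()
  bip <- path_edge_bipartite(enumerate_simple_paths(net, "a", "d"), net)
  dump <- bipartite_membership(bip)
  expect_identical(nrow(dump), sum(lengths(bip$membership)))
  expect_setequal(unique(dump$path), seq_len(5))
})
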