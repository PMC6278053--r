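#' Brute-force oracles by full instance enumeration
#'
#' Definitionally-correct but exponential references used to verify the
#' polynomial algorithms. Every quantity is computed by enumerating all
#' `2^m` deterministic instances, so a size guard refuses larger inputs.
#'
#' `oracle_sp_distribution()` counts shortest paths in each instance through
#' the NSP indicator construction over the enumerated simple paths: a path
#' contributes 1 when it is present and no strictly shorter co-present path
#' exists (ties all count).
#'
#' @param net A `prob_network`.
#' @param source,sink Node identifiers.
#' @param max_edges Enumeration guard (default 16, i.e. at most 65,536
#'   instances).
#' @return `oracle_sp_distribution()`: an `sp_distribution`.
#' @examples
#' tri <- prob_network(data.frame(from = c("a", "a", "c"),
#'                                to = c("b", "c", "b"), p = 0.5))
#' oracle_sp_distribution(tri, "a", "b")$prob # 0.375 0.625
#' @export
oracle_sp_distribution <- function(net, source, sink, max_edges = 16L) {
  assert_network(net)
  assert_nodes(net, source, sink)
  paths <- enumerate_simple_paths(net, source, sink)
  inst <- enumerate_instances(net, max_edges = max_edges)
  if (nrow(paths) == 0L) {
    return(new_sp_distribution(source, sink, prob = 1, n_paths = 0L))
  }
  k_max <- max(tabulate(paths$length))
  p_y <- numeric(k_max + 1L)
  m <- nrow(net$edges)
  for (i in seq_len(nrow(inst))) {
    pres <- rep(FALSE, m)
    pres[inst$present[[i]]] <- TRUE
    nsp <- nsp_count(paths, pres)
    p_y[nsp + 1L] <- p_y[nsp + 1L] + inst$probability[i]
  }
  new_sp_distribution(source, sink, prob = p_y, n_paths = nrow(paths))
}

# NSP indicator: sum over paths i of Y_i * prod_k (Y_k Z_ik + (1 - Y_k)),
# Y_i = path present, Z_ik = 1 iff L_i <= L_k
nsp_count <- function(paths, present_edges) {
  y <- vapply(paths$edges, function(e) all(present_edges[e]), logical(1))
  if (!any(y)) return(0L)
  lens <- paths$length
  total <- 0L
  for (i in which(y)) {
    beaten <- any(y & lens < lens[i])
    if (!beaten) total <- total + 1L
  }
  total
}

#' @rdname oracle_sp_distribution
#' @details `oracle_edge_betweenness()` evaluates the expected-betweenness
#'   definition literally: per instance and node pair, each edge receives the
#'   fraction of that instance's shortest paths passing through it; the
#'   pair's expectation is normalised by its connectivity probability, summed
#'   over pairs and finally divided by the edge's presence probability.
#' @return `oracle_edge_betweenness()`: tibble as
#'   [expected_edge_betweenness()].
#' @export
oracle_edge_betweenness <- function(net, max_edges = 16L) {
  assert_network(net)
  inst <- enumerate_instances(net, max_edges = max_edges)
  m <- nrow(net$edges)
  pairs <- node_pairs(net$nodes, ordered = net$directed)
  exp_b <- numeric(m)
  for (k in seq_len(nrow(pairs))) {
    paths <- enumerate_simple_paths(net, pairs$s[k], pairs$t[k])
    if (nrow(paths) == 0L) next
    lens <- paths$length
    contrib <- numeric(m)
    conn <- 0
    for (i in seq_len(nrow(inst))) {
      pres <- rep(FALSE, m)
      pres[inst$present[[i]]] <- TRUE
      y <- vapply(paths$edges, function(e) all(pres[e]), logical(1))
      if (!any(y)) next
      conn <- conn + inst$probability[i]
      shortest <- which(y & lens == min(lens[y]))
      w <- inst$probability[i] / length(shortest)
      for (h in shortest) {
        contrib[paths$edges[[h]]] <- contrib[paths$edges[[h]]] + w
      }
    }
    if (conn > 0) exp_b <- exp_b + contrib / conn
  }
  tibble(
    from = net$edges$from, to = net$edges$to, p = net$edges$p,
    expected_count = exp_b, betweenness = exp_b / net$edges$p
  )
}

#' @rdname oracle_sp_distribution
#' @param partition Partition of the network's nodes.
#' @details `oracle_expected_modularity()` averages the deterministic
#'   modularity over all instances, with empty instances contributing 0.
#' @return `oracle_expected_modularity()`: a single number.
#' @export
oracle_expected_modularity <- function(net, partition, max_edges = 16L) {
  assert_network(net)
  part <- as_partition(partition, net$nodes)
  inst <- enumerate_instances(net, max_edges = max_edges)
  q <- 0
  for (i in seq_len(nrow(inst))) {
    pres <- inst$present[[i]]
    if (length(pres) == 0L) next # empty instance contributes 0
    q <- q + inst$probability[i] *
      deterministic_modularity(det_instance(net, pres), part)
  }
  q
}
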