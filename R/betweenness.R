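#' Expected edge and node betweenness of a probabilistic network
#'
#' Generalises Girvan-Newman equal-split betweenness to networks with
#' uncertain edges. For each node pair the exact shortest-path count
#' distribution is computed once and, whenever a set of `j` equal-length
#' shortest paths is realised with probability mass `alpha`, every edge of
#' every such path is credited `alpha / j` (edges on several of the paths
#' accumulate). The pair's total credit to an edge is normalised by the
#' probability that the pair is connected at all, and pairs that can never
#' connect contribute nothing. The edge betweenness is finally rescaled by
#' the edge's own presence probability:
#' `f(e) = Exp(B_e) / p_e`.
#'
#' Note the rescaling is applied exactly as defined, so an isolated edge with
#' presence probability `p` has betweenness `1/p`, not 1: the conditional
#' credit (`p / p = 1`, from the connectivity normalisation) is divided by
#' `p` once more. In the deterministic limit (`p = 1` everywhere) the result
#' coincides with classical equal-split edge betweenness.
#'
#' Node betweenness follows the same aggregation with credit going to the
#' interior nodes of the contributing paths (endpoints excluded) and no
#' presence rescaling, since nodes are certain; in the deterministic limit it
#' equals classical node betweenness.
#'
#' Pairs are unordered for undirected networks and ordered for directed ones.
#'
#' @param net A `prob_network`.
#' @param max_paths,max_terms Caps forwarded to the per-pair computation.
#' @return A tibble: for edges, columns `from`, `to`, `p`, `expected_count`
#'   (`Exp(B_e)`) and `betweenness` (`f(e)`); for nodes, columns `node` and
#'   `betweenness`.
#' @examples
#' expected_edge_betweenness(toy_network())
#' @export
expected_edge_betweenness <- function(net, max_paths = 1e5, max_terms = 5e5) {
  assert_network(net)
  agg <- accumulate_contributions(net, max_paths, max_terms)
  tibble(
    from = net$edges$from,
    to = net$edges$to,
    p = net$edges$p,
    expected_count = agg$edges,
    betweenness = agg$edges / net$edges$p
  )
}

#' @rdname expected_edge_betweenness
#' @export
expected_node_betweenness <- function(net, max_paths = 1e5, max_terms = 5e5) {
  assert_network(net)
  agg <- accumulate_contributions(net, max_paths, max_terms)
  tibble(node = net$nodes, betweenness = agg$nodes)
}

accumulate_contributions <- function(net, max_paths, max_terms) {
  nodes <- net$nodes
  edge_tot <- numeric(nrow(net$edges))
  node_tot <- numeric(length(nodes))
  pairs <- node_pairs(nodes, ordered = net$directed)
  for (k in seq_len(nrow(pairs))) {
    res <- xp_engine(net, pairs$s[k], pairs$t[k],
                     max_paths = max_paths, max_terms = max_terms, track = TRUE)
    conn <- connectivity_probability(res$distribution)
    if (conn <= 0) next
    edge_tot[res$edges$edge] <- edge_tot[res$edges$edge] + res$edges$contribution / conn
    node_tot <- node_tot + res$nodes$contribution / conn
  }
  list(edges = edge_tot, nodes = node_tot)
}

node_pairs <- function(nodes, ordered) {
  n <- length(nodes)
  if (n < 2L) return(tibble(s = character(), t = character()))
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  pairs <- tibble(s = nodes[idx[, 1]], t = nodes[idx[, 2]])
  if (ordered) {
    pairs <- dplyr::bind_rows(pairs, tibble(s = pairs$t, t = pairs$s))
  }
  pairs
}

#' Write a betweenness table to TSV
#'
#' @param table Output of [expected_edge_betweenness()] or
#'   [expected_node_betweenness()].
#' @param path File path.
#' @return The table, invisibly.
#' @export
write_betweenness <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(table)
}
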