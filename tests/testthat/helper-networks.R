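# Fixtures and generators shared across the suite. Everything is built in
# code; random cases are always drawn under an explicit seed.

triangle_network <- function(p = 0.5) {
  prob_network(data.frame(
    from = c("a", "a", "c"),
    to   = c("b", "c", "b"),
    p    = p
  ))
}

single_edge_network <- function(p = 0.5) {
  prob_network(data.frame(from = "s", to = "t", p = p))
}

path_network <- function(p = 1) {
  prob_network(data.frame(from = c("a", "b"), to = c("b", "c"), p = p))
}

diamond_network <- function(p = 1) {
  prob_network(data.frame(
    from = c("a", "a", "b", "c"),
    to   = c("b", "c", "d", "d"),
    p    = p
  ))
}

# random connected-ish topology with m edges on nn nodes and given probs;
# node ids are zero-padded so lexicographic order is stable
random_small_network <- function(nn, m, p = NULL, directed = FALSE) {
  all_pairs <- t(combn(nn, 2))
  if (directed) all_pairs <- rbind(all_pairs, all_pairs[, 2:1])
  take <- sample(nrow(all_pairs), min(m, nrow(all_pairs)))
  el <- all_pairs[take, , drop = FALSE]
  if (is.null(p)) p <- round(runif(nrow(el), 0.05, 1), 4)
  prob_network(
    data.frame(from = sprintf("v%02d", el[, 1]),
               to = sprintf("v%02d", el[, 2]), p = p),
    nodes = sprintf("v%02d", seq_len(nn)),
    directed = directed
  )
}

# three planted four-cliques joined in a line by single weaker edges
three_cliques_network <- function(p_in = 1, p_bridge = 1) {
  clique <- function(nodes) t(combn(nodes, 2))
  blocks <- rbind(
    clique(c("a1", "a2", "a3", "a4")),
    clique(c("b1", "b2", "b3", "b4")),
    clique(c("c1", "c2", "c3", "c4"))
  )
  bridges <- rbind(c("a4", "b1"), c("b4", "c1"))
  prob_network(data.frame(
    from = c(blocks[, 1], bridges[, 1]),
    to = c(blocks[, 2], bridges[, 2]),
    p = c(rep(p_in, nrow(blocks)), rep(p_bridge, 2))
  ))
}
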