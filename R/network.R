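#' Build a probabilistic network
#'
#' A probabilistic network is a graph whose edges carry independent presence
#' probabilities in `(0, 1]`. Semantically it is a distribution over the
#' `2^m` deterministic instances obtained by keeping or dropping each edge,
#' with the probability of an instance given by the product rule: present
#' edges contribute `p`, absent edges `1 - p`.
#'
#' @param edges A data frame whose first three columns are the source node,
#'   target node and presence probability (canonical names `from`, `to`,
#'   `p`). Node identifiers are treated as opaque strings; no integer
#'   coercion is performed.
#' @param nodes Optional character vector of node identifiers. Endpoints of
#'   `edges` are always included; use this to add isolated nodes.
#' @param directed Logical; if `FALSE` (default) edges are unordered pairs
#'   and `(u, v)` duplicates `(v, u)`.
#'
#' @return A `prob_network` object: a list with elements `nodes` (character),
#'   `edges` (a tibble with columns `from`, `to`, `p`) and `directed`.
#'
#' @details Validation enforces that every probability lies strictly in
#'   `(0, 1]` (an absent edge is expressed by omitting it, not by `p = 0`),
#'   that there are no self-loops and no duplicate edges.
#'
#' @examples
#' net <- prob_network(data.frame(from = "a", to = "b", p = 0.5))
#' net
#' @export
prob_network <- function(edges, nodes = NULL, directed = FALSE) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- tibble(from = character(), to = character(), p = numeric())
  }
  edges <- as_tibble(as.data.frame(edges))
  if (ncol(edges) < 3L) {
    abort("`edges` needs three columns: from, to, p.", class = "probnet_validation")
  }
  edges <- setNames(edges[, 1:3], c("from", "to", "p"))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$p <- as.numeric(edges$p)

  bad <- which(!is.finite(edges$p) | edges$p <= 0 | edges$p > 1)
  if (length(bad) > 0L) {
    abort(
      sprintf("edge probability out of (0, 1] at row %d (p = %s)",
              bad[1], format(edges$p[bad[1]])),
      class = "probnet_validation"
    )
  }
  loops <- which(edges$from == edges$to)
  if (length(loops) > 0L) {
    abort(sprintf("self-loop at row %d (%s)", loops[1], edges$from[loops[1]]),
          class = "probnet_validation")
  }
  key <- edge_key(edges$from, edges$to, directed)
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    abort(
      sprintf("duplicate edge at row %d (%s, %s)", dup[1],
              edges$from[dup[1]], edges$to[dup[1]]),
      class = "probnet_validation"
    )
  }
  nodes <- sort(unique(c(as.character(nodes), edges$from, edges$to)))
  structure(
    list(nodes = nodes, edges = edges, directed = isTRUE(directed)),
    class = "prob_network"
  )
}

edge_key <- function(from, to, directed) {
  if (directed) {
    paste(from, to, sep = "\r")
  } else {
    paste(pmin(from, to), pmax(from, to), sep = "\r")
  }
}

#' @export
print.prob_network <- function(x, ...) {
  cat(sprintf(
    "<prob_network: %d nodes, %d edges, %s>\n",
    length(x$nodes), nrow(x$edges), if (x$directed) "directed" else "undirected"
  ))
  print(x$edges, n = 6)
  invisible(x)
}

#' @export
format.prob_network <- function(x, ...) {
  sprintf("<prob_network: %d nodes, %d edges>", length(x$nodes), nrow(x$edges))
}

is_prob_network <- function(x) inherits(x, "prob_network")

assert_network <- function(net) {
  if (!is_prob_network(net)) {
    abort("expected a `prob_network` object", class = "probnet_validation")
  }
  invisible(net)
}

assert_nodes <- function(net, ...) {
  ids <- c(...)
  missing <- setdiff(ids, net$nodes)
  if (length(missing) > 0L) {
    abort(sprintf("node(s) not in network: %s", paste(missing, collapse = ", ")),
          class = "probnet_validation")
  }
  invisible(ids)
}

#' Example five-node probabilistic network
#'
#' The small protein-interaction-style example used throughout the package
#' documentation: five nodes `a, b, c, d, e` and seven edges
#' `(a,d), (b,c), (b,d), (a,c), (c,e), (b,e), (e,d)`. Between `a` and `d` it
#' has five simple paths falling into three length groups (1, 3 and 4), so
#' the shortest-path count between them takes values in `{0, 1, 2}`.
#'
#' @param p Numeric vector of seven edge probabilities (recycled if length
#'   one). The topology is what matters for the worked examples; defaults
#'   are arbitrary but fixed.
#' @return A `prob_network`.
#' @examples
#' toy_network()
#' @export
toy_network <- function(p = c(0.1, 0.8, 0.7, 0.9, 0.6, 0.4, 0.7)) {
  p <- rep_len(p, 7L)
  prob_network(tibble(
    from = c("a", "b", "b", "a", "c", "b", "e"),
    to   = c("d", "c", "d", "c", "e", "e", "d"),
    p    = p
  ))
}

# adjacency list: node -> tibble-free list of (neighbour index, edge index)
adjacency_index <- function(net) {
  n <- length(net$nodes)
  from <- match(net$edges$from, net$nodes)
  to <- match(net$edges$to, net$nodes)
  adj <- vector("list", n)
  nb <- vector("list", n)
  m <- nrow(net$edges)
  if (m > 0L) {
    if (net$directed) {
      ends_u <- from; ends_v <- to; eidx <- seq_len(m)
    } else {
      ends_u <- c(from, to); ends_v <- c(to, from); eidx <- c(seq_len(m), seq_len(m))
    }
    ord <- order(ends_u, net$nodes[ends_v], method = "radix")
    ends_u <- ends_u[ord]; ends_v <- ends_v[ord]; eidx <- eidx[ord]
    sp <- split(seq_along(ends_u), ends_u)
    for (u in names(sp)) {
      i <- as.integer(u)
      adj[[i]] <- eidx[sp[[u]]]
      nb[[i]] <- ends_v[sp[[u]]]
    }
  }
  list(neighbours = nb, edge = adj, n = n)
}
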