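#' Enumerate simple paths between two nodes
#'
#' Locates every simple path (no repeated node) from `source` to `sink` on
#' the network topology with all edges assumed present, by recursive
#' depth-first search. Neighbours are expanded in lexicographic node-id
#' order, so the path order is fully deterministic. Exactness of the
#' downstream shortest-path count distribution requires the *complete* path
#' set, so exceeding a cap is a hard error rather than a truncation.
#'
#' @param net A `prob_network`.
#' @param source,sink Distinct node identifiers.
#' @param max_length Optional cap on path length (number of edges);
#'   `Inf` (default) enumerates all lengths. A finite cap makes the
#'   enumeration intentionally partial and is only appropriate for
#'   exploratory use.
#' @param max_paths Hard cap on the number of paths; exceeding it raises an
#'   error of class `probnet_overflow`.
#' @return A tibble with one row per path: `path` (index), `length`,
#'   `edges` (list of integer edge row indices) and `nodes` (list of node-id
#'   sequences). Zero rows when the pair is disconnected.
#' @examples
#' enumerate_simple_paths(toy_network(), "a", "d")
#' @export
enumerate_simple_paths <- function(net, source, sink,
                                   max_length = Inf, max_paths = 1e5) {
  assert_network(net)
  assert_nodes(net, source, sink)
  if (identical(source, sink)) {
    abort("`source` and `sink` must differ", class = "probnet_validation")
  }
  adj <- adjacency_index(net)
  s <- match(source, net$nodes)
  t <- match(sink, net$nodes)

  counts <- lengths(adj$neighbours)
  head <- c(0L, cumsum(counts))
  nbr <- unlist(adj$neighbours, use.names = FALSE) %||% integer(0)
  eid <- unlist(adj$edge, use.names = FALSE) %||% integer(0)
  max_len <- as.integer(min(max_length, adj$n))
  res <- cpp_simple_paths(adj$n, head, as.integer(nbr) - 1L, as.integer(eid) - 1L,
                          s - 1L, t - 1L, max_len, as.double(max_paths))
  if (isTRUE(res$overflow)) {
    abort(
      sprintf("more than max_paths = %d simple paths between %s and %s",
              as.integer(max_paths), source, sink),
      class = "probnet_overflow"
    )
  }
  found_edges <- res$paths
  n_found <- length(found_edges)

  # rebuild node sequences by walking each edge list from the source
  walk_nodes <- function(e) {
    cur <- source
    out <- character(length(e) + 1L)
    out[1L] <- cur
    for (k in seq_along(e)) {
      u <- net$edges$from[e[k]]
      v <- net$edges$to[e[k]]
      cur <- if (u == cur) v else u
      out[k + 1L] <- cur
    }
    out
  }

  tibble(
    path = seq_len(n_found),
    length = vapply(found_edges, length, integer(1)),
    edges = found_edges,
    nodes = lapply(found_edges, walk_nodes)
  )
}

#' Path-edge bipartite graph
#'
#' Captures the dependency among the simple paths connecting one node pair:
#' one side has a node per path (its degree equals the path length), the
#' other a node per distinct underlying edge, and a membership edge links a
#' path to every edge it uses. This graph drives the polynomial algorithm in
#' [count_shortest_paths()].
#'
#' @param paths A nonempty path tibble from [enumerate_simple_paths()], all
#'   for the same source/sink pair.
#' @param net The `prob_network` the paths were enumerated on.
#' @return A `path_edge_bipartite` object: list with `paths` (the input
#'   tibble), `edge_index` (sorted distinct edge rows = the edge-node side),
#'   `membership` (per path, positions into `edge_index`), `p` (edge-node
#'   probabilities) and `net`.
#' @export
path_edge_bipartite <- function(paths, net) {
  assert_network(net)
  if (is.null(paths) || nrow(paths) == 0L) {
    abort("no paths: the shortest-path count is the point mass at 0",
          class = "probnet_validation")
  }
  edge_index <- sort(unique(unlist(paths$edges)))
  membership <- lapply(paths$edges, function(e) match(e, edge_index))
  structure(
    list(
      paths = paths,
      edge_index = edge_index,
      membership = membership,
      p = net$edges$p[edge_index],
      net = net
    ),
    class = "path_edge_bipartite"
  )
}

#' @export
print.path_edge_bipartite <- function(x, ...) {
  cat(sprintf("<path_edge_bipartite: %d path-nodes, %d edge-nodes, %d membership edges>\n",
              nrow(x$paths), length(x$edge_index), sum(lengths(x$membership))))
  invisible(x)
}

#' Degree of an edge-node in the bipartite graph
#'
#' The number of paths that use a given edge.
#'
#' @param bip A `path_edge_bipartite`.
#' @return Integer vector over `bip$edge_index`.
#' @export
edge_node_degree <- function(bip) {
  tab <- tabulate(unlist(bip$membership), nbins = length(bip$edge_index))
  setNames(as.integer(tab),
           paste(bip$net$edges$from[bip$edge_index],
                 bip$net$edges$to[bip$edge_index], sep = "--"))
}

#' Group path-nodes by length
#'
#' Path-nodes are ordered by ascending bipartite degree (= path length) and
#' grouped by equal degree; the groups drive the early-select multiplication
#' schedule.
#'
#' @param bip A `path_edge_bipartite`.
#' @return A tibble with columns `length` (ascending) and `paths` (list of
#'   path indices).
#' @export
group_by_length <- function(bip) {
  lens <- bip$paths$length
  ulen <- sort(unique(lens))
  tibble(
    length = ulen,
    paths = lapply(ulen, function(l) which(lens == l))
  )
}

#' Dump a bipartite graph as a two-column table
#'
#' Debug helper: one row per membership edge (path id, edge id).
#'
#' @param bip A `path_edge_bipartite`.
#' @param path Optional file to write a TSV to.
#' @return A tibble with columns `path` and `edge`, invisibly when writing.
#' @export
bipartite_membership <- function(bip, path = NULL) {
  ids <- paste(bip$net$edges$from[bip$edge_index],
               bip$net$edges$to[bip$edge_index], sep = "--")
  out <- tibble(
    path = rep(bip$paths$path, lengths(bip$membership)),
    edge = ids[unlist(bip$membership)]
  )
  if (!is.null(path)) {
    readr::write_tsv(out, path)
    return(invisible(out))
  }
  out
}
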