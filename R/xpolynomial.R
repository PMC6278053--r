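#' Exact distribution of the number of shortest paths
#'
#' Computes the exact probability law of the random variable "number of
#' shortest `source`-`sink` paths" over all deterministic instances of a
#' probabilistic network, without enumerating the instances.
#'
#' The algorithm multiplies one two-term *edge polynomial*
#' `p_j * prod(x_i) + q_j` per distinct edge of the path-edge bipartite
#' graph, where the product runs over the variables of the paths containing
#' that edge. A *collapse* step fires as soon as the last polynomial
#' touching a path variable has been absorbed: a full exponent means every
#' edge of that path was present, so the variable becomes a path-length
#' marker `t_l`; any smaller exponent means the path is broken and the
#' variable is dropped. Path variables are processed in ascending length
#' groups, and a *select* step fires at the end of each group: a term
#' carrying markers at the current length `r` is retired with `y^j`, `j`
#' being the marker multiplicity, because no longer path can beat a length-r
#' path that is already present. The retired coefficients are exactly the
#' probabilities `p_j = Pr(B = j)`.
#'
#' Terms with identical signatures are merged by summing coefficients after
#' every multiplication; a term whose every path has broken is folded into
#' the disconnection mass immediately. Both are algebraic identities, not
#' approximations, and the result is checked against a mass-conservation
#' guard.
#'
#' @param net A `prob_network`.
#' @param source,sink Distinct node identifiers in `net`.
#' @param max_paths Cap forwarded to [enumerate_simple_paths()].
#' @param max_terms Hard cap on the merged term-pool size (guards against
#'   combinatorial blow-up on path-dense pairs); exceeding it raises a
#'   `probnet_overflow` error.
#' @return An `sp_distribution` object: list with `source`, `sink`,
#'   `support` (`0:k_max`), `prob` (probabilities summing to 1), and the
#'   number of simple paths `n_paths`. `k_max` is the largest per-length
#'   path multiplicity, so the support covers every attainable count.
#' @seealso [expected_count()], [connectivity_probability()],
#'   [oracle_sp_distribution()] for the brute-force cross-check,
#'   [naive_count_shortest_paths()] for the multiply-all reference.
#' @examples
#' d <- count_shortest_paths(toy_network(), "a", "d")
#' tidy(d)
#' expected_count(d)
#' @export
count_shortest_paths <- function(net, source, sink,
                                 max_paths = 1e5, max_terms = 5e5) {
  res <- xp_engine(net, source, sink, max_paths = max_paths,
                   max_terms = max_terms, track = FALSE)
  res$distribution
}

#' Per-pair edge and node contributions to expected betweenness
#'
#' Runs the same polynomial computation as [count_shortest_paths()] but
#' additionally records, every time a term is retired with `j` shortest
#' paths, a weight `coefficient / j` for each edge (and each interior node)
#' of each contributing path: the equal-split rule under which multiple
#' shortest paths between a pair share unit weight.
#'
#' @inheritParams count_shortest_paths
#' @return A list of class `pair_contribution` with elements `distribution`
#'   (the `sp_distribution`), `edges` (tibble `edge`, `from`, `to`,
#'   `contribution`) and `nodes` (tibble `node`, `contribution`); the edge
#'   table covers the edges lying on at least one source-sink path, all
#'   other contributions being zero.
#' @examples
#' pair_edge_contributions(toy_network(), "a", "d")$edges
#' @export
pair_edge_contributions <- function(net, source, sink,
                                    max_paths = 1e5, max_terms = 5e5) {
  res <- xp_engine(net, source, sink, max_paths = max_paths,
                   max_terms = max_terms, track = TRUE)
  structure(
    list(distribution = res$distribution, edges = res$edges, nodes = res$nodes),
    class = "pair_contribution"
  )
}

# ---- the engine -----------------------------------------------------------

# Shared implementation of the two-step early-select algorithm.
# Terms are represented by (coefficient, alive path set, marker state):
# a path is alive in a term iff every one of its already-multiplied edges is
# present in the term's scenario, in which case its x-exponent equals the
# number of those edges -- so the exponent map carries no information beyond
# alive/dead and the pool merges aggressively. The hot loop lives in C++
# (src/xp_engine.cpp); this wrapper handles enumeration, degenerate cases and
# the mass-conservation guard.
xp_engine <- function(net, source, sink, max_paths, max_terms, track) {
  assert_network(net)
  paths <- enumerate_simple_paths(net, source, sink, max_paths = max_paths)
  n_nodes <- length(net$nodes)

  if (nrow(paths) == 0L) {
    dist <- new_sp_distribution(source, sink, prob = 1, n_paths = 0L)
    return(list(
      distribution = dist,
      edges = tibble(edge = integer(), from = character(), to = character(),
                     contribution = numeric()),
      nodes = tibble(node = character(), contribution = numeric())
    ))
  }

  interior <- lapply(paths$nodes, function(nd) {
    match(nd[-c(1L, length(nd))], net$nodes)
  })
  res <- tryCatch(
    cpp_xp_engine(paths$edges, paths$length, net$edges$p, interior,
                  n_nodes, isTRUE(track), as.double(max_terms)),
    error = function(e) {
      if (grepl("max_terms", conditionMessage(e), fixed = TRUE)) {
        abort(conditionMessage(e), class = "probnet_overflow")
      }
      stop(e)
    }
  )
  p_y <- res$prob
  edge_contrib <- res$edge_contrib
  node_contrib <- res$node_contrib

  drift <- abs(sum(p_y) - 1)
  if (drift > 1e-6) {
    abort(sprintf("probability mass drifted by %.3g; internal error", drift),
          class = "probnet_internal")
  }

  dist <- new_sp_distribution(source, sink, prob = p_y, n_paths = nrow(paths))
  on_paths <- sort(unique(unlist(paths$edges)))
  list(
    distribution = dist,
    edges = tibble(
      edge = on_paths,
      from = net$edges$from[on_paths],
      to = net$edges$to[on_paths],
      contribution = edge_contrib[on_paths]
    ),
    nodes = tibble(node = net$nodes, contribution = node_contrib)
  )
}

# ---- distribution type ----------------------------------------------------

new_sp_distribution <- function(source, sink, prob, n_paths) {
  structure(
    list(
      source = source, sink = sink,
      support = seq_along(prob) - 1L,
      prob = as.numeric(prob),
      n_paths = as.integer(n_paths)
    ),
    class = "sp_distribution"
  )
}

#' @export
print.sp_distribution <- function(x, ...) {
  cat(sprintf("<sp_distribution %s ~ %s>\n", x$source, x$sink))
  print(tidy(x), n = length(x$prob))
  cat(sprintf("expected count %.6g, connectivity %.6g\n",
              expected_count(x), connectivity_probability(x)))
  invisible(x)
}

#' Moments of a shortest-path count distribution
#'
#' `expected_count()` returns the mean number of shortest paths,
#' `connectivity_probability()` the probability that at least one path is
#' realised (one minus the mass at zero).
#'
#' @param dist An `sp_distribution`.
#' @return A single number.
#' @export
expected_count <- function(dist) {
  stopifnot(inherits(dist, "sp_distribution"))
  sum(dist$support * dist$prob)
}

#' @rdname expected_count
#' @export
connectivity_probability <- function(dist) {
  stopifnot(inherits(dist, "sp_distribution"))
  1 - dist$prob[1L]
}

#' @export
tidy.sp_distribution <- function(x, ...) {
  tibble(k = x$support, prob = x$prob)
}

#' @export
glance.sp_distribution <- function(x, ...) {
  tibble(
    source = x$source, sink = x$sink,
    n_paths = x$n_paths,
    k_max = max(x$support),
    expected = expected_count(x),
    connectivity = connectivity_probability(x)
  )
}

#' @export
autoplot.sp_distribution <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = factor(.data$k), y = .data$prob)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "number of shortest paths",
      y = "probability",
      title = sprintf("Shortest-path count law, %s ~ %s", object$source, object$sink)
    )
}

#' Serialise a distribution to JSON
#'
#' @param dist An `sp_distribution`.
#' @param path Optional file; when `NULL` the JSON string is returned.
#' @return JSON with fields `source`, `sink`, `support`, `prob`, `expected`.
#' @export
sp_distribution_json <- function(dist, path = NULL) {
  stopifnot(inherits(dist, "sp_distribution"))
  obj <- list(
    source = dist$source, sink = dist$sink,
    support = dist$support, prob = dist$prob,
    expected = expected_count(dist)
  )
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
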