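#' Newman modularity of a deterministic instance
#'
#' The community-grouped form of modularity: for each community `C`,
#' `l_C / m - (d_C / 2m)^2` where `l_C` counts present edges inside `C`,
#' `d_C` sums present degrees over `C`'s nodes and `m` is the instance's
#' present edge count. Equals the pairwise adjacency-matrix definition.
#'
#' @param instance A `det_instance` with at least one present edge
#'   (modularity is undefined on an empty graph).
#' @param partition Data frame with columns `node` and `community` covering
#'   all nodes, or a named vector node -> label.
#' @return A single number `<= 1`.
#' @examples
#' net <- toy_network(p = 1)
#' deterministic_modularity(binarize(net),
#'   data.frame(node = net$nodes, community = c(1, 1, 1, 2, 2)))
#' @export
deterministic_modularity <- function(instance, partition) {
  stopifnot(inherits(instance, "det_instance"))
  part <- as_partition(partition, instance$nodes)
  m <- nrow(instance$edges)
  if (m == 0L) {
    abort("modularity is undefined for an instance with no edges",
          class = "probnet_validation")
  }
  comm <- part$community[match(instance$nodes, part$node)]
  cf <- comm[match(instance$edges$from, instance$nodes)]
  ct <- comm[match(instance$edges$to, instance$nodes)]
  q <- 0
  for (r in sort(unique(comm))) {
    l_c <- sum(cf == r & ct == r)
    d_c <- sum(cf == r) + sum(ct == r)
    q <- q + l_c / m - (d_c / (2 * m))^2
  }
  q
}

as_partition <- function(partition, nodes) {
  if (!is.data.frame(partition)) {
    partition <- tibble(node = names(partition), community = unname(partition))
  }
  part <- normalise_partition(partition)
  missing <- setdiff(nodes, part$node)
  if (length(missing) > 0L) {
    abort(sprintf("partition misses node(s): %s", paste(missing, collapse = ", ")),
          class = "probnet_validation")
  }
  part[part$node %in% nodes, ]
}

#' Expected modularity of a partition of a probabilistic network
#'
#' Computes the expectation of Newman modularity over all deterministic
#' instances without enumerating them. For each community the edges are
#' classified as *within* (both endpoints inside), *boundary* (exactly one
#' endpoint inside) or *outside*; each class yields a univariate polynomial
#' by iteratively multiplying `p_i * v + q_i` factors, so its coefficients
#' are the presence-count law of that class (a Poisson-binomial). Because the
#' classes are disjoint, the coefficient of `x^i y^j z^k` in the product is
#' `a_i * b_j * c_k`, and a term with `i` within, `j` boundary and `k`
#' outside edges contributes
#' `i/(i+j+k) - ((2i+j) / (2(i+j+k)))^2` to the community's expected
#' modularity. The all-absent term (`i = j = k = 0`) contributes 0 - the
#' unique finite choice, which also preserves the deterministic limit.
#'
#' Modularity is defined on the undirected reading of the network; directed
#' input is symmetrised with a warning.
#'
#' @param net A `prob_network`.
#' @param partition As in [deterministic_modularity()]; must cover all nodes
#'   of `net`.
#' @return A `prob_modularity` object: list with `Q` (expected modularity),
#'   `communities` (tibble `community`, `Q_c`, `n_within`, `n_boundary`,
#'   `n_outside`) and `partition`.
#' @examples
#' net <- prob_network(data.frame(from = c("a", "b"), to = c("b", "c"),
#'                                p = c(1, 0.5)))
#' expected_modularity(net, c(a = 1, b = 1, c = 2))$Q
#' @export
expected_modularity <- function(net, partition) {
  assert_network(net)
  if (net$directed) {
    warn("modularity is undirected; treating edges as unordered pairs")
  }
  if (nrow(net$edges) == 0L) {
    abort("expected modularity is undefined for an edgeless network",
          class = "probnet_validation")
  }
  part <- as_partition(partition, net$nodes)
  comm <- part$community[match(net$nodes, part$node)]
  cf <- comm[match(net$edges$from, net$nodes)]
  ct <- comm[match(net$edges$to, net$nodes)]
  labels <- sort(unique(comm))

  rows <- lapply(labels, function(r) {
    within <- cf == r & ct == r
    boundary <- xor(cf == r, ct == r)
    outside <- !(within | boundary)
    a <- presence_count_poly(net$edges$p[within])
    b <- presence_count_poly(net$edges$p[boundary])
    cc <- presence_count_poly(net$edges$p[outside])
    q_c <- xyz_modularity_sum(a, b, cc)
    tibble(
      community = r, Q_c = q_c,
      n_within = sum(within), n_boundary = sum(boundary), n_outside = sum(outside)
    )
  })
  communities <- dplyr::bind_rows(rows)
  structure(
    list(Q = sum(communities$Q_c), communities = communities, partition = part),
    class = "prob_modularity"
  )
}

# coefficients of prod_i (p_i v + q_i): law of the number of present edges,
# built by iterative convolution (quadratic in the class size)
presence_count_poly <- function(p) {
  coef <- 1
  for (pi in p) {
    coef <- c(coef * (1 - pi), 0) + c(0, coef * pi)
  }
  coef
}

xyz_modularity_sum <- function(a, b, cc) {
  i <- seq_along(a) - 1L
  j <- seq_along(b) - 1L
  k <- seq_along(cc) - 1L
  alpha <- outer(outer(a, b), cc)
  I <- array(rep(i, times = length(j) * length(k)), dim = dim(alpha))
  J <- aperm(array(rep(j, times = length(i) * length(k)),
                   dim = c(length(j), length(i), length(k))), c(2, 1, 3))
  K <- aperm(array(rep(k, times = length(i) * length(j)),
                   dim = c(length(k), length(i), length(j))), c(2, 3, 1))
  m <- I + J + K
  g <- ifelse(m == 0, 0, I / m - ((2 * I + J) / (2 * m))^2)
  sum(alpha * g)
}

#' @export
print.prob_modularity <- function(x, ...) {
  cat(sprintf("<prob_modularity: Q = %.6g over %d communities>\n",
              x$Q, nrow(x$communities)))
  print(x$communities)
  invisible(x)
}

#' @export
tidy.prob_modularity <- function(x, ...) x$communities

#' @export
glance.prob_modularity <- function(x, ...) {
  tibble(Q = x$Q, k = nrow(x$communities))
}

#' Community detection by divisive edge removal
#'
#' Adapts the Girvan-Newman divisive algorithm to probabilistic networks:
#' repeatedly remove the edge with the highest *expected* betweenness
#' (recomputed after every removal, ties broken by lexicographic edge id),
#' record the connected components of the surviving topology as a candidate
#' partition, score each candidate by its expected modularity with respect
#' to the *original* probabilistic network, and return the best level.
#' Components are taken on the surviving topology with every remaining edge
#' treated as present; the probabilistic structure enters through the
#' betweenness ranking and the modularity expectation.
#'
#' @param net A `prob_network` with at least one edge. Directed input is
#'   symmetrised for the modularity score (with a warning).
#' @param max_paths,max_terms Forwarded to the betweenness computation.
#' @return A `prob_communities` object: list with `partition` (tibble
#'   `node`, `community` of the best level), `Q` (its expected modularity),
#'   `dendrogram` (tibble `step`, `removed_from`, `removed_to`,
#'   `betweenness`, `n_communities`, `modularity`; step 0 is the intact
#'   network) and `best_step`.
#' @examples
#' bridged <- two_triangles_bridge()
#' detect_communities(bridged)
#' @export
detect_communities <- function(net, max_paths = 1e5, max_terms = 5e5) {
  assert_network(net)
  if (nrow(net$edges) == 0L) {
    abort("cannot detect communities in an edgeless network", class = "probnet_validation")
  }
  work <- net
  levels <- list()
  removals <- tibble(step = 0L, removed_from = NA_character_,
                     removed_to = NA_character_, betweenness = NA_real_)
  step <- 0L
  repeat {
    part <- components_partition(work)
    q <- suppressWarnings(expected_modularity(net, part))$Q
    levels[[step + 1L]] <- list(partition = part, Q = q)
    if (nrow(work$edges) == 0L) break
    bt <- expected_edge_betweenness(work, max_paths = max_paths, max_terms = max_terms)
    key <- edge_key(bt$from, bt$to, work$directed)
    best <- order(-bt$betweenness, key)[1L]
    step <- step + 1L
    removals <- dplyr::bind_rows(removals, tibble(
      step = step, removed_from = bt$from[best], removed_to = bt$to[best],
      betweenness = bt$betweenness[best]
    ))
    work$edges <- work$edges[-best, ]
  }
  qs <- vapply(levels, `[[`, numeric(1), "Q")
  ks <- vapply(levels, function(l) max(l$partition$community), numeric(1))
  best_step <- which.max(qs) - 1L
  dendrogram <- dplyr::mutate(removals, n_communities = ks, modularity = qs)
  structure(
    list(
      partition = levels[[best_step + 1L]]$partition,
      Q = qs[best_step + 1L],
      dendrogram = dendrogram,
      best_step = best_step
    ),
    class = "prob_communities"
  )
}

components_partition <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  memb <- igraph::components(g)$membership
  normalise_partition(tibble(node = names(memb), community = as.integer(memb)))
}

#' @export
print.prob_communities <- function(x, ...) {
  cat(sprintf("<prob_communities: %d communities, expected modularity %.6g (step %d)>\n",
              max(x$partition$community), x$Q, x$best_step))
  print(x$partition, n = 10)
  invisible(x)
}

#' @export
tidy.prob_communities <- function(x, ...) x$partition

#' @export
glance.prob_communities <- function(x, ...) {
  tibble(k = max(x$partition$community), Q = x$Q,
         best_step = x$best_step, n_steps = nrow(x$dendrogram) - 1L)
}

#' @export
autoplot.prob_communities <- function(object, ...) {
  ggplot2::ggplot(object$dendrogram,
                  ggplot2::aes(x = .data$step, y = .data$modularity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_step, linetype = "dashed") +
    ggplot2::labs(x = "edges removed", y = "expected modularity",
                  title = "Divisive community detection trace")
}

#' Rand index of two partitions
#'
#' Fraction of node pairs on which two partitions agree: co-clustered in
#' both, or separated in both.
#'
#' @param part1,part2 Partitions over the same node set (data frame with
#'   `node`, `community`, or a named vector).
#' @return A number in `[0, 1]`.
#' @examples
#' rand_index(c(a = 1, b = 1, c = 2), c(a = 1, b = 2, c = 3))
#' @export
rand_index <- function(part1, part2) {
  p1 <- if (is.data.frame(part1)) normalise_partition(part1) else
    normalise_partition(tibble(node = names(part1), community = unname(part1)))
  p2 <- if (is.data.frame(part2)) normalise_partition(part2) else
    normalise_partition(tibble(node = names(part2), community = unname(part2)))
  if (!setequal(p1$node, p2$node)) {
    abort("partitions cover different node sets", class = "probnet_validation")
  }
  c1 <- p1$community
  c2 <- p2$community[match(p1$node, p2$node)]
  n <- length(c1)
  if (n < 2L) return(1)
  tab <- table(c1, c2)
  s_ij <- sum(choose(tab, 2))
  s_i <- sum(choose(rowSums(tab), 2))
  s_j <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  a0 <- s_ij
  a1 <- total - s_i - s_j + s_ij
  (a0 + a1) / total
}

#' Literature z-score
#'
#' Standardises a publication count against the mean and standard deviation
#' of counts over comparable pairs: `z = (eta - mu) / sigma`. Values above 2
#' are the conventional reporting threshold.
#'
#' @param eta Observed count(s).
#' @param mu Mean count.
#' @param sigma Standard deviation, strictly positive.
#' @return Numeric z-score(s).
#' @export
literature_zscore <- function(eta, mu, sigma) {
  if (!is.numeric(sigma) || any(sigma <= 0)) {
    abort("`sigma` must be positive", class = "probnet_validation")
  }
  (eta - mu) / sigma
}

#' Two communities joined by a weak bridge
#'
#' A six-node fixture: two triangles with strong internal edges (`p = 0.9`)
#' joined by a single weak bridge (`p = 0.1`). The bridge carries all
#' inter-community shortest paths, so divisive community detection recovers
#' the two triangles.
#'
#' @param p_in,p_bridge Internal and bridge edge probabilities.
#' @return A `prob_network`.
#' @export
two_triangles_bridge <- function(p_in = 0.9, p_bridge = 0.1) {
  prob_network(tibble(
    from = c("a", "a", "b", "d", "d", "e", "c"),
    to   = c("b", "c", "c", "e", "f", "f", "d"),
    p    = c(rep(p_in, 6), p_bridge)
  ))
}
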