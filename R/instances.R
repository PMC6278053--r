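#' Deterministic instances of a probabilistic network
#'
#' A deterministic instance keeps the node set of its parent network and a
#' subset of the parent's edges, with probabilities dropped. The helper
#' constructors below realise the three baseline transforms (binarise,
#' threshold, Bernoulli sampling) and exact enumeration.
#'
#' @param net A `prob_network`.
#' @param present Integer vector of edge row indices into `net$edges` (or a
#'   logical vector over all edges) that are present.
#' @return A `det_instance`: list with `nodes`, `edges` (tibble `from`, `to`),
#'   `edge_index` (rows of the parent edge table) and `directed`.
#' @export
det_instance <- function(net, present) {
  assert_network(net)
  m <- nrow(net$edges)
  if (is.logical(present)) {
    if (length(present) != m) {
      abort("logical `present` must have one entry per edge", class = "probnet_validation")
    }
    present <- which(present)
  }
  present <- as.integer(present)
  if (length(present) > 0L && (min(present) < 1L || max(present) > m)) {
    abort("`present` refers to edges outside the network", class = "probnet_validation")
  }
  if (anyDuplicated(present)) {
    abort("`present` lists an edge twice", class = "probnet_validation")
  }
  structure(
    list(
      nodes = net$nodes,
      edges = net$edges[present, c("from", "to")],
      edge_index = sort(present),
      directed = net$directed
    ),
    class = "det_instance"
  )
}

#' @export
print.det_instance <- function(x, ...) {
  cat(sprintf("<det_instance: %d nodes, %d present edges>\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Probability of observing a deterministic instance
#'
#' Under edge independence the probability of an instance is the product of
#' `p` over present edges times the product of `1 - p` over absent edges.
#'
#' @param net A `prob_network`.
#' @param present Present edge subset: integer row indices into `net$edges`,
#'   a logical vector over all edges, or a `det_instance` derived from `net`.
#' @return A probability in `[0, 1]`.
#' @examples
#' net <- toy_network(p = 0.5)
#' instance_probability(net, seq_len(7)) # 0.5^7
#' @export
instance_probability <- function(net, present) {
  assert_network(net)
  m <- nrow(net$edges)
  if (inherits(present, "det_instance")) present <- present$edge_index
  if (is.logical(present)) present <- which(present)
  present <- as.integer(present)
  if (length(present) > 0L && (min(present) < 1L || max(present) > m)) {
    abort("`present` refers to edges outside the network", class = "probnet_validation")
  }
  keep <- rep(FALSE, m)
  keep[present] <- TRUE
  prod(ifelse(keep, net$edges$p, 1 - net$edges$p))
}

#' Enumerate all deterministic instances
#'
#' Yields the full distribution over the `2^m` deterministic instances. This
#' is exponential in the number of edges, so a hard limit guards against
#' accidental blow-up.
#'
#' @param net A `prob_network`.
#' @param max_edges Refuse to enumerate networks with more edges than this.
#' @return A tibble with columns `present` (list of integer edge-index
#'   vectors) and `probability`, one row per instance. Probabilities sum
#'   to 1.
#' @examples
#' enumerate_instances(prob_network(data.frame(from = "a", to = "b", p = .3)))
#' @export
enumerate_instances <- function(net, max_edges = 20L) {
  assert_network(net)
  m <- nrow(net$edges)
  if (m > max_edges) {
    abort(
      sprintf("refusing to enumerate 2^%d instances (limit max_edges = %d)", m, max_edges),
      class = "probnet_overflow"
    )
  }
  n_inst <- 2^m
  p <- net$edges$p
  masks <- instance_masks(m)
  prob <- vapply(seq_len(n_inst), function(i) {
    keep <- masks[[i]]
    pres <- rep(FALSE, m); pres[keep] <- TRUE
    prod(ifelse(pres, p, 1 - p))
  }, numeric(1))
  tibble(present = masks, probability = prob)
}

# all subsets of 1..m as integer vectors, in binary-counter order
instance_masks <- function(m) {
  if (m == 0L) return(list(integer()))
  lapply(0:(2^m - 1), function(bits) which(bitwAnd(bits, 2^(0:(m - 1))) > 0L))
}

#' Sample a deterministic instance
#'
#' Performs one independent Bernoulli trial per edge with its presence
#' probability.
#'
#' @param net A `prob_network`.
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used (set a seed with [set.seed()] for reproducibility).
#' @return A `det_instance`.
#' @export
sample_instance <- function(net, seed = NULL) {
  assert_network(net)
  draw <- function() runif(nrow(net$edges)) < net$edges$p
  keep <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  det_instance(net, which(keep))
}

#' Baseline transforms to a deterministic network
#'
#' `binarize()` keeps every edge regardless of probability; the threshold
#' transform keeps exactly the edges with probability strictly above `tau`
#' (so `tau = 0.6` removes an edge with `p = 0.6`). With all probabilities
#' identical the threshold transform is degenerate: it keeps either every
#' edge or none.
#'
#' @param net A `prob_network`.
#' @return A `det_instance`.
#' @examples
#' nrow(binarize(toy_network())$edges)   # 7
#' @export
binarize <- function(net) {
  assert_network(net)
  det_instance(net, seq_len(nrow(net$edges)))
}

#' @rdname binarize
#' @param tau Threshold in `[0, 1]`; edges with `p > tau` are kept.
#' @export
threshold_transform <- function(net, tau) {
  assert_network(net)
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau)) {
    abort("`tau` must be a single number", class = "probnet_validation")
  }
  det_instance(net, which(net$edges$p > tau))
}
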