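#' Symbolic polynomial terms and the collapse/select operators
#'
#' These helpers expose the polynomial algebra in its literal textbook form:
#' a term carries a coefficient, an exponent per path variable `x_i`, a
#' multiplicity per path-length marker `t_l`, and a shortest-path marker
#' exponent `y`. [naive_count_shortest_paths()] is written in terms of these
#' operators; the production algorithm in [count_shortest_paths()] uses a
#' merged representation that is algebraically equivalent but far smaller.
#'
#' @param coefficient Probability mass of the term.
#' @param x_exponents Named integer vector, path index -> exponent.
#' @param t_markers Named integer vector, path length -> marker multiplicity.
#' @param y_exponent Integer shortest-path count carried by the term.
#' @return `poly_term()` returns a `poly_term` object; the operators return
#'   a transformed `poly_term`.
#' @examples
#' tm <- poly_term(0.5, c(`1` = 1, `2` = 3))
#' collapse_term(collapse_term(tm, 1, deg = 1, len = 1), 2, deg = 3, len = 3)
#' @export
poly_term <- function(coefficient, x_exponents = integer(), t_markers = integer(),
                      y_exponent = 0L) {
  stopifnot(is.numeric(coefficient), length(coefficient) == 1L)
  x_exponents <- as_named_int(x_exponents)
  t_markers <- as_named_int(t_markers)
  if (y_exponent > 0L && length(x_exponents) > 0L && any(x_exponents > 0L)) {
    abort("a selected term cannot carry live x variables", class = "probnet_validation")
  }
  structure(
    list(coefficient = coefficient, x_exponents = x_exponents,
         t_markers = t_markers, y_exponent = as.integer(y_exponent)),
    class = "poly_term"
  )
}

as_named_int <- function(x) {
  x <- x[x != 0L]
  v <- as.integer(x)
  names(v) <- names(x)
  v
}

#' @export
print.poly_term <- function(x, ...) {
  parts <- format(x$coefficient)
  if (length(x$x_exponents)) {
    parts <- c(parts, sprintf("x%s^%d", names(x$x_exponents), x$x_exponents))
  }
  if (length(x$t_markers)) {
    parts <- c(parts, sprintf("t%s^%d", names(x$t_markers), x$t_markers))
  }
  if (x$y_exponent > 0L) parts <- c(parts, sprintf("y^%d", x$y_exponent))
  cat(paste(parts, collapse = " * "), "\n")
  invisible(x)
}

#' Edge polynomial of an edge-node
#'
#' The two-term polynomial `p_j * prod(x_i) + q_j` of an edge-node of the
#' path-edge bipartite graph, the product running over the path variables of
#' the paths containing the edge.
#'
#' @param bip A [path_edge_bipartite()].
#' @param edge_node Position of the edge-node in `bip$edge_index`.
#' @return An `edge_polynomial`: list with `p`, `q`, `paths` (the path
#'   indices whose variables appear in the present term) and `edge` (the row
#'   of the underlying edge in the network's edge table).
#' @examples
#' bip <- path_edge_bipartite(enumerate_simple_paths(toy_network(), "a", "d"),
#'                            toy_network())
#' edge_polynomial(bip, 1)
#' @export
edge_polynomial <- function(bip, edge_node) {
  stopifnot(inherits(bip, "path_edge_bipartite"))
  edge_node <- as.integer(edge_node)
  if (edge_node < 1L || edge_node > length(bip$edge_index)) {
    abort("unknown edge-node", class = "probnet_validation")
  }
  paths <- which(vapply(bip$membership, function(js) edge_node %in% js, logical(1)))
  structure(
    list(p = bip$p[edge_node], q = 1 - bip$p[edge_node],
         paths = paths, edge = bip$edge_index[edge_node]),
    class = "edge_polynomial"
  )
}

#' @export
print.edge_polynomial <- function(x, ...) {
  cat(sprintf("%s * %s + %s\n", format(x$p),
              paste(sprintf("x%d", x$paths), collapse = " * "), format(x$q)))
  invisible(x)
}

#' @rdname poly_term
#' @param term A `poly_term`.
#' @param r Path index whose variable is collapsed.
#' @param deg Bipartite degree of the path-node (= path length).
#' @param len Path length used for the marker; defaults to `deg`.
#' @details `collapse_term()` may only be applied once the final edge
#'   polynomial of `x_r` has been multiplied in: a full exponent
#'   (`c_r = deg`) turns the variable into a length marker `t_len`, any
#'   smaller exponent deletes it (the path is broken). An exponent above the
#'   degree is an internal inconsistency.
#' @export
collapse_term <- function(term, r, deg, len = deg) {
  stopifnot(inherits(term, "poly_term"))
  key <- as.character(r)
  c_r <- term$x_exponents[key]
  c_r <- if (is.na(c_r)) 0L else as.integer(c_r)
  if (c_r > deg) {
    abort(sprintf("exponent %d of x%s exceeds its degree %d", c_r, key, deg),
          class = "probnet_internal")
  }
  x <- term$x_exponents[setdiff(names(term$x_exponents), key)]
  t <- term$t_markers
  if (c_r == deg) {
    lkey <- as.character(len)
    t[lkey] <- (if (lkey %in% names(t)) t[[lkey]] else 0L) + 1L
  }
  poly_term(term$coefficient, x, t, term$y_exponent)
}

#' @rdname poly_term
#' @details `select_term()` keeps only the smallest-length marker of a term,
#'   converting its multiplicity into the exponent of `y` and discarding all
#'   longer markers; it errors when the term carries no marker.
#' @export
select_term <- function(term) {
  stopifnot(inherits(term, "poly_term"))
  if (length(term$t_markers) == 0L) {
    abort("term carries no t marker; nothing to select", class = "probnet_validation")
  }
  lens <- as.numeric(names(term$t_markers))
  j <- term$t_markers[[which.min(lens)]]
  poly_term(term$coefficient, integer(), integer(), y_exponent = j)
}

#' Reference shortest-path count by full polynomial expansion
#'
#' Multiplies *all* edge polynomials, collapses every path variable once its
#' last polynomial is in, and applies the select operator only at the very
#' end. This is the direct transcription of the algebra and serves as an
#' internal reference for the early-select production algorithm, which must
#' agree with it exactly on every input. Exponential in the number of
#' distinct path edges, so only suitable for small path sets.
#'
#' @inheritParams count_shortest_paths
#' @return An `sp_distribution`.
#' @export
naive_count_shortest_paths <- function(net, source, sink, max_paths = 1e4) {
  assert_network(net)
  paths <- enumerate_simple_paths(net, source, sink, max_paths = max_paths)
  if (nrow(paths) == 0L) {
    return(new_sp_distribution(source, sink, prob = 1, n_paths = 0L))
  }
  bip <- path_edge_bipartite(paths, net)
  lens <- paths$length
  k_max <- max(tabulate(lens))
  n_e <- length(bip$edge_index)
  polys <- lapply(seq_len(n_e), function(j) edge_polynomial(bip, j))
  # last polynomial touching each path variable, in plain 1..n_e order
  final_of <- vapply(seq_len(nrow(paths)), function(i) {
    max(which(vapply(polys, function(z) i %in% z$paths, logical(1))))
  }, numeric(1))

  terms <- list(poly_term(1))
  for (j in seq_len(n_e)) {
    z <- polys[[j]]
    out <- list()
    for (tm in terms) {
      if (z$p > 0) {
        x1 <- tm$x_exponents
        for (i in z$paths) {
          key <- as.character(i)
          x1[key] <- (if (key %in% names(x1)) x1[[key]] else 0L) + 1L
        }
        out[[length(out) + 1L]] <- poly_term(tm$coefficient * z$p, x1, tm$t_markers)
      }
      if (z$q > 0) {
        out[[length(out) + 1L]] <- poly_term(tm$coefficient * z$q, tm$x_exponents, tm$t_markers)
      }
    }
    # collapse variables whose final edge polynomial was just multiplied
    done <- which(final_of == j)
    if (length(done)) {
      out <- lapply(out, function(tm) {
        for (r in done) tm <- collapse_term(tm, r, deg = lens[r], len = lens[r])
        tm
      })
    }
    terms <- merge_poly_terms(out)
  }

  p_y <- numeric(k_max + 1L)
  for (tm in terms) {
    if (length(tm$t_markers) == 0L) {
      p_y[1L] <- p_y[1L] + tm$coefficient
    } else {
      sel <- select_term(tm)
      p_y[sel$y_exponent + 1L] <- p_y[sel$y_exponent + 1L] + sel$coefficient
    }
  }
  drift <- abs(sum(p_y) - 1)
  if (drift > 1e-6) {
    abort(sprintf("probability mass drifted by %.3g; internal error", drift),
          class = "probnet_internal")
  }
  new_sp_distribution(source, sink, prob = p_y, n_paths = nrow(paths))
}

merge_poly_terms <- function(terms) {
  sig <- vapply(terms, function(tm) {
    xo <- order(as.integer(names(tm$x_exponents)))
    to <- order(as.numeric(names(tm$t_markers)))
    paste(
      paste(names(tm$x_exponents)[xo], tm$x_exponents[xo], collapse = ",", sep = ":"),
      paste(names(tm$t_markers)[to], tm$t_markers[to], collapse = ",", sep = ":"),
      tm$y_exponent,
      sep = "|"
    )
  }, character(1))
  first <- which(!duplicated(sig))
  grp <- match(sig, sig[first])
  coefs <- as.numeric(rowsum(vapply(terms, `[[`, numeric(1), "coefficient"), grp,
                             reorder = FALSE))
  lapply(seq_along(first), function(k) {
    tm <- terms[[first[k]]]
    tm$coefficient <- coefs[k]
    tm
  })
}
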