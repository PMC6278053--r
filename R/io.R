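#' Read and write probabilistic networks
#'
#' The native edge-list format is a three-column tab-separated file
#' (`source`, `target`, `probability`), diff-friendly by design:
#' `#`-prefixed lines are comments, and an optional `#nodes:` line lists
#' isolated nodes (tab-separated) that carry no edges. GraphML input/output
#' goes through igraph and stores the probability in the `probability` edge
#' attribute.
#'
#' @param path File path.
#' @param format One of `"edgelist"` or `"graphml"`; `read_network()` picks
#'   by file extension when not given.
#' @param directed Logical, passed to [prob_network()].
#' @return A `prob_network` for readers; the input (invisibly) for writers.
#' @name network_io
NULL

#' @rdname network_io
#' @export
read_network <- function(path, format = NULL, directed = FALSE) {
  if (is.null(format)) {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "edgelist"
  }
  format <- match.arg(format, c("edgelist", "graphml"))
  switch(format,
    edgelist = read_edgelist(path, directed = directed),
    graphml = read_graphml(path, directed = directed)
  )
}

#' @rdname network_io
#' @export
read_edgelist <- function(path, directed = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "probnet_io")
  }
  lines <- readLines(path)
  nodes <- character()
  rows <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i], which = "right")
    if (nchar(line) == 0L) next
    if (startsWith(line, "#nodes:")) {
      extra <- strsplit(sub("^#nodes:[ \t]*", "", line), "\t", fixed = TRUE)[[1]]
      nodes <- c(nodes, extra[nzchar(extra)])
      next
    }
    if (startsWith(line, "#")) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      # tolerate space-separated records for hand-written files
      fields <- strsplit(line, "[ \t]+")[[1]]
    }
    if (length(fields) != 3L) {
      abort(sprintf("line %d: expected 3 fields, got %d", i, length(fields)),
            class = "probnet_parse")
    }
    p <- suppressWarnings(as.numeric(fields[3]))
    if (is.na(p)) {
      abort(sprintf("line %d: probability `%s` is not a number", i, fields[3]),
            class = "probnet_parse")
    }
    if (p <= 0 || p > 1) {
      abort(sprintf("line %d: probability %s outside (0, 1]", i, fields[3]),
            class = "probnet_validation")
    }
    rows[[length(rows) + 1L]] <- tibble(from = fields[1], to = fields[2], p = p)
  }
  edges <- if (length(rows)) dplyr::bind_rows(rows) else NULL
  prob_network(edges, nodes = nodes, directed = directed)
}

#' @rdname network_io
#' @param net A `prob_network`.
#' @export
write_edgelist <- function(net, path) {
  assert_network(net)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# probabilistic network edge list: source\ttarget\tprobability", con)
  isolated <- setdiff(net$nodes, c(net$edges$from, net$edges$to))
  if (length(isolated) > 0L) {
    writeLines(paste0("#nodes:\t", paste(isolated, collapse = "\t")), con)
  }
  if (nrow(net$edges) > 0L) {
    writeLines(
      sprintf("%s\t%s\t%s", net$edges$from, net$edges$to,
              formatC(net$edges$p, digits = 17, format = "g")),
      con
    )
  }
  invisible(net)
}

#' @rdname network_io
#' @export
read_graphml <- function(path, directed = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "probnet_io")
  }
  g <- igraph::read_graph(path, format = "graphml")
  if (!"probability" %in% igraph::edge_attr_names(g)) {
    abort("GraphML file has no `probability` edge attribute", class = "probnet_parse")
  }
  ends <- igraph::as_edgelist(g, names = TRUE)
  p <- igraph::edge_attr(g, "probability")
  if (any(p <= 0 | p > 1)) {
    abort("GraphML probability outside (0, 1]", class = "probnet_validation")
  }
  prob_network(
    tibble(from = as.character(ends[, 1]), to = as.character(ends[, 2]), p = as.numeric(p)),
    nodes = igraph::V(g)$name,
    directed = directed || igraph::is_directed(g)
  )
}

#' @rdname network_io
#' @export
write_graphml <- function(net, path) {
  assert_network(net)
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(net)
}

#' Convert a probabilistic network to an igraph object
#'
#' Edge probabilities are carried in the `probability` edge attribute.
#'
#' @param net A `prob_network`.
#' @return An igraph graph.
#' @export
as_igraph <- function(net) {
  assert_network(net)
  g <- igraph::graph_from_data_frame(
    net$edges[, c("from", "to")],
    directed = net$directed,
    vertices = data.frame(name = net$nodes)
  )
  igraph::E(g)$probability <- net$edges$p
  g
}

#' Read and write node partitions
#'
#' A partition file is a two-column tab-separated table `node<TAB>community`.
#'
#' @param path File path.
#' @return `read_partition()` returns a tibble with columns `node` and
#'   `community` (integer labels normalised to `1..k`).
#' @name partition_io
#' @export
read_partition <- function(path) {
  df <- readr::read_tsv(path, col_names = c("node", "community"),
                        col_types = "cc", comment = "#")
  normalise_partition(tibble(node = df$node, community = df$community))
}

#' @rdname partition_io
#' @param partition A data frame with columns `node` and `community`.
#' @export
write_partition <- function(partition, path) {
  readr::write_tsv(partition[, c("node", "community")], path, col_names = FALSE)
  invisible(partition)
}

# relabel communities as 1..k in order of first appearance of sorted nodes
normalise_partition <- function(partition) {
  partition <- as_tibble(partition)
  if (anyDuplicated(partition$node)) {
    abort("partition assigns a node more than once", class = "probnet_validation")
  }
  partition <- partition[order(partition$node), ]
  partition$community <- as.integer(factor(partition$community,
                                           levels = unique(partition$community)))
  partition
}
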