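# Protein-protein interaction network parsing, centrality analysis and the
# triple-median hub filter defining the crucial gene cluster.
#
# Edge lists follow the STRING TSV dialect (default columns `#node1`,
# `node2`, `combined_score`); the parsed network is an undirected simple
# graph. Shortest paths are unweighted: the confidence score is kept as
# edge metadata only, consistent with analyzers that report integer degree
# medians.

#' Parse a STRING-dialect TSV edge list
#'
#' Builds an undirected simple graph: duplicate A-B / B-A rows are collapsed
#' keeping the maximum combined score, and self-loops are dropped.
#'
#' @param file Path to a TSV file, or literal text containing newlines.
#' @param columns Named map of the node and score columns.
#' @param min_score Optional confidence cutoff; edges with
#'   `combined_score < min_score` are dropped (no cutoff by default).
#' @return A `ppi_network`: list with `nodes` (character) and `edges`
#'   (tibble `a`, `b`, `combined_score` with `a < b`).
#' @export
parse_string_tsv <- function(file,
                             columns = c(node1 = "#node1", node2 = "node2",
                                         score = "combined_score"),
                             min_score = 0) {
  input <- np_read_input(file)
  tab <- readr::read_tsv(input, show_col_types = FALSE, progress = FALSE,
                         comment = "", name_repair = "minimal")
  for (role in names(columns)) {
    if (!columns[[role]] %in% names(tab)) {
      np_stop("np_format_error", "PPI table is missing column '%s' (role: %s)",
              columns[[role]], role)
    }
  }
  n1 <- toupper(trimws(as.character(tab[[columns[["node1"]]]])))
  n2 <- toupper(trimws(as.character(tab[[columns[["node2"]]]])))
  score <- as.numeric(tab[[columns[["score"]]]])
  if (nrow(tab) > 0) {
    np_assert_finite(score, "combined_score")
    if (any(score < 0 | score > 1)) {
      np_stop("np_value_error", "combined_score must lie in [0, 1]")
    }
  }
  edges <- tibble(a = pmin(n1, n2), b = pmax(n1, n2), combined_score = score) |>
    filter(a != b, combined_score >= min_score)
  if (nrow(edges) > 0) {
    edges <- edges |>
      group_by(a, b) |>
      summarise(combined_score = max(combined_score), .groups = "drop")
  }
  net <- list(nodes = sort(unique(c(edges$a, edges$b))), edges = edges)
  class(net) <- "ppi_network"
  net
}

#' Build a PPI network from an edge tibble
#'
#' @param edges Tibble with columns `a`, `b`, `combined_score`.
#' @param nodes Optional full node set (to keep isolated nodes).
#' @return A `ppi_network`.
#' @export
ppi_network <- function(edges, nodes = NULL) {
  edges <- as_tibble(edges)
  edges <- tibble(a = pmin(edges$a, edges$b), b = pmax(edges$a, edges$b),
                  combined_score = edges$combined_score) |>
    filter(a != b)
  if (nrow(edges) > 0) {
    edges <- edges |>
      group_by(a, b) |>
      summarise(combined_score = max(combined_score), .groups = "drop")
  }
  nodes <- sort(unique(c(nodes, edges$a, edges$b)))
  structure(list(nodes = nodes, edges = edges), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network: %d nodes, %d edges>\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

ppi_as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$edges$a, to = net$edges$b,
               combined_score = net$edges$combined_score),
    directed = FALSE,
    vertices = data.frame(name = net$nodes))
  g
}

#' Node centralities of a PPI network
#'
#' Degree (incident edge count), betweenness (pair-dependency sum over
#' unweighted shortest paths, normalized by `(n-1)(n-2)/2` with `n` the
#' total node count) and closeness (`(m-1) / sum of distances` within each
#' connected component of size `m`; isolated nodes score 0).
#'
#' @param net A `ppi_network`.
#' @return Tibble with columns `node`, `degree`, `betweenness`, `closeness`,
#'   one row per node in `net$nodes` order.
#' @export
centralities <- function(net) {
  if (length(net$nodes) == 0) {
    np_stop("np_value_error", "cannot compute centralities of an empty graph")
  }
  g <- ppi_as_igraph(net)
  btw <- if (igraph::vcount(g) < 3) {
    rep(0, igraph::vcount(g))
  } else {
    igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  }
  cls <- suppressWarnings(igraph::closeness(g, normalized = TRUE))
  cls[!is.finite(cls)] <- 0
  btw[!is.finite(btw)] <- 0
  tibble(node = igraph::V(g)$name,
         degree = as.integer(igraph::degree(g)),
         betweenness = unname(btw),
         closeness = unname(cls))
}

#' Triple-median hub filter
#'
#' Retains nodes whose degree, betweenness and closeness all strictly exceed
#' the respective medians computed over all input records (even-length
#' median = mean of the two middle order statistics). This is the "crucial
#' gene cluster" screen.
#'
#' @param records Centrality tibble from [centralities()].
#' @return Character vector of retained node symbols.
#' @export
median_filter <- function(records) {
  if (nrow(records) == 0) {
    np_stop("np_value_error", "median_filter needs at least one record")
  }
  keep <- records$degree > median(records$degree) &
    records$betweenness > median(records$betweenness) &
    records$closeness > median(records$closeness)
  records$node[keep]
}

#' Write a network in SIF format
#'
#' @param x A `ppi_network` or `tripartite_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(x, path) {
  lines <- if (inherits(x, "ppi_network")) {
    sprintf("%s\tpp\t%s", x$edges$a, x$edges$b)
  } else if (inherits(x, "tripartite_network")) {
    sprintf("%s\t%s\t%s", x$edges$from, x$edges$layer, x$edges$to)
  } else {
    np_stop("np_value_error", "write_sif expects a network object")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a network in GraphML format
#'
#' @param x A `ppi_network` or `tripartite_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(x, path) {
  g <- if (inherits(x, "ppi_network")) {
    ppi_as_igraph(x)
  } else if (inherits(x, "tripartite_network")) {
    tripartite_as_igraph(x)
  } else {
    np_stop("np_value_error", "write_graphml expects a network object")
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
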