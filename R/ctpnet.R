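# Tripartite compound-target-pathway network assembly and degree ranking.
#
# The network is a typed graph whose only edges connect compounds to targets
# and targets to pathways; node degree ranks "promising" entities.

#' Build a tripartite compound-target-pathway network
#'
#' Node count equals `|compounds| + |targets| + |pathways|`; edge count
#' equals the number of distinct compound-target plus distinct
#' target-pathway pairs. Edges referencing unknown nodes are rejected and
#' reported (or raise an error in strict mode).
#'
#' @param compounds,targets,pathways Character vectors of node labels; a
#'   label may not appear in more than one type.
#' @param ct_edges Two-column data frame (compound, target) or matrix.
#' @param tp_edges Two-column data frame (target, pathway) or matrix.
#' @param strict If `TRUE`, any invalid edge raises an error.
#' @return A `tripartite_network`: list with `nodes` (tibble `node`,
#'   `type`), `edges` (tibble `from`, `to`, `layer`) and `rejected`.
#' @export
build_tripartite <- function(compounds, targets, pathways,
                             ct_edges = NULL, tp_edges = NULL,
                             strict = FALSE) {
  compounds <- unique(as.character(compounds))
  targets <- unique(as.character(targets))
  pathways <- unique(as.character(pathways))
  overlap <- c(intersect(compounds, targets), intersect(targets, pathways),
               intersect(compounds, pathways))
  if (length(overlap) > 0) {
    np_stop("np_value_error", "node label(s) present in more than one type: %s",
            paste(unique(overlap), collapse = ", "))
  }
  nodes <- tibble(
    node = c(compounds, targets, pathways),
    type = rep(c("compound", "target", "pathway"),
               c(length(compounds), length(targets), length(pathways)))
  )
  norm_edges <- function(e, from_set, to_set, layer) {
    if (is.null(e) || NROW(e) == 0) {
      return(list(edges = tibble(from = character(), to = character(),
                                 layer = character()),
                  rejected = tibble(from = character(), to = character(),
                                    layer = character())))
    }
    e <- as.data.frame(e, stringsAsFactors = FALSE)
    ed <- distinct(tibble(from = as.character(e[[1]]),
                          to = as.character(e[[2]]), layer = layer))
    ok <- ed$from %in% from_set & ed$to %in% to_set
    list(edges = ed[ok, ], rejected = ed[!ok, ])
  }
  ct <- norm_edges(ct_edges, compounds, targets, "ct")
  tp <- norm_edges(tp_edges, targets, pathways, "tp")
  rejected <- bind_rows(ct$rejected, tp$rejected)
  if (strict && nrow(rejected) > 0) {
    np_stop("np_value_error", "%d edge(s) reference unknown nodes, e.g. %s-%s",
            nrow(rejected), rejected$from[1], rejected$to[1])
  }
  structure(list(nodes = nodes, edges = bind_rows(ct$edges, tp$edges),
                 rejected = rejected),
            class = "tripartite_network")
}

#' @export
print.tripartite_network <- function(x, ...) {
  cat(sprintf("<tripartite_network: %d nodes (%s), %d edges>\n",
              nrow(x$nodes),
              paste(table(x$nodes$type)[c("compound", "target", "pathway")],
                    c("compounds", "targets", "pathways"), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

tripartite_as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    data.frame(from = net$edges$from, to = net$edges$to,
               layer = net$edges$layer),
    directed = FALSE,
    vertices = data.frame(name = net$nodes$node, type = net$nodes$type))
}

#' Degree of every node in a tripartite network
#'
#' @param net A `tripartite_network`.
#' @return Tibble `node`, `type`, `degree` (incident edge count).
#' @export
tripartite_degrees <- function(net) {
  deg <- table(factor(c(net$edges$from, net$edges$to),
                      levels = net$nodes$node))
  tibble(node = net$nodes$node, type = net$nodes$type,
         degree = as.integer(deg))
}

#' Rank nodes of one type by degree
#'
#' Top-`k` nodes of the requested type by degree descending; ties broken by
#' node label lexicographic order; `k` larger than the number of nodes
#' returns the full ranking.
#'
#' @param net A `tripartite_network`.
#' @param node_type `"compound"`, `"target"` or `"pathway"`.
#' @param k Number of nodes to return (default all).
#' @return Tibble `node`, `type`, `degree`, `rank` (1-based, consecutive).
#' @export
rank_by_degree <- function(net, node_type = c("target", "compound", "pathway"),
                           k = Inf) {
  node_type <- match.arg(node_type)
  deg <- tripartite_degrees(net)
  deg <- deg[deg$type == node_type, , drop = FALSE]
  deg <- arrange(deg, desc(degree), node)
  deg$rank <- seq_len(nrow(deg))
  head(deg, min(k, nrow(deg)))
}
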