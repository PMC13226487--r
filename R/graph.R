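#' Abstract a skeleton into a vascular graph
#'
#' Bifurcation points and endpoints of the skeleton become graph nodes, and
#' each continuous skeleton segment between a pair of adjacent graph nodes
#' (two bifurcations, or a bifurcation and an endpoint) becomes a graph
#' edge.  Structural degree counts parent, child and fusion links, so
#' anastomoses contribute to node degree and can close cycles.  Isolated
#' nodes and one anchor node per pure cycle are also graph nodes.
#'
#' @param skel a [skeleton()].
#' @return an object of class `vascular_graph`: list with `nodes`
#'   (data.frame `id, x, y, z, degree`), `edges` (list of node-id polyline
#'   paths), `edge_ends` (2-column matrix of graph-node ids) and
#'   `n_components`.
#' @export
build_graph <- function(skel) {
  stopifnot(inherits(skel, "skeleton"))
  sp <- skeleton_paths(skel)
  nodes <- skel$nodes
  gids <- nodes$id[sp$node_idx]
  edge_ends <- if (length(sp$paths)) {
    t(vapply(sp$paths, function(p) c(nodes$id[p[1]], nodes$id[p[length(p)]]),
             numeric(2)))
  } else matrix(numeric(0), ncol = 2)
  degree <- setNames(integer(length(gids)), gids)
  for (k in seq_len(nrow(edge_ends))) {
    a <- as.character(edge_ends[k, 1]); b <- as.character(edge_ends[k, 2])
    degree[a] <- degree[a] + 1L
    degree[b] <- degree[b] + 1L   # self-loop counts twice by falling here too
  }
  gnodes <- data.frame(id = gids,
                       x = nodes$x[sp$node_idx],
                       y = nodes$y[sp$node_idx],
                       z = nodes$z[sp$node_idx],
                       degree = as.integer(degree[as.character(gids)]))
  n_comp <- if (length(gids) == 0) 0L else {
    g <- igraph::graph_from_data_frame(
      d = if (nrow(edge_ends)) data.frame(from = as.character(edge_ends[, 1]),
                                          to = as.character(edge_ends[, 2]))
          else data.frame(from = character(0), to = character(0)),
      directed = FALSE,
      vertices = data.frame(name = as.character(gids)))
    igraph::count_components(g)
  }
  structure(list(nodes = gnodes,
                 edges = lapply(sp$paths, function(p) nodes$id[p]),
                 edge_ends = edge_ends,
                 n_components = n_comp),
            class = "vascular_graph")
}

#' @export
print.vascular_graph <- function(x, ...) {
  cat(sprintf("<vascular_graph: %d nodes, %d edges, %d component(s)>\n",
              nrow(x$nodes), length(x$edges), x$n_components))
  invisible(x)
}

#' Graph-level summary statistics
#'
#' Node and edge counts, the node-degree histogram and the number of
#' connected components, with the handshake identity
#' (sum of degrees = 2 x edge count) asserted.
#'
#' @param graph a [build_graph()] result.
#' @return list with `n_nodes`, `n_edges`, `degree_histogram` (named table),
#'   `n_components`.
#' @export
graph_stats <- function(graph) {
  stopifnot(inherits(graph, "vascular_graph"))
  degs <- graph$nodes$degree
  stopifnot(sum(degs) == 2L * length(graph$edges))
  list(n_nodes = nrow(graph$nodes),
       n_edges = length(graph$edges),
       degree_histogram = table(degs),
       n_components = graph$n_components)
}

#' Export a vascular graph to JSON
#'
#' @param graph a [build_graph()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(graph, path) {
  jsonlite::write_json(
    list(nodes = graph$nodes,
         edges = lapply(graph$edges, as.integer),
         n_components = graph$n_components),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
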