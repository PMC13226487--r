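#' Vascular skeleton (SWC semantics)
#'
#' A skeleton is a forest of 3D points with radii: each node has a unique
#' positive integer id, a position in continuous 0-based voxel-index
#' coordinates (sub-voxel positions allowed), a radius in physical um, and a
#' parent id (`-1` for roots).  Vascular networks contain cycles
#' (anastomoses) that a pure SWC tree cannot express; these are carried as
#' `fusion_links`, unordered pairs of node ids closing a cycle, serialized
#' as `#FUSION i j` comment lines so standard SWC readers still see a
#' forest.
#'
#' @param nodes data.frame with columns `id, type, x, y, z, radius, parent`.
#' @param fusion_links two-column integer matrix of node-id pairs (optional).
#' @return an object of class `skeleton`.
#' @export
skeleton <- function(nodes = empty_nodes(), fusion_links = NULL) {
  nodes <- as.data.frame(nodes)
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nodes)))
    stop("skeleton nodes need columns: ", paste(need, collapse = ", "))
  nodes <- nodes[, need]
  if (anyDuplicated(nodes$id))
    stop("duplicate node id: ", nodes$id[duplicated(nodes$id)][1])
  if (any(nodes$radius < 0)) stop("negative radius")
  bad <- nodes$parent != -1 & !(nodes$parent %in% nodes$id)
  if (any(bad))
    stop("parent id not present: ", nodes$parent[bad][1])
  if (is.null(fusion_links) || NROW(fusion_links) == 0) {
    fusion_links <- matrix(integer(0), ncol = 2)
  } else {
    fusion_links <- matrix(as.integer(fusion_links), ncol = 2)
    if (any(!(fusion_links %in% nodes$id)))
      stop("fusion link references a missing node id")
    if (any(fusion_links[, 1] == fusion_links[, 2]))
      stop("fusion self-link")
    fusion_links <- unique(t(apply(fusion_links, 1, sort)))
    fusion_links <- matrix(as.integer(fusion_links), ncol = 2)
  }
  sk <- structure(list(nodes = nodes, fusion_links = fusion_links),
                  class = "skeleton")
  assert_forest(sk)
  sk
}

empty_nodes <- function() {
  data.frame(id = integer(0), type = integer(0), x = numeric(0),
             y = numeric(0), z = numeric(0), radius = numeric(0),
             parent = integer(0))
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton: %d nodes, %d roots, %d fusion links>\n",
              nrow(x$nodes), sum(x$nodes$parent == -1),
              nrow(x$fusion_links)))
  invisible(x)
}

n_nodes <- function(skel) nrow(skel$nodes)

# detect cycles in parent links (must be a forest)
assert_forest <- function(skel) {
  nodes <- skel$nodes
  if (nrow(nodes) == 0) return(invisible(TRUE))
  idx <- match(nodes$parent, nodes$id)  # NA for roots
  state <- integer(nrow(nodes))         # 0 unseen, 1 in progress, 2 done
  for (i in seq_len(nrow(nodes))) {
    j <- i
    chain <- integer(0)
    while (!is.na(j) && state[j] == 0L) {
      state[j] <- 1L
      chain <- c(chain, j)
      j <- idx[j]
    }
    if (!is.na(j) && state[j] == 1L)
      stop("cycle in parent links involving node id ", nodes$id[j])
    state[chain] <- 2L
  }
  invisible(TRUE)
}

#' Read a skeleton from an SWC file
#'
#' Parses whitespace-delimited 7-column SWC records
#' (`id type x y z radius parent`); `#` lines are comments, except
#' `#FUSION i j` lines which are read back as cycle-closing fusion links.
#' Coordinates are taken as stored (by this package's convention, 0-based
#' voxel indices with radii in um).
#'
#' @param path SWC file path.
#' @return a [skeleton()].
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  fusion <- NULL
  recs <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "") next
    if (startsWith(line, "#")) {
      m <- regmatches(line, regexec("^#\\s*FUSION\\s+(\\d+)\\s+(\\d+)", line,
                                    ignore.case = TRUE))[[1]]
      if (length(m) == 3)
        fusion <- rbind(fusion, as.integer(m[2:3]))
      next
    }
    f <- strsplit(line, "\\s+")[[1]]
    if (length(f) != 7)
      stop(sprintf("malformed SWC line %d: expected 7 fields, got %d",
                   ln, length(f)))
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v)))
      stop(sprintf("malformed SWC line %d: non-numeric field", ln))
    recs[[length(recs) + 1]] <- v
  }
  if (length(recs) == 0) return(skeleton())
  m <- do.call(rbind, recs)
  nodes <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                      parent = as.integer(m[, 7]))
  skeleton(nodes, fusion)
}

#' Write a skeleton to an SWC file
#'
#' Nodes are emitted topologically (parents before children); fusion links
#' become `#FUSION i j` comment lines so the file stays valid SWC for
#' readers that ignore comments.
#'
#' @param skel a [skeleton()].
#' @param path output path.
#' @param digits decimal digits for coordinates and radii (>= 6 significant
#'   digits keeps this package's round-trip exact).
#' @return `path`, invisibly.
#' @export
write_swc <- function(skel, path, digits = 6) {
  stopifnot(inherits(skel, "skeleton"))
  assert_forest(skel)
  nodes <- skel$nodes
  out <- c("# SWC written by vesselbench",
           "# columns: id type x y z radius parent (0-based voxel coords, radius um)")
  if (nrow(skel$fusion_links))
    out <- c(out, sprintf("#FUSION %d %d", skel$fusion_links[, 1],
                          skel$fusion_links[, 2]))
  if (nrow(nodes)) {
    ord <- topo_order(nodes)
    nodes <- nodes[ord, ]
    fmt <- sprintf("%%d %%d %%.%df %%.%df %%.%df %%.%df %%d",
                   digits, digits, digits, digits)
    out <- c(out, sprintf(fmt, nodes$id, nodes$type, nodes$x, nodes$y,
                          nodes$z, nodes$radius, nodes$parent))
  }
  writeLines(out, path)
  invisible(path)
}

topo_order <- function(nodes) {
  idx <- match(nodes$parent, nodes$id)
  depth <- integer(nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    j <- i; d <- 0
    while (!is.na(idx[j])) { d <- d + 1; j <- idx[j]; if (d > nrow(nodes)) stop("cycle in parent links") }
    depth[i] <- d
  }
  order(depth, nodes$id)
}

# --- structural decomposition ----------------------------------------------

# undirected adjacency (parent links + fusion links) as a list keyed by
# position in the node table
skeleton_adjacency <- function(skel) {
  nodes <- skel$nodes
  n <- nrow(nodes)
  adj <- vector("list", n)
  pidx <- match(nodes$parent, nodes$id)
  for (i in seq_len(n)) {
    p <- pidx[i]
    if (!is.na(p)) {
      adj[[i]] <- c(adj[[i]], p)
      adj[[p]] <- c(adj[[p]], i)
    }
  }
  if (nrow(skel$fusion_links)) {
    a <- match(skel$fusion_links[, 1], nodes$id)
    b <- match(skel$fusion_links[, 2], nodes$id)
    for (k in seq_along(a)) {
      adj[[a[k]]] <- c(adj[[a[k]]], b[k])
      adj[[b[k]]] <- c(adj[[b[k]]], a[k])
    }
  }
  adj
}

structural_degree <- function(skel) {
  lengths(skeleton_adjacency(skel))
}

# Decompose a skeleton into maximal degree-2 paths between graph nodes
# (structural degree 1 or >= 3, isolated nodes, and one anchor per pure
# cycle).  Returns row-index paths; both ends of every path are graph nodes.
skeleton_paths <- function(skel) {
  nodes <- skel$nodes
  n <- nrow(nodes)
  if (n == 0)
    return(list(node_idx = integer(0), paths = list(), degree = integer(0)))
  adj <- skeleton_adjacency(skel)
  deg <- lengths(adj)
  is_gnode <- deg != 2L

  # edge bookkeeping: multiset of undirected edges
  ekey <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
  used <- new.env(hash = TRUE)
  mark <- function(a, b) {
    k <- ekey(a, b)
    cnt <- if (is.null(used[[k]])) 0L else used[[k]]
    used[[k]] <- cnt + 1L
  }
  times_used <- function(a, b) {
    k <- ekey(a, b)
    if (is.null(used[[k]])) 0L else used[[k]]
  }
  multiplicity <- function(a, b) sum(adj[[a]] == b)

  paths <- list()
  walk <- function(start, nb) {
    path <- c(start, nb)
    mark(start, nb)
    prev <- start; cur <- nb
    while (!is_gnode[cur]) {
      nxt <- adj[[cur]]
      cand <- nxt[nxt != prev]
      if (length(cand) == 0) cand <- prev  # 2-node multi-edge loop
      nxt <- cand[1]
      mark(cur, nxt)
      path <- c(path, nxt)
      prev <- cur; cur <- nxt
    }
    path
  }

  for (i in which(is_gnode)) {
    for (nb in adj[[i]]) {
      if (times_used(i, nb) < multiplicity(i, nb))
        paths[[length(paths) + 1]] <- walk(i, nb)
    }
  }
  # (edge-use bookkeeping guarantees each path is traced exactly once)
  # leftover pure cycles (every node degree 2)
  on_path <- unique(unlist(paths))
  left <- setdiff(which(deg == 2L), on_path)
  while (length(left)) {
    start <- left[1]
    is_gnode[start] <- TRUE
    p <- walk(start, adj[[start]][1])
    paths[[length(paths) + 1]] <- p
    left <- setdiff(left, p)
  }
  list(node_idx = which(is_gnode), paths = paths, degree = deg)
}

# physical polyline length (um) of a row-index path
path_phys_length <- function(skel, path, voxel_size) {
  if (length(path) < 2) return(0)
  P <- as.matrix(skel$nodes[path, c("x", "y", "z")])
  d <- diff(P) %*% diag(as.numeric(voxel_size)[1:3])
  sum(sqrt(rowSums(d * d)))
}
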