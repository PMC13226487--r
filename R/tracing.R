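#' Parameters for the voxel-scooping tracer
#'
#' @param connectivity neighbourhood used for shell propagation and
#'   clustering (26 is the standard choice).
#' @param cluster_link_radius Chebyshev radius used when linking shell
#'   clusters to the previous shell.
#' @param min_spur_len default terminal-branch length (nodes) for
#'   [prune_spurs()].
#' @param physical_edt use anisotropy-aware physical distances for the
#'   radius-assigning distance transform (default: voxel-index space).
#' @return list of class `scoop_params`.
#' @export
scoop_params <- function(connectivity = 26, cluster_link_radius = 1,
                         min_spur_len = 5, physical_edt = FALSE) {
  stopifnot(connectivity %in% c(6, 26), min_spur_len >= 1)
  structure(list(connectivity = connectivity,
                 cluster_link_radius = cluster_link_radius,
                 min_spur_len = min_spur_len,
                 physical_edt = physical_edt),
            class = "scoop_params")
}

# 26 (or 6) neighbour offsets as an m x 3 matrix
neighbour_offsets <- function(connectivity = 26) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  g
}

# union-find clustering of a voxel set (coords m x 3, 0-based) under
# `connectivity`; returns integer cluster labels 1..k
cluster_voxels <- function(coords, connectivity = 26) {
  m <- nrow(coords)
  if (m == 1) return(1L)
  key <- function(cc) paste(cc[, 1], cc[, 2], cc[, 3])
  idx <- seq_len(m)
  lookup <- new.env(hash = TRUE, size = m)
  ks <- key(coords)
  for (i in idx) lookup[[ks[i]]] <- i
  parent <- idx
  findp <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offs <- neighbour_offsets(connectivity)
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[k, ], "+")
    nk <- key(nb)
    for (i in idx) {
      j <- lookup[[nk[i]]]
      if (!is.null(j) && j > i) {
        ri <- findp(i); rj <- findp(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(idx, findp, integer(1))
  as.integer(factor(roots))
}

#' Voxel-scooping centerline extraction
#'
#' Front-propagation skeletonisation of a binary segmentation.  Per
#' connected component, the front starts at the foreground voxel
#' maximising the Euclidean distance transform (the most interior point)
#' and advances one 26-connected shell of unvisited foreground per
#' iteration ("scooping" the shell away).  Each shell is partitioned into
#' connected clusters; every cluster becomes a skeleton node at its
#' centroid (snapped to the nearest cluster voxel when the centroid falls
#' outside the mask) with radius taken from the distance transform, linked
#' to the adjacent cluster of the previous shell.  A shell splitting into
#' several clusters produces a bifurcation; a cluster touching two
#' different branches of the previous shell marks an anastomosis and is
#' recorded as a fusion link.  Every foreground voxel is visited exactly
#' once.
#'
#' @param seg a [vb_volume()] or array (binarised at 0.5).
#' @param params a [scoop_params()].
#' @return a [skeleton()] with attribute `voxels_visited`.
#' @export
voxel_scoop <- function(seg, params = scoop_params()) {
  vol <- as_vb_volume(seg)
  mask <- vol$data > 0.5
  d <- dim(mask)
  if (!any(mask)) return(skeleton())
  vs <- if (params$physical_edt) as.numeric(vol$voxel_size) else c(1, 1, 1)
  radmap <- edt(mask, vs, to = "background")
  comp <- label_components(mask, 26)
  offs <- neighbour_offsets(params$connectivity)

  depth <- array(-1L, dim = d)
  ids <- integer(0); xs <- ys <- zs <- rs <- numeric(0)
  parents <- integer(0); fusion <- NULL
  nid <- 0L
  visited_total <- 0L
  lin_of <- function(cc) cc[, 1] + d[1] * (cc[, 2] + d[2] * cc[, 3]) + 1
  coord_of <- function(lin) {
    lin0 <- lin - 1
    cbind(lin0 %% d[1], (lin0 %/% d[1]) %% d[2], lin0 %/% (d[1] * d[2]))
  }

  for (ci in seq_len(max(comp))) {
    comp_lin <- which(comp == ci)
    seed <- comp_lin[which.max(radmap[comp_lin])]
    depth[seed] <- 0L
    frontier <- seed
    prev_map <- NULL   # env: linear idx -> node id of previous shell cluster
    while (length(frontier)) {
      visited_total <- visited_total + length(frontier)
      cc <- coord_of(frontier)
      cl <- cluster_voxels(cc, params$connectivity)
      new_map <- new.env(hash = TRUE, size = length(frontier))
      for (c_id in seq_len(max(cl))) {
        sel <- cl == c_id
        vox <- cc[sel, , drop = FALSE]
        centroid <- colMeans(vox)
        rc <- pmin(d - 1, pmax(0, round(centroid)))
        if (mask[rc[1] + 1, rc[2] + 1, rc[3] + 1]) {
          pos <- centroid
          rad <- radmap[rc[1] + 1, rc[2] + 1, rc[3] + 1]
        } else {
          dd <- rowSums(sweep(vox, 2, centroid)^2)
          nearest <- vox[which.min(dd), ]
          pos <- nearest
          rad <- radmap[nearest[1] + 1, nearest[2] + 1, nearest[3] + 1]
        }
        # link to previous-shell clusters
        parent_id <- -1L
        if (!is.null(prev_map)) {
          cand <- integer(0)
          for (k in seq_len(nrow(offs))) {
            nb <- sweep(vox, 2, offs[k, ], "+")
            ok <- nb[, 1] >= 0 & nb[, 2] >= 0 & nb[, 3] >= 0 &
                  nb[, 1] < d[1] & nb[, 2] < d[2] & nb[, 3] < d[3]
            if (!any(ok)) next
            nl <- lin_of(nb[ok, , drop = FALSE])
            for (l in nl) {
              v <- prev_map[[as.character(l)]]
              if (!is.null(v)) cand <- c(cand, v)
            }
          }
          if (length(cand)) {
            tab <- sort(table(cand), decreasing = TRUE)
            parent_id <- as.integer(names(tab)[1])
            if (length(tab) > 1) {
              others <- as.integer(names(tab)[-1])
              fusion <- rbind(fusion, cbind(rep(nid + 1L, length(others)),
                                            others))
            }
          }
        }
        nid <- nid + 1L
        ids[nid] <- nid; xs[nid] <- pos[1]; ys[nid] <- pos[2]
        zs[nid] <- pos[3]; rs[nid] <- rad; parents[nid] <- parent_id
        lv <- lin_of(vox)
        for (l in lv) new_map[[as.character(l)]] <- nid
      }
      # advance the front
      nxt <- integer(0)
      for (k in seq_len(nrow(offs))) {
        nb <- sweep(cc, 2, offs[k, ], "+")
        ok <- nb[, 1] >= 0 & nb[, 2] >= 0 & nb[, 3] >= 0 &
              nb[, 1] < d[1] & nb[, 2] < d[2] & nb[, 3] < d[3]
        if (!any(ok)) next
        nl <- lin_of(nb[ok, , drop = FALSE])
        nl <- nl[mask[nl] & depth[nl] < 0L]
        if (length(nl)) {
          depth[nl] <- 1L   # mark claimed
          nxt <- c(nxt, nl)
        }
      }
      frontier <- nxt
      prev_map <- new_map
    }
  }
  sk <- skeleton(data.frame(id = ids, type = 2L, x = xs, y = ys, z = zs,
                            radius = rs, parent = parents),
                 fusion_links = fusion)
  attr(sk, "voxels_visited") <- visited_total
  sk
}

#' Thinning-based centerline extraction
#'
#' Topology-preserving iterative thinning reduces the binary mask to a
#' one-voxel-wide skeleton; the skeleton voxel graph (26-connectivity) is
#' then classified by neighbour count (1 = endpoint, >= 3 = junction),
#' junction voxel clusters are collapsed to their centroid, paths are
#' traced into edges, and radii are assigned from the distance transform
#' of the input mask.  Cycles that survive thinning are encoded as fusion
#' links.
#'
#' @param seg a [vb_volume()] or array (binarised at 0.5).
#' @param physical_edt use physical distances for the radius-assigning
#'   distance transform.
#' @return a [skeleton()].
#' @export
thinning_trace <- function(seg, physical_edt = FALSE) {
  vol <- as_vb_volume(seg)
  mask <- vol$data > 0.5
  d <- dim(mask)
  if (!any(mask)) return(skeleton())
  vs <- if (physical_edt) as.numeric(vol$voxel_size) else c(1, 1, 1)
  radmap <- edt(mask, vs, to = "background")
  thin <- array(.thin3d_cpp(mask, as.integer(d)), dim = d)
  lin <- which(thin)
  m <- length(lin)
  lin0 <- lin - 1
  coords <- cbind(lin0 %% d[1], (lin0 %/% d[1]) %% d[2],
                  lin0 %/% (d[1] * d[2]))
  pos_of <- setNames(seq_len(m), lin)
  offs <- neighbour_offsets(26)
  # voxel-level adjacency (each undirected pair once)
  elist <- list()
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[k, ], "+")
    ok <- nb[, 1] >= 0 & nb[, 2] >= 0 & nb[, 3] >= 0 &
          nb[, 1] < d[1] & nb[, 2] < d[2] & nb[, 3] < d[3]
    nl <- nb[ok, 1] + d[1] * (nb[ok, 2] + d[2] * nb[ok, 3]) + 1
    j <- pos_of[as.character(nl)]
    i <- which(ok)[!is.na(j)]
    j <- j[!is.na(j)]
    keep <- i < j
    if (any(keep)) elist[[length(elist) + 1]] <- cbind(i[keep], j[keep])
  }
  E <- if (length(elist)) do.call(rbind, elist) else matrix(integer(0), ncol = 2)
  deg <- tabulate(c(E[, 1], E[, 2]), nbins = m)

  # collapse junction voxel clusters
  junc <- which(deg >= 3)
  vgroup <- seq_len(m)           # vertex id per voxel (junctions share)
  gpos <- coords                 # row per voxel; junction rows overwritten
  if (length(junc)) {
    jcl <- cluster_voxels(coords[junc, , drop = FALSE], 26)
    for (g in seq_len(max(jcl))) {
      members <- junc[jcl == g]
      rep_v <- members[1]
      vgroup[members] <- rep_v
      gpos[rep_v, ] <- colMeans(coords[members, , drop = FALSE])
    }
  }
  keep_v <- sort(unique(vgroup))
  vid <- setNames(seq_along(keep_v), keep_v)
  nv <- length(keep_v)
  if (nrow(E)) {
    ge <- cbind(vid[as.character(vgroup[E[, 1]])],
                vid[as.character(vgroup[E[, 2]])])
    ge <- ge[ge[, 1] != ge[, 2], , drop = FALSE]
    if (nrow(ge)) {
      kk <- paste(pmin(ge[, 1], ge[, 2]), pmax(ge[, 1], ge[, 2]))
      ge <- ge[!duplicated(kk), , drop = FALSE]
    }
  } else ge <- matrix(integer(0), ncol = 2)

  adj <- vector("list", nv)
  for (r in seq_len(nrow(ge))) {
    adj[[ge[r, 1]]] <- c(adj[[ge[r, 1]]], ge[r, 2])
    adj[[ge[r, 2]]] <- c(adj[[ge[r, 2]]], ge[r, 1])
  }
  vdeg <- lengths(adj)

  # BFS spanning forest; non-tree edges become fusion links
  parent <- rep(NA_integer_, nv)
  visited <- rep(FALSE, nv)
  order_out <- integer(0)
  fusion <- NULL
  seen_edge <- new.env(hash = TRUE)
  roots <- order(vdeg != 1)      # prefer endpoints as roots
  for (root in seq_len(nv)[roots]) {
    if (visited[root]) next
    visited[root] <- TRUE
    parent[root] <- -1L
    queue <- root
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order_out <- c(order_out, v)
      for (w in adj[[v]]) {
        ek <- paste(min(v, w), max(v, w))
        if (!visited[w]) {
          visited[w] <- TRUE
          parent[w] <- v
          seen_edge[[ek]] <- TRUE
          queue <- c(queue, w)
        } else if (is.null(seen_edge[[ek]])) {
          seen_edge[[ek]] <- TRUE
          fusion <- rbind(fusion, c(v, w))
        }
      }
    }
  }
  new_id <- setNames(seq_len(nv), order_out)   # BFS order -> ids
  voxrow <- keep_v                              # representative voxel row
  px <- gpos[voxrow, 1]; py <- gpos[voxrow, 2]; pz <- gpos[voxrow, 3]
  rad <- radmap[cbind(coords[voxrow, 1] + 1, coords[voxrow, 2] + 1,
                      coords[voxrow, 3] + 1)]
  idv <- as.integer(new_id[as.character(seq_len(nv))])
  parv <- ifelse(parent == -1L, -1L,
                 as.integer(new_id[as.character(parent)]))
  nodes <- data.frame(id = idv, type = 2L, x = px, y = py, z = pz,
                      radius = rad, parent = parv)
  nodes <- nodes[order(nodes$id), ]
  fl <- if (is.null(fusion)) NULL else
    cbind(as.integer(new_id[as.character(fusion[, 1])]),
          as.integer(new_id[as.character(fusion[, 2])]))
  skeleton(nodes, fl)
}

#' Prune short terminal branches (spurs)
#'
#' Skeletonisation of thick vessels produces short false side branches.
#' A terminal edge (one end an endpoint, the other a branch point) is
#' removed when it has fewer than `min_len` nodes or is physically shorter
#' than `radius_factor` times the radius at the attaching branch point.
#' Surviving degree-2 junctions merge implicitly at the graph level; the
#' pass iterates until a fixed point.
#'
#' @param skel a [skeleton()].
#' @param min_len minimum node count of a terminal edge.
#' @param radius_factor length threshold in units of the branch-point
#'   radius.
#' @param voxel_size physical voxel size used for edge lengths.
#' @return the pruned [skeleton()].
#' @export
prune_spurs <- function(skel, min_len = 5, radius_factor = 1.5,
                        voxel_size = c(1, 1, 2)) {
  stopifnot(inherits(skel, "skeleton"))
  vs <- as_voxel_size(voxel_size)
  repeat {
    sp <- skeleton_paths(skel)
    if (!length(sp$paths)) return(skel)
    deg <- sp$degree
    remove <- integer(0)
    for (path in sp$paths) {
      a <- path[1]; b <- path[length(path)]
      da <- deg[a]; db <- deg[b]
      if (xor(da == 1, db == 1) && max(da, db) >= 3) {
        tip <- if (da == 1) a else b
        branch <- if (da == 1) b else a
        plen <- path_phys_length(skel, path, vs)
        if (length(path) < min_len ||
            plen < radius_factor * skel$nodes$radius[branch]) {
          remove <- union(remove, setdiff(path, branch))
        }
      }
    }
    if (!length(remove)) return(skel)
    skel <- drop_nodes(skel, remove)
  }
}

# remove node rows (indices), reparenting survivors through the removed set
drop_nodes <- function(skel, rows) {
  nodes <- skel$nodes
  gone_ids <- nodes$id[rows]
  pidx <- match(nodes$parent, nodes$id)
  resolve <- function(i) {
    j <- pidx[i]
    while (!is.na(j) && j %in% rows) j <- pidx[j]
    if (is.na(j)) -1L else nodes$id[j]
  }
  keep <- setdiff(seq_len(nrow(nodes)), rows)
  newp <- nodes$parent[keep]
  fixme <- which(newp %in% gone_ids)
  for (f in fixme) newp[f] <- resolve(keep[f])
  nd <- nodes[keep, ]
  nd$parent <- newp
  fl <- skel$fusion_links
  if (nrow(fl))
    fl <- fl[!(fl[, 1] %in% gone_ids | fl[, 2] %in% gone_ids), , drop = FALSE]
  skeleton(nd, fl)
}
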