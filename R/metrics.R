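#' Distance-threshold point-set matching (recall / precision / F1)
#'
#' A point of one set matches if its nearest neighbour in the other set is
#' closer than `thre` (Euclidean distance in voxel-index space; strict
#' `<` by default).  Recall is the matched fraction of the ground-truth
#' set G, precision the matched fraction of the predicted set P, and
#' F1 their harmonic mean.  The canonical thresholds are 3 voxels for
#' skeleton points and 5 for branch points.
#'
#' @param P,G numeric matrices (n x 3) of predicted / ground-truth points.
#' @param thre distance threshold in voxels.
#' @param inclusive use `<=` instead of the default strict `<`.
#' @param squared compare squared distances against `thre` (the literal
#'   squared-norm reading; off by default).
#' @return list of class `match_result` with `recall`, `precision`, `f1`,
#'   `n_matched_g`, `n_matched_p`, `n_g`, `n_p` and a `degenerate` flag for
#'   empty inputs.
#' @export
match_points <- function(P, G, thre = 3, inclusive = FALSE, squared = FALSE) {
  stopifnot(thre > 0)
  P <- as_points(P); G <- as_points(G)
  np <- nrow(P); ng <- nrow(G)
  if (np == 0 && ng == 0)
    return(structure(list(recall = 0, precision = 0, f1 = 0,
                          n_matched_g = 0L, n_matched_p = 0L,
                          n_g = 0L, n_p = 0L, degenerate = TRUE),
                     class = "match_result"))
  cmp <- if (inclusive) `<=` else `<`
  hit <- function(A, B) {
    if (nrow(A) == 0) return(logical(0))
    if (nrow(B) == 0) return(rep(FALSE, nrow(A)))
    d <- nn_dist(A, B)
    if (squared) cmp(d^2, thre) else cmp(d, thre)
  }
  hg <- hit(G, P)
  hp <- hit(P, G)
  recall <- if (ng > 0) mean(hg) else 0
  precision <- if (np > 0) mean(hp) else 0
  f1 <- if (recall + precision > 0)
    2 * recall * precision / (recall + precision) else 0
  structure(list(recall = recall, precision = precision, f1 = f1,
                 n_matched_g = sum(hg), n_matched_p = sum(hp),
                 n_g = ng, n_p = np,
                 degenerate = (np == 0 || ng == 0)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match: recall %.4f, precision %.4f, F1 %.4f (Ng=%d, Np=%d)%s>\n",
              x$recall, x$precision, x$f1, x$n_g, x$n_p,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

as_points <- function(x) {
  if (is.null(x)) return(matrix(numeric(0), ncol = 3))
  if (inherits(x, "centerlines") || is.data.frame(x))
    return(as.matrix(x[, c("x", "y", "z")]))
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = TRUE)
  stopifnot(ncol(x) == 3, all(is.finite(x)))
  x
}

# nearest-neighbour distances from each row of A to the set B (chunked
# dense computation; point sets at block scale stay small)
nn_dist <- function(A, B) {
  nb2 <- rowSums(B^2)
  out <- numeric(nrow(A))
  chunk <- max(1, floor(2e6 / nrow(B)))
  for (s in seq(1, nrow(A), by = chunk)) {
    e <- min(nrow(A), s + chunk - 1)
    Ai <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Ai^2), nb2, "+") - 2 * Ai %*% t(B)
    out[s:e] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  out
}

#' Centerline-level skeleton comparison
#'
#' Both skeletons are resampled at `step`-voxel arc-length intervals and
#' the resampled point clouds are matched with the skeleton threshold
#' (3 voxels by default).
#'
#' @param pred,gt [skeleton()]s.
#' @param step resampling interval (voxels).
#' @param thre matching threshold (voxels).
#' @param ... passed to [match_points()].
#' @return a `match_result`.
#' @export
evaluate_skeleton <- function(pred, gt, step = 1.0, thre = 3, ...) {
  match_points(resample_centerline(pred, step),
               resample_centerline(gt, step), thre = thre, ...)
}

#' Branch points and endpoints of a skeleton
#'
#' Branch points are nodes of structural degree >= 3 (parent, child and
#' fusion links all count); endpoints have degree 1.
#'
#' @param skel a [skeleton()].
#' @return n x 3 matrix of point coordinates (attribute `ids` holds node
#'   ids).
#' @export
extract_branch_points <- function(skel) {
  deg <- structural_degree(skel)
  sel <- which(deg >= 3)
  structure(as.matrix(skel$nodes[sel, c("x", "y", "z")]),
            ids = skel$nodes$id[sel])
}

#' @rdname extract_branch_points
#' @export
extract_endpoints <- function(skel) {
  deg <- structural_degree(skel)
  sel <- which(deg == 1)
  structure(as.matrix(skel$nodes[sel, c("x", "y", "z")]),
            ids = skel$nodes$id[sel])
}

#' Branch-point localisation comparison
#'
#' Branch points of both skeletons matched with the branch-point threshold
#' (5 voxels by default).
#'
#' @param pred,gt [skeleton()]s.
#' @param thre matching threshold (voxels).
#' @param ... passed to [match_points()].
#' @return a `match_result`.
#' @export
evaluate_branch_points <- function(pred, gt, thre = 5, ...) {
  match_points(extract_branch_points(pred), extract_branch_points(gt),
               thre = thre, ...)
}

#' Branch angles at bifurcations
#'
#' For every branch point and every incident edge, the local direction is
#' the unit vector (in physical um coordinates) from the branch point to
#' the `k`-th resampled point along the edge (or the edge end when
#' shorter).  One angle is reported per unordered pair of incident edges;
#' pairs are labelled `child-child` or `parent-child` using the SWC parent
#' orientation.
#'
#' @param skel a [skeleton()].
#' @param k direction estimated at the k-th 1-voxel resampled point.
#' @param voxel_size physical voxel size.
#' @return data.frame with `node` (branch node id), `pair` label and
#'   `angle_deg`.
#' @export
branch_angles <- function(skel, k = 5, voxel_size = c(1, 1, 2)) {
  vs <- as.numeric(as_voxel_size(voxel_size))
  sp <- skeleton_paths(skel)
  nodes <- skel$nodes
  deg <- sp$degree
  out <- list()
  branch_rows <- sp$node_idx[deg[sp$node_idx] >= 3]
  for (b in branch_rows) {
    dirs <- list(); kinds <- character(0)
    for (path in sp$paths) {
      ends <- c(path[1], path[length(path)])
      if (!(b %in% ends)) next
      p <- if (path[1] == b) path else rev(path)
      P <- as.matrix(nodes[p, c("x", "y", "z")])
      rs <- resample_path_points(P, step = 1)
      tgt <- rs[min(k + 1, nrow(rs)), ]
      v <- (tgt - P[1, ]) * vs
      nv <- sqrt(sum(v^2))
      if (nv < 1e-9) next
      nxt <- p[2]
      kind <- if (nodes$parent[b] == nodes$id[nxt]) "parent" else "child"
      dirs[[length(dirs) + 1]] <- v / nv
      kinds <- c(kinds, kind)
      if (path[1] == b && path[length(path)] == b) {
        # self-loop contributes its second end too
        P2 <- as.matrix(nodes[rev(p), c("x", "y", "z")])
        rs2 <- resample_path_points(P2, step = 1)
        tgt2 <- rs2[min(k + 1, nrow(rs2)), ]
        v2 <- (tgt2 - P2[1, ]) * vs
        if (sqrt(sum(v2^2)) >= 1e-9) {
          dirs[[length(dirs) + 1]] <- v2 / sqrt(sum(v2^2))
          kinds <- c(kinds, "child")
        }
      }
    }
    nd <- length(dirs)
    if (nd < 2) next
    for (i in seq_len(nd - 1)) for (j in (i + 1):nd) {
      ang <- acos(pmin(1, pmax(-1, sum(dirs[[i]] * dirs[[j]])))) * 180 / pi
      pair <- if ("parent" %in% c(kinds[i], kinds[j])) "parent-child"
              else "child-child"
      out[[length(out) + 1]] <- data.frame(node = nodes$id[b], pair = pair,
                                           angle_deg = ang)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(node = integer(0), pair = character(0),
                  angle_deg = numeric(0))
}

# arc-length resampling of a bare polyline (rows = points)
resample_path_points <- function(P, step = 1) {
  if (nrow(P) < 2) return(P)
  seg <- sqrt(rowSums(diff(P)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L < 1e-12) return(P[1, , drop = FALSE])
  nseg <- max(1, round(L / step))
  u <- seq(0, L, length.out = nseg + 1)
  s2 <- make_strict(s / L) * L
  cbind(stats::approx(s2, P[, 1], xout = u)$y,
        stats::approx(s2, P[, 2], xout = u)$y,
        stats::approx(s2, P[, 3], xout = u)$y)
}

#' Vessel density on a sub-block grid
#'
#' The block is divided into cells of `cell`^3 voxels (partial cells at
#' the boundary keep their exact physical volume); the skeleton is
#' resampled at 1-voxel steps, each inter-point segment's physical length
#' is assigned to the cell containing its midpoint, and density is length
#' over cell volume in mm/mm^3.  A 192^3 block yields exactly 27 cells.
#'
#' @param skel a [skeleton()] inside the block.
#' @param block_shape block extent `(nx, ny, nz)` voxels.
#' @param voxel_size physical voxel size (um).
#' @param cell cell edge length in voxels.
#' @return list of class `density_grid`: `grid` (3D array, mm/mm^3),
#'   `mean`, `sd`, `total_length_mm`.
#' @export
vessel_density <- function(skel, block_shape, voxel_size = c(1, 1, 2),
                           cell = 64) {
  vs <- as.numeric(as_voxel_size(voxel_size))
  shp <- as.integer(block_shape)
  ncell <- pmax(1L, as.integer(ceiling(shp / cell)))
  grid_len <- array(0, dim = ncell)
  cl <- resample_centerline(skel, step = 1)
  total_mm <- 0
  if (nrow(cl) > 1) {
    same_edge <- cl$edge[-1] == cl$edge[-nrow(cl)]
    a <- as.matrix(cl[-nrow(cl), c("x", "y", "z")])[same_edge, , drop = FALSE]
    b <- as.matrix(cl[-1, c("x", "y", "z")])[same_edge, , drop = FALSE]
    if (nrow(a)) {
      seg_um <- sqrt(rowSums(((b - a) %*% diag(vs))^2))
      mid <- (a + b) / 2
      ci <- pmin(floor(mid[, 1] / cell), ncell[1] - 1)
      cj <- pmin(floor(mid[, 2] / cell), ncell[2] - 1)
      ck <- pmin(floor(mid[, 3] / cell), ncell[3] - 1)
      seg_mm <- seg_um * 1e-3
      for (s in seq_along(seg_mm))
        grid_len[ci[s] + 1, cj[s] + 1, ck[s] + 1] <-
          grid_len[ci[s] + 1, cj[s] + 1, ck[s] + 1] + seg_mm[s]
      total_mm <- sum(seg_mm)
    }
  }
  # exact physical cell volumes (partial boundary cells cropped)
  ext <- function(n, k) pmin(cell, n - (seq_len(k) - 1) * cell)
  vx <- ext(shp[1], ncell[1]) * vs[1]
  vy <- ext(shp[2], ncell[2]) * vs[2]
  vz <- ext(shp[3], ncell[3]) * vs[3]
  vol_mm3 <- outer(outer(vx, vy), vz) * 1e-9
  dens <- grid_len / vol_mm3
  structure(list(grid = dens, mean = mean(dens), sd = sd(as.numeric(dens)),
                 total_length_mm = total_mm),
            class = "density_grid")
}

#' Intensity and radius statistics at skeleton points
#'
#' The skeleton is resampled at 1-voxel steps, the volume is sampled
#' trilinearly at each point, and mean/SD of the sampled intensities and
#' of the interpolated radii are reported.
#'
#' @param vol a [vb_volume()].
#' @param skel a [skeleton()].
#' @return list with `mean`, `sd`, `radius_mean`, `radius_sd`, `n`, and an
#'   `empty` flag.
#' @export
skeleton_intensity_stats <- function(vol, skel) {
  cl <- resample_centerline(skel, step = 1)
  if (nrow(cl) == 0)
    return(list(mean = NA_real_, sd = NA_real_, radius_mean = NA_real_,
                radius_sd = NA_real_, n = 0L, empty = TRUE))
  v <- trilinear(vol, as.matrix(cl[, c("x", "y", "z")]))$values
  list(mean = mean(v), sd = sd(v),
       radius_mean = mean(cl$radius), radius_sd = sd(cl$radius),
       n = nrow(cl), empty = FALSE)
}

#' Signal-to-noise ratio of a vessel volume
#'
#' Signal is the mean intensity at skeleton points (or the mask foreground
#' mean when no skeleton is given); background is every voxel outside the
#' mask dilated by `dilation` voxels; SNR = signal / SD(background).
#'
#' @param vol a [vb_volume()].
#' @param gt_mask binary [vb_volume()] or array.
#' @param dilation ball radius (voxels) excluded around the foreground.
#' @param skel optional [skeleton()] for the signal estimate.
#' @return SNR as a numeric scalar with attributes `signal`,
#'   `background_sd` and `infinite`.
#' @export
snr <- function(vol, gt_mask, dilation = 3, skel = NULL) {
  m <- if (inherits(gt_mask, "vb_volume")) gt_mask$data > 0.5 else gt_mask > 0.5
  if (!any(m) || all(m)) stop("mask must be non-empty and not full")
  signal <- if (!is.null(skel)) {
    cl <- resample_centerline(skel, step = 1)
    mean(trilinear(vol, as.matrix(cl[, c("x", "y", "z")]))$values)
  } else mean(vol$data[m])
  bg <- vol$data[!dilate_ball(m, dilation)]
  bsd <- sd(bg)
  if (!is.finite(bsd) || bsd == 0)
    return(structure(Inf, signal = signal, background_sd = bsd,
                     infinite = TRUE))
  structure(signal / bsd, signal = signal, background_sd = bsd,
            infinite = FALSE)
}

#' Propose local regions for connectivity review
#'
#' Slides a cubic window over the volume and emits a region of interest
#' wherever the window contains two or more skeleton endpoints (possible
#' broken connection) or at least one branch point (topology worth
#' checking).  Overlapping regions are merged into bounding boxes, ordered
#' by corner.
#'
#' @param skel a [skeleton()].
#' @param window window edge length (voxels).
#' @param stride window stride (voxels).
#' @param shape volume extent; default the skeleton bounding box.
#' @return data.frame with corner `x0, y0, z0` and size `sx, sy, sz`.
#' @export
smartvision_candidates <- function(skel, window = 32, stride = 16,
                                   shape = NULL) {
  ep <- extract_endpoints(skel)
  bp <- extract_branch_points(skel)
  empty <- data.frame(x0 = numeric(0), y0 = numeric(0), z0 = numeric(0),
                      sx = numeric(0), sy = numeric(0), sz = numeric(0))
  if (nrow(ep) + nrow(bp) == 0) return(empty)
  if (is.null(shape))
    shape <- ceiling(apply(rbind(ep, bp), 2, max)) + 1
  origins <- lapply(1:3, function(a) {
    o <- seq(0, max(0, shape[a] - window), by = stride)
    unique(c(o, max(0, shape[a] - window)))
  })
  rois <- list()
  for (oz in origins[[3]]) for (oy in origins[[2]]) for (ox in origins[[1]]) {
    o <- c(ox, oy, oz)
    inwin <- function(pts) {
      if (nrow(pts) == 0) return(0L)
      sum(pts[, 1] >= o[1] & pts[, 1] < o[1] + window &
          pts[, 2] >= o[2] & pts[, 2] < o[2] + window &
          pts[, 3] >= o[3] & pts[, 3] < o[3] + window)
    }
    if (inwin(ep) >= 2 || inwin(bp) >= 1)
      rois[[length(rois) + 1]] <- c(o, rep(window, 3))
  }
  if (!length(rois)) return(empty)
  R <- do.call(rbind, rois)
  # merge overlapping boxes into bounding boxes, to a fixed point
  repeat {
    merged <- FALSE
    i <- 1
    while (i < nrow(R)) {
      j <- i + 1
      while (j <= nrow(R)) {
        a0 <- R[i, 1:3]; a1 <- a0 + R[i, 4:6]
        b0 <- R[j, 1:3]; b1 <- b0 + R[j, 4:6]
        if (all(a0 < b1) && all(b0 < a1)) {
          lo <- pmin(a0, b0); hi <- pmax(a1, b1)
          R[i, ] <- c(lo, hi - lo)
          R <- R[-j, , drop = FALSE]
          merged <- TRUE
        } else j <- j + 1
      }
      i <- i + 1
    }
    if (!merged) break
  }
  R <- R[order(R[, 1], R[, 2], R[, 3]), , drop = FALSE]
  data.frame(x0 = R[, 1], y0 = R[, 2], z0 = R[, 3],
             sx = R[, 4], sy = R[, 5], sz = R[, 6])
}
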