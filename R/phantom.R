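#' Specification for a synthetic vascular phantom
#'
#' Describes an fMOST-like volume of tubular vessels: random branching trees
#' with radii between capillary (~2 um) and trunk (~20 um) scale, rendered
#' at anisotropic voxel size with 8-bit intensities, additive Gaussian
#' noise, and dark lumens inside vessels thicker than
#' `hollow_radius_threshold` (large labeled vessels carry dye only in the
#' wall, so their interior images dark).
#'
#' @param shape volume extent `(nx, ny, nz)` in voxels.
#' @param voxel_size physical voxel size, um.
#' @param n_trees number of vessel trees to grow.
#' @param radius_range `(r_min, r_max)` radii in um.
#' @param branch_prob per-step bifurcation probability.
#' @param tortuosity scale of the per-step direction perturbation.
#' @param n_steps growth-step budget per tree.
#' @param hollow_radius_threshold radius (um) above which the lumen renders
#'   dark.
#' @param lumen_fraction fraction of the radius left dark (0 <= f < 1).
#' @param foreground_intensity mean vessel level on the 8-bit scale.
#' @param background_level mean background level.
#' @param noise_sd additive Gaussian noise sigma.
#' @param seed RNG seed; all phantom output is deterministic given the seed.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 32),
                         voxel_size = c(1, 1, 2),
                         n_trees = 2,
                         radius_range = c(2, 20),
                         branch_prob = 0.02,
                         tortuosity = 0.1,
                         n_steps = 150,
                         hollow_radius_threshold = 8,
                         lumen_fraction = 0.5,
                         foreground_intensity = 120,
                         background_level = 10,
                         noise_sd = 5,
                         seed = 1) {
  stopifnot(length(shape) == 3, all(shape >= 1),
            radius_range[1] <= radius_range[2], radius_range[1] > 0,
            lumen_fraction >= 0, lumen_fraction < 1,
            branch_prob >= 0, branch_prob <= 1)
  structure(list(shape = as.integer(shape),
                 voxel_size = as_voxel_size(voxel_size),
                 n_trees = n_trees, radius_range = radius_range,
                 branch_prob = branch_prob, tortuosity = tortuosity,
                 n_steps = n_steps,
                 hollow_radius_threshold = hollow_radius_threshold,
                 lumen_fraction = lumen_fraction,
                 foreground_intensity = foreground_intensity,
                 background_level = background_level,
                 noise_sd = noise_sd, seed = seed),
            class = "phantom_spec")
}

with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

unit <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) stop("zero direction")
  v / n
}

#' Grow a random vascular skeleton
#'
#' Trees are grown by stepwise extension: each step advances the active tip
#' by one voxel along its direction, perturbs the direction by
#' `tortuosity`-scaled Gaussian noise, and bifurcates with probability
#' `branch_prob`; child radii never exceed the parent radius and stay
#' within `radius_range`.  Growth stops at the volume boundary (with a
#' radius-dependent margin so the rendered vessel stays inside) or when the
#' per-tree step budget is exhausted.  Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return a [skeleton()] with all nodes inside the volume.
#' @export
generate_skeleton <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shp <- spec$shape
  vs <- as.numeric(spec$voxel_size)
  rmin <- spec$radius_range[1]; rmax <- spec$radius_range[2]
  margin0 <- rmin / vs + 1
  if (any(shp - 1 - 2 * margin0 <= 0))
    stop("shape too small to place any tree")
  with_seed(spec$seed, {
    ids <- integer(0); xs <- ys <- zs <- rs <- numeric(0)
    parents <- integer(0)
    nid <- 0L
    add_node <- function(pos, r, parent) {
      nid <<- nid + 1L
      ids[nid] <<- nid; xs[nid] <<- pos[1]; ys[nid] <<- pos[2]
      zs[nid] <<- pos[3]; rs[nid] <<- r; parents[nid] <<- parent
      nid
    }
    inside <- function(pos, r) {
      m <- r / vs
      all(pos >= m) && all(pos <= shp - 1 - m)
    }
    for (tree in seq_len(spec$n_trees)) {
      r0 <- runif(1, rmin, rmax)
      m <- r0 / vs + 1
      lo <- m; hi <- shp - 1 - m
      if (any(hi <= lo)) { r0 <- rmin; m <- r0 / vs + 1; lo <- m; hi <- shp - 1 - m }
      root_pos <- lo + runif(3) * (hi - lo)
      root <- add_node(root_pos, r0, -1L)
      tips <- list(list(pos = root_pos, dir = unit(rnorm(3)), r = r0,
                        parent = root))
      budget <- spec$n_steps
      # round-robin stepping so every active tip (trunk and branches)
      # advances each sweep
      while (budget > 0 && length(tips) > 0) {
        i <- 1
        while (i <= length(tips) && budget > 0) {
          tip <- tips[[i]]
          budget <- budget - 1
          dir <- unit(tip$dir + spec$tortuosity * rnorm(3))
          pos <- tip$pos + dir
          if (!inside(pos, tip$r)) {
            tips[[i]] <- NULL
            next
          }
          node <- add_node(pos, tip$r, tip$parent)
          if (runif(1) < spec$branch_prob) {
            rc <- max(rmin, tip$r * runif(1, 0.6, 0.95))
            tips[[length(tips) + 1]] <-
              list(pos = pos, dir = unit(dir + rnorm(3)), r = rc,
                   parent = node)
          }
          tips[[i]] <- list(pos = pos, dir = dir, r = tip$r, parent = node)
          i <- i + 1
        }
      }
    }
    skeleton(data.frame(id = ids, type = 2L, x = xs, y = ys, z = zs,
                        radius = rs, parent = parents))
  })
}

#' Render a skeleton into an image and a binary mask
#'
#' A voxel is foreground in the mask iff its physical
#' (anisotropy-aware) distance to the skeleton polyline is at most the
#' locally interpolated radius.  In the image, vessels with radius above
#' `spec$hollow_radius_threshold` are rendered hollow: voxels closer than
#' `lumen_fraction * radius` to the centerline stay at background level
#' while the mask remains solid.  The image is
#' `background_level + foreground_intensity * wall + N(0, noise_sd)`,
#' clipped to \[0, 255\] and rounded to the 8-bit grid.
#'
#' @param skel a [skeleton()] lying inside `spec$shape`.
#' @param spec a [phantom_spec()].
#' @return list with `image` and `mask`, both [vb_volume()]s.
#' @export
render_volume <- function(skel, spec) {
  shp <- spec$shape
  vs <- as.numeric(spec$voxel_size)
  mask <- array(FALSE, dim = shp)
  dmin <- array(Inf, dim = shp)   # distance to the nearest polyline point
  rmin <- array(0, dim = shp)     # local radius at that nearest point
  nodes <- skel$nodes
  segs <- segment_table(skel)
  for (k in seq_len(nrow(segs))) {
    a <- c(segs$x1[k], segs$y1[k], segs$z1[k])
    b <- c(segs$x2[k], segs$y2[k], segs$z2[k])
    r1 <- segs$r1[k]; r2 <- segs$r2[k]
    rmax <- max(r1, r2)
    lo <- pmax(0, floor(pmin(a, b) - rmax / vs))
    hi <- pmin(shp - 1, ceiling(pmax(a, b) + rmax / vs))
    if (any(hi < lo)) next
    gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
    G <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    ab <- (b - a) * vs
    L2 <- sum(ab * ab)
    AP <- sweep(G, 2, a) %*% diag(vs)
    t <- if (L2 < 1e-12) rep(0, nrow(G)) else
      pmin(1, pmax(0, as.numeric(AP %*% ab) / L2))
    D <- AP - outer(t, ab)
    d <- sqrt(rowSums(D * D))
    rloc <- r1 + t * (r2 - r1)
    ins <- d <= rloc
    idx <- G[, 1] + shp[1] * (G[, 2] + shp[2] * G[, 3]) + 1
    if (any(ins)) mask[idx[ins]] <- TRUE
    closer <- d < dmin[idx]
    if (any(closer)) {
      dmin[idx[closer]] <- d[closer]
      rmin[idx[closer]] <- rloc[closer]
    }
  }
  # lumen carved against the whole polyline, not per segment, so end caps
  # of neighbouring segments cannot paint the interior as wall
  lumen <- mask & (rmin > spec$hollow_radius_threshold) &
    (dmin < spec$lumen_fraction * rmin)
  wall <- mask & !lumen
  img <- with_seed(spec$seed + 1L, {
    v <- spec$background_level + spec$foreground_intensity * wall
    if (spec$noise_sd > 0) v <- v + rnorm(length(v), 0, spec$noise_sd)
    array(pmin(255, pmax(0, round(v))), dim = shp)
  })
  list(image = vb_volume(img, spec$voxel_size),
       mask = vb_volume(array(as.numeric(mask), dim = shp), spec$voxel_size))
}

# parent-child segments (plus zero-length stubs for isolated roots)
segment_table <- function(skel) {
  nodes <- skel$nodes
  pidx <- match(nodes$parent, nodes$id)
  has_p <- !is.na(pidx)
  child_count <- tabulate(pidx[has_p], nbins = nrow(nodes))
  iso <- which(!has_p & child_count == 0)
  ci <- which(has_p)
  pi <- pidx[ci]
  data.frame(
    x1 = c(nodes$x[pi], nodes$x[iso]), y1 = c(nodes$y[pi], nodes$y[iso]),
    z1 = c(nodes$z[pi], nodes$z[iso]),
    x2 = c(nodes$x[ci], nodes$x[iso]), y2 = c(nodes$y[ci], nodes$y[iso]),
    z2 = c(nodes$z[ci], nodes$z[iso]),
    r1 = c(nodes$radius[pi], nodes$radius[iso]),
    r2 = c(nodes$radius[ci], nodes$radius[iso]))
}

chain_nodes <- function(from_id, xs, ys, zs, r, start_id, parent0) {
  n <- length(xs)
  data.frame(id = start_id + seq_len(n) - 1L, type = 2L,
             x = xs, y = ys, z = zs, radius = r,
             parent = c(parent0, start_id + seq_len(n - 1) - 1L))
}

#' Deterministic test fixtures
#'
#' Builds the five named phantoms used throughout the test-suite, each with
#' image, solid binary mask and exact ground-truth skeleton:
#'
#' * `straight_tube`: straight x-axis vessel, radius 3 um, noiseless.
#' * `y_junction`: symmetric Y, limb directions 90 degrees apart, radius 3 um.
#' * `hollow_trunk`: radius 10 um trunk rendered as an annulus
#'   (lumen radius 5 um), end caps inside the volume so the lumen is a
#'   closed cavity.
#' * `capillary_mesh`: thin (2 um) tube ladder containing one anastomosis
#'   encoded as a fusion link (one cycle).
#' * `weak_signal`: faint capillary, foreground mean ~10 on the 8-bit scale.
#'
#' @param outdir optional directory; when given, every fixture is written
#'   as `<name>_image.tif`, `<name>_mask.tif`, `<name>.swc` and
#'   `<name>.json` metadata.
#' @return named list of fixtures, each a list with `image`, `mask`,
#'   `skeleton` and `spec`.
#' @export
make_fixture_suite <- function(outdir = NULL) {
  fx <- list()

  # straight_tube -------------------------------------------------------
  sp <- phantom_spec(shape = c(48, 32, 16), noise_sd = 0, seed = 11,
                     radius_range = c(3, 3))
  nd <- chain_nodes(NULL, xs = 2:45, ys = rep(16, 44), zs = rep(8, 44),
                    r = 3, start_id = 1L, parent0 = -1L)
  sk <- skeleton(nd)
  fx$straight_tube <- c(render_volume(sk, sp), list(skeleton = sk, spec = sp))

  # y_junction ----------------------------------------------------------
  sp <- phantom_spec(shape = c(64, 64, 16), noise_sd = 0, seed = 12,
                     radius_range = c(3, 3))
  stem <- chain_nodes(NULL, xs = 4:28, ys = rep(32, 25), zs = rep(8, 25),
                      r = 3, start_id = 1L, parent0 = -1L)
  nlimb <- 16
  l1 <- chain_nodes(NULL, xs = 28 + seq_len(nlimb), ys = 32 + seq_len(nlimb),
                    zs = rep(8, nlimb), r = 3, start_id = 26L, parent0 = 25L)
  l2 <- chain_nodes(NULL, xs = 28 + seq_len(nlimb), ys = 32 - seq_len(nlimb),
                    zs = rep(8, nlimb), r = 3,
                    start_id = 26L + nlimb, parent0 = 25L)
  sk <- skeleton(rbind(stem, l1, l2))
  fx$y_junction <- c(render_volume(sk, sp), list(skeleton = sk, spec = sp))

  # hollow_trunk --------------------------------------------------------
  sp <- phantom_spec(shape = c(48, 40, 24), noise_sd = 0, seed = 13,
                     radius_range = c(10, 10), hollow_radius_threshold = 8,
                     lumen_fraction = 0.5)
  nd <- chain_nodes(NULL, xs = 6:41, ys = rep(20, 36), zs = rep(12, 36),
                    r = 10, start_id = 1L, parent0 = -1L)
  sk <- skeleton(nd)
  fx$hollow_trunk <- c(render_volume(sk, sp), list(skeleton = sk, spec = sp))

  # capillary_mesh ------------------------------------------------------
  sp <- phantom_spec(shape = c(48, 48, 16), noise_sd = 2, seed = 14,
                     radius_range = c(2, 2), foreground_intensity = 60)
  a <- chain_nodes(NULL, xs = 4:43, ys = rep(14, 40), zs = rep(8, 40),
                   r = 2, start_id = 1L, parent0 = -1L)          # tube A
  a_at <- function(x) a$id[a$x == x]
  rung1 <- chain_nodes(NULL, xs = rep(16, 15), ys = 15:29, zs = rep(8, 15),
                       r = 2, start_id = 41L, parent0 = a_at(16))
  bL <- chain_nodes(NULL, xs = 16:4, ys = rep(30, 13), zs = rep(8, 13),
                    r = 2, start_id = 56L, parent0 = 55L)        # B leftwards
  bR <- chain_nodes(NULL, xs = 17:43, ys = rep(30, 27), zs = rep(8, 27),
                    r = 2, start_id = 69L, parent0 = 56L)        # B rightwards
  rung2 <- chain_nodes(NULL, xs = rep(32, 15), ys = 15:29, zs = rep(8, 15),
                       r = 2, start_id = 96L, parent0 = a_at(32))
  b_at32 <- bR$id[bR$x == 32]
  sk <- skeleton(rbind(a, rung1, bL, bR, rung2),
                 fusion_links = matrix(c(110L, b_at32), ncol = 2))
  fx$capillary_mesh <- c(render_volume(sk, sp), list(skeleton = sk, spec = sp))

  # weak_signal ---------------------------------------------------------
  sp <- phantom_spec(shape = c(48, 32, 16), noise_sd = 2, seed = 15,
                     radius_range = c(2.5, 2.5), foreground_intensity = 8,
                     background_level = 2)
  nd <- chain_nodes(NULL, xs = 3:44, ys = rep(16, 42), zs = rep(8, 42),
                    r = 2.5, start_id = 1L, parent0 = -1L)
  sk <- skeleton(nd)
  fx$weak_signal <- c(render_volume(sk, sp), list(skeleton = sk, spec = sp))

  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    for (nm in names(fx)) {
      write_volume(fx[[nm]]$image, file.path(outdir, paste0(nm, "_image.tif")))
      write_volume(fx[[nm]]$mask, file.path(outdir, paste0(nm, "_mask.tif")))
      write_swc(fx[[nm]]$skeleton, file.path(outdir, paste0(nm, ".swc")))
      meta <- fx[[nm]]$spec
      meta$voxel_size <- as.numeric(meta$voxel_size)
      jsonlite::write_json(unclass(meta),
                           file.path(outdir, paste0(nm, ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  fx
}

#' Tile a volume into overlapping blocks
#'
#' Block start offsets are spaced evenly from 0 to `extent - b` on each
#' axis (rounded to integers), so blocks overlap whenever `k * b` exceeds
#' the extent and their union covers the volume whenever `k * b >= extent`.
#'
#' @param vol a [vb_volume()] or 3D array.
#' @param block block edge lengths `(bx, by, bz)` (scalar recycled).
#' @param n_blocks_per_axis blocks per axis `(kx, ky, kz)` (scalar recycled).
#' @return list of blocks, each a list with `data` (sub-array) and `offset`
#'   (0-based corner).
#' @export
tile_blocks <- function(vol, block, n_blocks_per_axis) {
  vol <- as_vb_volume(vol)
  d <- dim(vol$data)
  b <- rep(as.integer(block), length.out = 3)
  k <- rep(as.integer(n_blocks_per_axis), length.out = 3)
  if (any(b > d)) stop("block size exceeds volume extent")
  if (any(k < 1)) stop("need at least one block per axis")
  starts <- lapply(1:3, function(a) {
    if (k[a] == 1) 0L else as.integer(round(seq(0, d[a] - b[a],
                                                length.out = k[a])))
  })
  out <- list()
  for (sz in starts[[3]]) for (sy in starts[[2]]) for (sx in starts[[1]]) {
    out[[length(out) + 1]] <- list(
      data = vol$data[sx + seq_len(b[1]), sy + seq_len(b[2]),
                      sz + seq_len(b[3]), drop = FALSE],
      offset = c(sx, sy, sz))
  }
  out
}

#' Select representative blocks by gray-histogram clustering
#'
#' Each block is summarised by its normalised 256-bin gray histogram;
#' blocks are grouped by k-means and the selection is drawn across clusters
#' proportionally to cluster size (largest-remainder rounding), so that the
#' training subset reflects the intensity diversity of the tiling.
#' Deterministic given `seed`.
#'
#' @param blocks list of blocks as returned by [tile_blocks()] (or plain
#'   arrays) with values on the 0..255 scale.
#' @param k_clusters number of k-means clusters.
#' @param n_select number of blocks to select (`<= length(blocks)`).
#' @param seed RNG seed.
#' @return integer vector of selected block indices (sorted).
#' @export
select_training_blocks <- function(blocks, k_clusters, n_select, seed = 1) {
  if (length(blocks) == 0) stop("empty block list")
  stopifnot(n_select <= length(blocks), k_clusters <= length(blocks))
  feats <- t(vapply(blocks, function(b) {
    v <- if (is.list(b)) b$data else b
    v <- pmin(255, pmax(0, floor(as.numeric(v))))
    tabulate(v + 1, nbins = 256) / length(v)
  }, numeric(256)))
  if (n_select == length(blocks)) return(seq_along(blocks))
  with_seed(seed, {
    k_eff <- min(k_clusters, nrow(unique(feats)))
    cl <- if (k_eff == 1) rep(1L, nrow(feats)) else
      kmeans(feats, centers = k_eff, nstart = 5, iter.max = 100)$cluster
    sizes <- tabulate(cl, nbins = k_eff)
    quota <- floor(n_select * sizes / sum(sizes))
    rem <- n_select - sum(quota)
    frac <- n_select * sizes / sum(sizes) - quota
    if (rem > 0) {
      ord <- order(frac, decreasing = TRUE)
      quota[ord[seq_len(rem)]] <- quota[ord[seq_len(rem)]] + 1L
    }
    # cap at cluster size, push surplus round-robin to clusters with room
    repeat {
      over <- quota > sizes
      if (!any(over)) break
      surplus <- sum(quota[over] - sizes[over])
      quota[over] <- sizes[over]
      room <- which(quota < sizes)
      for (i in room) {
        if (surplus == 0) break
        add <- min(surplus, sizes[i] - quota[i])
        quota[i] <- quota[i] + add
        surplus <- surplus - add
      }
    }
    sel <- integer(0)
    for (i in seq_len(k_eff)) {
      members <- which(cl == i)
      if (quota[i] > 0)
        sel <- c(sel, members[sample.int(length(members), quota[i])])
    }
    sort(sel)
  })
}
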