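test_that("degenerate growth parameters give a straight constant-radius polyline", {
  sp <- phantom_spec(shape = c(64, 64, 32), n_trees = 1, branch_prob = 0,
                     tortuosity = 0, n_steps = 40, radius_range = c(3, 3),
                     seed = 5)
  sk <- generate_skeleton(sp)
  expect_equal(length(unique(sk$nodes$radius)), 1)
  expect_equal(nrow(extract_branch_points(sk)), 0)
  # collinear: all steps equal the first step vector
  P <- as.matrix(sk$nodes[, c("x", "y", "z")])
  steps <- diff(P)
  expect_lt(max(abs(sweep(steps, 2, steps[1, ]))), 1e-9)
})

test_that("skeleton generation is deterministic given the seed", {
  sp <- phantom_spec(seed = 42, n_steps = 80, branch_prob = 0.05)
  expect_identical(generate_skeleton(sp), generate_skeleton(sp))
  rv1 <- render_volume(generate_skeleton(sp), sp)
  rv2 <- render_volume(generate_skeleton(sp), sp)
  expect_identical(rv1$image$data, rv2$image$data)
})

test_that("bifurcation count follows the per-step branching probability", {
  # one tree, 2000 steps, p = 0.05 -> Binomial(2000, 0.05):
  # mean 100, sd ~9.75; the across-seed mean must fall within 3 sd
  # the volume is made large and the walk diffusive so boundary exits are
  # rare and nearly all 2000 step budgets are spent
  counts <- vapply(1:50, function(seed) {
    sp <- phantom_spec(shape = c(2048, 2048, 1024), n_trees = 1,
                       branch_prob = 0.05, tortuosity = 0.8, n_steps = 2000,
                       radius_range = c(2, 2), seed = seed)
    sk <- generate_skeleton(sp)
    nrow(extract_branch_points(sk))
  }, numeric(1))
  mu <- 2000 * 0.05
  sdv <- sqrt(2000 * 0.05 * 0.95)
  expect_gt(mean(counts), mu - 3 * sdv)
  expect_lt(mean(counts), mu + 3 * sdv)
})

test_that("rendering obeys the physical distance rule", {
  # single node, radius 3 um, anisotropic voxels
  sp <- phantom_spec(shape = c(21, 21, 11), noise_sd = 0,
                     radius_range = c(3, 3), seed = 1)
  nd <- data.frame(id = 1L, type = 2L, x = 10, y = 10, z = 5, radius = 3,
                   parent = -1L)
  rv <- render_volume(skeleton(nd), sp)
  m <- rv$mask$data
  expect_equal(m[14, 11, 6], 1)  # (13,10,5): 3 um away in x -> inside
  expect_equal(m[15, 11, 6], 0)  # 4 um away -> outside
  expect_equal(m[11, 11, 7], 1)  # 1 z-voxel = 2 um -> inside
  expect_equal(m[11, 11, 8], 0)  # 2 z-voxels = 4 um -> outside

  # annulus: tube radius 4, hollow above 3, lumen fraction 0.5
  sp <- phantom_spec(shape = c(32, 16, 16), noise_sd = 0,
                     radius_range = c(4, 4), hollow_radius_threshold = 3,
                     lumen_fraction = 0.5, seed = 1)
  nd <- chain_skeleton(20, y = 8, z = 8, r = 4, x0 = 6)
  rv <- render_volume(nd, sp)
  img <- rv$image$data
  expect_equal(img[17, 9, 9], sp$background_level)       # centerline dark
  expect_equal(img[17, 12, 9],
               sp$background_level + sp$foreground_intensity)  # wall at 3 um
  expect_equal(rv$mask$data[17, 9, 9], 1)                 # mask stays solid
})

test_that("background noise statistics match the model", {
  sp <- phantom_spec(shape = c(40, 40, 40), noise_sd = 5,
                     background_level = 10, n_trees = 1, n_steps = 5,
                     radius_range = c(2, 2), seed = 3)
  nd <- data.frame(id = 1L, type = 2L, x = 35, y = 35, z = 35, radius = 2,
                   parent = -1L)
  rv <- render_volume(skeleton(nd), sp)
  corner <- rv$image$data[1:20, 1:20, 1:20]
  expect_lt(abs(mean(corner) - 10), 0.5)
})

test_that("fixture suite provides the five standard phantoms with ground truth", {
  fx <- fixture_suite()
  expect_named(fx, c("straight_tube", "y_junction", "hollow_trunk",
                     "capillary_mesh", "weak_signal"))
  # y_junction ground truth: 1 branch node, 3 endpoints
  g <- build_graph(fx$y_junction$skeleton)
  expect_equal(sum(g$nodes$degree >= 3), 1)
  expect_equal(sum(g$nodes$degree == 1), 3)
  # hollow trunk: centerline voxels darker than wall by >= half foreground
  ht <- fx$hollow_trunk
  ctr <- ht$image$data[25, 21, 13]
  wall <- ht$image$data[25, 29, 13]
  expect_gte(wall - ctr, 0.5 * ht$spec$foreground_intensity)
  # every ground-truth skeleton point lies inside the rendered mask
  for (nm in names(fx)) {
    nodes <- fx[[nm]]$skeleton$nodes
    idx <- cbind(round(nodes$x) + 1, round(nodes$y) + 1, round(nodes$z) + 1)
    expect_true(all(fx[[nm]]$mask$data[idx] == 1), label = nm)
  }
  # fixtures write to disk as TIFF + SWC + JSON
  td <- withr::local_tempdir()
  make_fixture_suite(td)
  expect_true(file.exists(file.path(td, "straight_tube_image.tif")))
  expect_true(file.exists(file.path(td, "capillary_mesh.swc")))
  expect_true(file.exists(file.path(td, "weak_signal.json")))
})

test_that("block tiling spaces starts evenly and covers the volume", {
  vol <- vb_volume(array(0, dim = c(512, 512, 512) / 8))  # 64^3 stand-in
  # the canonical geometry at full scale, checked arithmetically
  ext <- 512; b <- 196; k <- 2
  starts <- round(seq(0, ext - b, length.out = k))
  expect_equal(starts, c(0, 316))

  blocks <- tile_blocks(vol, 40, c(2, 2, 2))
  expect_equal(length(blocks), 8)
  offs <- t(vapply(blocks, `[[`, numeric(3), "offset"))
  expect_equal(sort(unique(offs[, 1])), c(0, 24))

  # identity tiling
  one <- tile_blocks(vol, 64, 1)
  expect_equal(length(one), 1)
  expect_equal(one[[1]]$offset, c(0, 0, 0))
  expect_identical(one[[1]]$data, vol$data)

  # exhaustive coverage check on a small volume
  small <- vb_volume(array(0, dim = c(32, 32, 32)))
  for (kk in list(c(3, 3, 3), c(3, 4, 5))) {   # k*b >= extent so cover holds
    bl <- tile_blocks(small, 13, kk)
    cov <- array(FALSE, dim = dim(small$data))
    for (b in bl) {
      o <- b$offset
      cov[o[1] + 1:13, o[2] + 1:13, o[3] + 1:13] <- TRUE
    }
    expect_true(all(cov))
  }
  expect_error(tile_blocks(small, 64, 2), "exceeds")
})

test_that("training-block selection is proportional, deterministic and separates populations", {
  set.seed(99)
  mk <- function(mean) array(pmax(0, pmin(255, round(rnorm(512, mean, 3)))),
                             dim = c(8, 8, 8))
  identical10 <- replicate(10, array(7, dim = c(8, 8, 8)), simplify = FALSE)
  s1 <- select_training_blocks(identical10, k_clusters = 1, n_select = 3,
                               seed = 4)
  expect_length(s1, 3)
  expect_identical(s1, select_training_blocks(identical10, 1, 3, seed = 4))

  dark <- lapply(1:4, function(i) mk(20))
  bright <- lapply(1:4, function(i) mk(200))
  sel <- select_training_blocks(c(dark, bright), k_clusters = 2,
                                n_select = 2, seed = 7)
  expect_length(sel, 2)
  expect_true(any(sel <= 4) && any(sel > 4))  # one from each population

  all8 <- select_training_blocks(c(dark, bright), 2, 8, seed = 1)
  expect_equal(all8, 1:8)
})
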