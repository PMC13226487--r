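test_that("camera projection and back-projection are consistent", {
  cam <- vb_camera(viewpoint = c(5, 5, 0), forward = c(0, 0, 1))
  r <- ray_from_view(cam, c(0, 0))
  expect_equal(r$origin, c(5, 5, 0))
  expect_equal(r$direction, c(0, 0, 1))

  # a projected point lies on its own back-projected ray (both models)
  set.seed(2)
  for (model in c("orthographic", "perspective")) {
    cam <- vb_camera(viewpoint = c(10, -4, 3),
                     forward = c(0.3, 0.5, 0.8), up = c(0, 1, 0),
                     model = model, focal = 2)
    for (i in 1:20) {
      p <- runif(3, 5, 40) * cam$forward + cam$viewpoint + rnorm(3)
      px <- camera_project(cam, p)
      ray <- ray_from_view(cam, px)
      v <- p - ray$origin
      dist <- sqrt(sum((v - sum(v * ray$direction) * ray$direction)^2))
      expect_lt(dist, 1e-6)
    }
  }

  # distinct pixels give non-parallel rays from the same perspective origin
  cam <- vb_camera(model = "perspective")
  r1 <- ray_from_view(cam, c(0, 0)); r2 <- ray_from_view(cam, c(1, 0))
  expect_equal(r1$origin, r2$origin)
  expect_gt(sum(abs(r1$direction - r2$direction)), 0)
  expect_error(vb_camera(forward = c(0, 0, 1), up = c(0, 0, 2)), "singular")
})

test_that("ray closest point handles intersecting, clamped and parallel cases", {
  # intersecting axes
  xi <- closest_point_between_rays(vb_ray(c(0, 0, 0), c(1, 0, 0)),
                                   vb_ray(c(0, 0, 0), c(0, 1, 0)))
  expect_equal(xi$Pc, c(0, 0, 0))
  expect_equal(xi$gap, 0)

  # clamped half-line case: optimum pinned at both origins
  xi <- closest_point_between_rays(vb_ray(c(0, 0, 0), c(1, 0, 0)),
                                   vb_ray(c(0, 1, 1), c(0, 0, 1)))
  expect_equal(xi$P1, c(0, 0, 0))
  expect_equal(xi$P2, c(0, 1, 1))
  expect_equal(xi$Pc, c(0, 0.5, 0.5))
  expect_equal(xi$gap, sqrt(2))

  # identical rays are flagged parallel with zero gap
  xi <- closest_point_between_rays(vb_ray(c(1, 2, 3), c(0, 0, 1)),
                                   vb_ray(c(1, 2, 3), c(0, 0, 1)))
  expect_true(xi$parallel)
  expect_equal(xi$gap, 0)

  expect_error(vb_ray(c(0, 0, 0), c(0, 0, 0)), "zero direction")
})

test_that("closest point agrees with grid-search minimisation on random ray pairs", {
  set.seed(11)
  grid_gap <- function(r1, r2, tmax = 8) {
    # coarse-to-fine search over (t, u) in [0, tmax]^2 down to 1e-3 steps
    best <- c(0, 0); width <- tmax / 2; ctr <- c(tmax, tmax) / 2
    gap <- function(t, u) {
      P1 <- r1$origin + t * r1$direction
      P2 <- r2$origin + u * r2$direction
      sqrt(sum((P1 - P2)^2))
    }
    step <- tmax / 80
    repeat {
      ts <- pmax(0, seq(ctr[1] - width, ctr[1] + width, by = step))
      us <- pmax(0, seq(ctr[2] - width, ctr[2] + width, by = step))
      g <- outer(ts, us, Vectorize(gap))
      k <- arrayInd(which.min(g), dim(g))
      ctr <- c(ts[k[1]], us[k[2]])
      if (step <= 1e-3) return(min(g))
      width <- 2 * step
      step <- step / 10
    }
  }
  for (i in 1:100) {
    r1 <- vb_ray(runif(3, 0, 4), rnorm(3))
    r2 <- vb_ray(runif(3, 0, 4), rnorm(3))
    xi <- closest_point_between_rays(r1, r2)
    if (xi$t1 > 7 || xi$t2 > 7) next  # outside the searched box
    expect_lt(abs(xi$gap - grid_gap(r1, r2)), 1e-3)
  }
})

test_that("rays through a common point localise it to numerical precision", {
  set.seed(5)
  for (i in 1:25) {
    p <- runif(3, 10, 30)
    o1 <- p - runif(1, 5, 15) * (d1 <- unit_vec(rnorm(3)))
    o2 <- p - runif(1, 5, 15) * (d2 <- unit_vec(rnorm(3)))
    xi <- closest_point_between_rays(vb_ray(o1, d1), vb_ray(o2, d2))
    expect_lt(sqrt(sum((xi$Pc - p)^2)), 1e-6)
  }
})

test_that("profile sampling interpolates trilinearly with OOB flags", {
  const <- vb_volume(array(7, dim = c(10, 10, 10)), c(1, 1, 2))
  pr <- sample_profile(const, c(5, 5, 5), c(0, 1, 0), 4)
  expect_equal(pr$values, rep(7, 9))
  expect_false(any(pr$oob))

  # linear ramp along x increases by the slope per unit step
  ramp <- vb_volume(array(rep(0:9, 100), dim = c(10, 10, 10)), c(1, 1, 2))
  pr <- sample_profile(ramp, c(4.5, 5, 5), c(1, 0, 0), 3)
  expect_equal(diff(pr$values), rep(1, 6))

  # anchor near a face: OOB on one side only
  pr <- sample_profile(const, c(1, 5, 5), c(1, 0, 0), 4)
  expect_true(any(pr$oob[1:4]))
  expect_false(any(pr$oob[5:9]))
  expect_error(sample_profile(const, c(5, 5, 5), c(1, 0, 0), 0), "half_extent")
})

test_that("FWHM interval selection is exact on pulses and Gaussian bumps", {
  mkprof <- function(vals) structure(
    list(offsets = seq_along(vals) - (length(vals) + 1) / 2, values = vals,
         oob = rep(FALSE, length(vals)), anchor = c(0, 0, 0),
         direction = c(1, 0, 0)), class = "intensity_profile")
  # rectangular pulse of width 6
  p <- mkprof(c(0, 0, 0, 1, 1, 1, 1, 1, 1, 0, 0))
  expect_equal(select_interval_fwhm(p)$L, 6)
  # Gaussian bump sigma = 2 steps: FWHM ~ 4.7 -> 5 samples above half max
  x <- -10:10
  p <- mkprof(exp(-x^2 / (2 * 2^2)))
  L <- select_interval_fwhm(p)$L
  expect_gte(L, 4); expect_lte(L, 6)
  # two separated pulses: only the taller peak's run is selected
  p <- mkprof(c(0, 5, 5, 0, 0, 0, 9, 9, 9, 0, 0))
  iv <- select_interval_fwhm(p)
  expect_equal(iv$L, 3)
  expect_error(select_interval_fwhm(mkprof(rep(2, 9))), "flat")
})

test_that("the radius formula evaluates exactly on hand cases", {
  mkiv <- function(L, d) structure(list(L = L, direction = d),
                                   class = "profile_interval")
  s <- voxel_size(1, 1, 2)
  expect_equal(estimate_radius(mkiv(0, c(1, 0, 0)), mkiv(0, c(0, 1, 0)), s), 0)
  expect_equal(estimate_radius(mkiv(4, c(1, 0, 0)), mkiv(4, c(0, 1, 0)), s), 2)
  expect_equal(estimate_radius(mkiv(3, c(0, 0, 1)), mkiv(6, c(1, 0, 0)), s), 3)
})

test_that("dual-ray FWHM pipeline recovers the straight-tube radius", {
  st <- fixture_suite()$straight_tube
  ctr <- c(24, 16, 8)
  r1 <- vb_ray(ctr - c(0, 12, 0), c(0, 1, 0))
  r2 <- vb_ray(ctr - c(0, 0, 6), c(0, 0, 1))
  xi <- closest_point_between_rays(r1, r2)
  expect_equal(xi$Pc, ctr)
  i1 <- select_interval_fwhm(sample_profile(st$image, xi$P1, r1$direction, 10))
  i2 <- select_interval_fwhm(sample_profile(st$image, xi$P2, r2$direction, 7))
  r <- estimate_radius(i1, i2, st$image$voxel_size)
  expect_lt(abs(r - 3), max(0.5, 0.15 * 3))
})
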