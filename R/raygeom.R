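#' Viewing ray
#'
#' A half-line in voxel-index space, used by the dual-view radius
#' annotation geometry: the user clicks the same vessel in two different
#' projections and each click back-projects to a ray.
#'
#' @param origin numeric length-3 origin (0-based voxel coords).
#' @param direction direction vector; normalised to unit length.
#' @return list of class `vb_ray`.
#' @export
vb_ray <- function(origin, direction) {
  stopifnot(length(origin) == 3, length(direction) == 3)
  structure(list(origin = as.numeric(origin),
                 direction = unit(as.numeric(direction))),
            class = "vb_ray")
}

#' Camera model for projection and back-projection
#'
#' An orthographic (default) or perspective camera defined by a viewpoint
#' and an orthonormal basis (`forward` towards the scene, `up`, and
#' `right = forward x up`).  Screen coordinates `(u, v)` are measured along
#' `right` and `up`.
#'
#' @param viewpoint camera position (voxel coords).
#' @param forward viewing direction.
#' @param up up vector (orthogonalised against `forward`).
#' @param model `"orthographic"` or `"perspective"`.
#' @param focal focal length for the perspective model.
#' @return list of class `vb_camera`.
#' @export
vb_camera <- function(viewpoint = c(0, 0, 0), forward = c(0, 0, 1),
                      up = c(0, 1, 0), model = c("orthographic", "perspective"),
                      focal = 1) {
  model <- match.arg(model)
  f <- unit(as.numeric(forward))
  u <- as.numeric(up)
  u <- u - sum(u * f) * f
  if (sqrt(sum(u * u)) < 1e-9) stop("singular camera: up parallel to forward")
  u <- unit(u)
  r <- c(f[2] * u[3] - f[3] * u[2],
         f[3] * u[1] - f[1] * u[3],
         f[1] * u[2] - f[2] * u[1])
  structure(list(viewpoint = as.numeric(viewpoint), forward = f, up = u,
                 right = r, model = model, focal = focal),
            class = "vb_camera")
}

#' Project a 3D point to screen coordinates
#'
#' @param camera a [vb_camera()].
#' @param point 3D point (voxel coords).
#' @return numeric `(u, v)` screen coordinates.
#' @export
camera_project <- function(camera, point) {
  rel <- as.numeric(point) - camera$viewpoint
  if (camera$model == "orthographic") {
    c(u = sum(rel * camera$right), v = sum(rel * camera$up))
  } else {
    d <- sum(rel * camera$forward)
    if (abs(d) < 1e-12) stop("point in the camera plane")
    c(u = camera$focal * sum(rel * camera$right) / d,
      v = camera$focal * sum(rel * camera$up) / d)
  }
}

#' Back-project a screen pixel to a viewing ray
#'
#' For an orthographic camera the ray starts at the pixel's offset in the
#' viewing plane and runs along `forward`; for a perspective camera all
#' rays start at the viewpoint.  A projected point always lies on its own
#' back-projected ray.
#'
#' @param camera a [vb_camera()].
#' @param pixel screen coordinates `(u, v)`.
#' @return a [vb_ray()].
#' @export
ray_from_view <- function(camera, pixel) {
  stopifnot(inherits(camera, "vb_camera"), length(pixel) == 2)
  u <- as.numeric(pixel[1]); v <- as.numeric(pixel[2])
  if (camera$model == "orthographic") {
    vb_ray(camera$viewpoint + u * camera$right + v * camera$up,
           camera$forward)
  } else {
    vb_ray(camera$viewpoint,
           camera$forward + (u / camera$focal) * camera$right +
             (v / camera$focal) * camera$up)
  }
}

#' Closest point between two viewing rays
#'
#' Finds the points `P1`, `P2` minimising the distance between the two
#' half-lines (parameters clamped to `t >= 0`, since rays emanate from a
#' viewpoint), the midpoint `Pc = (P1 + P2) / 2` of the common
#' perpendicular, and the residual `gap = |P1 - P2|`.  `Pc` is the 3D
#' vessel-centre estimate of the dual-view click geometry.  Parallel rays
#' are flagged.
#'
#' @param r1,r2 [vb_ray()]s.
#' @return list of class `ray_intersection` with `Pc`, `P1`, `P2`, `gap`,
#'   `t1`, `t2` and `parallel`.
#' @export
closest_point_between_rays <- function(r1, r2) {
  stopifnot(inherits(r1, "vb_ray"), inherits(r2, "vb_ray"))
  d1 <- r1$direction; d2 <- r2$direction
  o1 <- r1$origin; o2 <- r2$origin
  b <- sum(d1 * d2)
  w0 <- o1 - o2
  denom <- 1 - b * b
  parallel <- denom < 1e-12
  eval_pair <- function(t, u) {
    P1 <- o1 + t * d1; P2 <- o2 + u * d2
    list(t = t, u = u, P1 = P1, P2 = P2,
         gap = sqrt(sum((P1 - P2)^2)))
  }
  if (parallel) {
    t <- 0
    u <- max(0, sum((o1 - o2) * d2))
    best <- eval_pair(t, u)
  } else {
    e1 <- -sum(w0 * d1); e2 <- sum(w0 * d2)
    t <- (e1 + b * e2) / denom
    u <- (e2 + b * e1) / denom
    if (t >= 0 && u >= 0) {
      best <- eval_pair(t, u)
    } else {
      cand1 <- eval_pair(0, max(0, sum((o1 - o2) * d2)))
      u0 <- 0
      cand2 <- eval_pair(max(0, sum((o2 - o1) * d1)), u0)
      best <- if (cand1$gap <= cand2$gap) cand1 else cand2
    }
  }
  structure(list(Pc = (best$P1 + best$P2) / 2, P1 = best$P1, P2 = best$P2,
                 gap = best$gap, t1 = best$t, t2 = best$u,
                 parallel = parallel),
            class = "ray_intersection")
}

#' Sample an intensity profile along a ray
#'
#' Trilinearly interpolates the volume at unit-voxel steps along the ray
#' direction and its opposite, centred on `anchor`.  Out-of-bounds samples
#' are set to 0 and flagged.
#'
#' @param vol a [vb_volume()].
#' @param anchor 3D anchor point on the ray (voxel coords).
#' @param direction ray direction (normalised internally).
#' @param half_extent number of unit steps on each side (>= 1).
#' @return list of class `intensity_profile` with `offsets`, `values`,
#'   `oob`, `anchor`, `direction`.
#' @export
sample_profile <- function(vol, anchor, direction, half_extent = 20) {
  stopifnot(inherits(vol, "vb_volume"))
  if (half_extent < 1) stop("half_extent must be >= 1")
  d <- unit(as.numeric(direction))
  offs <- seq(-half_extent, half_extent)
  pts <- outer(offs, d) + matrix(as.numeric(anchor), length(offs), 3,
                                 byrow = TRUE)
  tri <- trilinear(vol, pts)
  structure(list(offsets = offs, values = tri$values, oob = tri$oob,
                 anchor = as.numeric(anchor), direction = d),
            class = "intensity_profile")
}

#' Select the vessel interval on a profile (FWHM rule)
#'
#' Deterministic stand-in for the interactive interval selection: the
#' interval is the maximal contiguous run of samples around the profile
#' peak whose value reaches half way between the profile minimum and
#' maximum.  The interval length L is the number of unit-spaced samples in
#' the run.
#'
#' @param profile a [sample_profile()] result.
#' @return list of class `profile_interval` with `L`, `direction`,
#'   `anchor`, `from`, `to` (offset bounds of the run).
#' @export
select_interval_fwhm <- function(profile) {
  stopifnot(inherits(profile, "intensity_profile"))
  v <- profile$values
  if (max(v) - min(v) < 1e-9) stop("flat profile: no vessel signal")
  level <- (max(v) + min(v)) / 2
  peak <- which.max(v)
  lo <- peak
  while (lo > 1 && v[lo - 1] >= level) lo <- lo - 1
  hi <- peak
  while (hi < length(v) && v[hi + 1] >= level) hi <- hi + 1
  structure(list(L = hi - lo + 1, direction = profile$direction,
                 anchor = profile$anchor,
                 from = profile$offsets[lo], to = profile$offsets[hi]),
            class = "profile_interval")
}

#' Dual-view vessel radius estimate
#'
#' Combines the interval lengths measured on the two rays into a radius:
#' `r = 0.25 * (L1 * |d1 . s| + L2 * |d2 . s|)` where `|d . s|` is the
#' Euclidean norm of the component-wise product of the unit ray direction
#' with the voxel size — each `L * |d . s|` is a measured diameter in um,
#' and the estimate is the mean radius of the two views.
#'
#' @param i1,i2 [select_interval_fwhm()] results (or lists with `L` and
#'   `direction`).
#' @param s a [voxel_size()].
#' @return radius in um.
#' @export
estimate_radius <- function(i1, i2, s = voxel_size()) {
  s <- as.numeric(as_voxel_size(s))
  stopifnot(i1$L >= 0, i2$L >= 0)
  step1 <- sqrt(sum((unit(i1$direction) * s)^2))
  step2 <- sqrt(sum((unit(i2$direction) * s)^2))
  0.25 * (i1$L * step1 + i2$L * step2)
}
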