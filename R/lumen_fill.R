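#' Fill hollow lumens in a vessel segmentation
#'
#' Segmentation networks often leave the interior of thick vessels dark
#' (dye lines only the wall), producing annular masks that break
#' downstream centerline tracing.  This pipeline fills such lumens:
#'
#' 1. nearest-neighbour downsample to half size per axis;
#' 2. min-max normalise to \[0, 1\];
#' 3. Gaussian smoothing (sigma `gaussian_sd`, 3 x 3 x 3 kernel);
#' 4. Otsu binarisation (256-bin histogram);
#' 5. morphological closing with a ball of `closing_radius` voxels,
#'    followed by a connected-background hole fill (background components
#'    not reaching the volume border become foreground) — closing alone
#'    cannot seal a long axial lumen at small radius;
#' 6. upsample back to the original grid (nearest-neighbour, which keeps
#'    the mask binary; set `upsample = "trilinear"` for interpolation with
#'    a 0.5 threshold);
#' 7. voxelwise OR with the binarised input, so the output foreground is
#'    always a superset of the input foreground.
#'
#' A constant-intensity input (Otsu undefined) is returned unchanged with
#' a warning.
#'
#' @param seg a [vb_volume()] or array: binary mask or probability map
#'   (probabilities are binarised at 0.5 for the final OR).
#' @param gaussian_sd Gaussian sigma of the smoothing step.
#' @param closing_radius ball radius (voxels) of the closing step.
#' @param upsample `"nearest"` or `"trilinear"`.
#' @return a binary [vb_volume()] (values 0/1).
#' @export
fill_hollow <- function(seg, gaussian_sd = 2.0, closing_radius = 2,
                        upsample = c("nearest", "trilinear")) {
  upsample <- match.arg(upsample)
  vol <- as_vb_volume(seg)
  arr <- vol$data
  if (length(arr) == 0) stop("empty volume")
  bin0 <- arr > 0.5
  if (max(arr) == min(arr)) {
    warning("constant-intensity volume: Otsu undefined, input returned unchanged")
    return(vb_volume(array(as.numeric(bin0), dim = dim(arr)),
                     vol$voxel_size))
  }
  d <- dim(arr)
  # (1) nearest-neighbour downsample x0.5
  ix <- seq(1, d[1], by = 2); iy <- seq(1, d[2], by = 2)
  iz <- seq(1, d[3], by = 2)
  small <- arr[ix, iy, iz, drop = FALSE]
  # (2) min-max normalise
  rng <- range(small)
  small <- if (rng[2] > rng[1]) (small - rng[1]) / (rng[2] - rng[1])
           else array(0, dim = dim(small))
  # (3) Gaussian smoothing, separable 3-tap kernel (3x3x3 support)
  small <- gauss3(small, gaussian_sd)
  # (4) Otsu
  thr <- otsu_threshold(small)
  binv <- small > thr
  # (5) closing + hole fill
  closed <- erode_ball(dilate_ball(binv, closing_radius), closing_radius)
  closed <- fill_holes(closed)
  # (6) upsample to original shape
  up <- upsample_mask(closed, d, method = upsample)
  # (7) OR merge
  out <- up | bin0
  vb_volume(array(as.numeric(out), dim = d), vol$voxel_size)
}

# separable convolution with the 3-tap Gaussian [g1, g0, g1], edge-replicated
gauss3 <- function(arr, sd) {
  k <- exp(-c(1, 0, 1) / (2 * sd^2))
  k <- k / sum(k)
  d <- dim(arr)
  clamp <- function(i, n) pmin(pmax(i, 1), n)
  out <- k[1] * arr[clamp(0:(d[1] - 1), d[1]), , , drop = FALSE] +
         k[2] * arr +
         k[3] * arr[clamp(2:(d[1] + 1), d[1]), , , drop = FALSE]
  out <- k[1] * out[, clamp(0:(d[2] - 1), d[2]), , drop = FALSE] +
         k[2] * out +
         k[3] * out[, clamp(2:(d[2] + 1), d[2]), , drop = FALSE]
  out <- k[1] * out[, , clamp(0:(d[3] - 1), d[3]), drop = FALSE] +
         k[2] * out +
         k[3] * out[, , clamp(2:(d[3] + 1), d[3]), drop = FALSE]
  out
}

# Otsu threshold on a 256-bin histogram of values in [0, 1]
otsu_threshold <- function(values, nbins = 256) {
  v <- as.numeric(values)
  bins <- pmin(nbins - 1, floor(v * nbins))
  h <- tabulate(bins + 1, nbins = nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(nbins) - 1))
  mu_t <- mu[nbins]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- -Inf
  k <- which.max(sb2)              # threshold between bin k-1 and k
  k / nbins
}

# background 6-components not touching the border become foreground
fill_holes <- function(mask) {
  lab <- label_components(!mask, connectivity = 6)
  d <- dim(lab)
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                     lab[, , c(1, d[3])]))
  border <- border[border > 0]
  mask | (lab > 0 & !(lab %in% border))
}

upsample_mask <- function(mask, target_dim, method = "nearest") {
  ds <- dim(mask)
  if (method == "nearest") {
    rx <- pmin(ds[1], ceiling(seq_len(target_dim[1]) / 2))
    ry <- pmin(ds[2], ceiling(seq_len(target_dim[2]) / 2))
    rz <- pmin(ds[3], ceiling(seq_len(target_dim[3]) / 2))
    mask[rx, ry, rz, drop = FALSE]
  } else {
    vol <- vb_volume(array(as.numeric(mask), dim = ds), c(1, 1, 1))
    # original voxel (x) maps to downsampled coordinate x/2
    pts <- as.matrix(expand.grid(x = (seq_len(target_dim[1]) - 1) / 2,
                                 y = (seq_len(target_dim[2]) - 1) / 2,
                                 z = (seq_len(target_dim[3]) - 1) / 2))
    vals <- trilinear(vol, pts)$values
    array(vals >= 0.5, dim = target_dim)
  }
}
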