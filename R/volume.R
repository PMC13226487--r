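#' Voxel size in micrometres
#'
#' Physical edge lengths of a voxel along x, y and z.  The canonical
#' acquisition geometry for the data this package emulates is anisotropic:
#' 1 um in x and y, 2 um in z.
#'
#' @param sx,sy,sz strictly positive edge lengths in micrometres.
#' @return a numeric vector of class `voxel_size` with elements sx, sy, sz.
#' @export
voxel_size <- function(sx = 1, sy = 1, sz = 2) {
  v <- c(sx = as.numeric(sx), sy = as.numeric(sy), sz = as.numeric(sz))
  if (any(!is.finite(v)) || any(v <= 0))
    stop("voxel sizes must be strictly positive and finite")
  structure(v, class = "voxel_size")
}

as_voxel_size <- function(x) {
  if (inherits(x, "voxel_size")) return(x)
  x <- as.numeric(x)
  if (length(x) == 1) x <- rep(x, 3)
  if (length(x) != 3) stop("voxel size must have 3 components")
  voxel_size(x[1], x[2], x[3])
}

#' 3D image volume with voxel-size metadata
#'
#' A thin container for a 3D scalar grid.  Data are stored in an R array of
#' dimension `(nx, ny, nz)`; the voxel with 0-based spatial coordinates
#' `(x, y, z)` lives at `data[x + 1, y + 1, z + 1]`.  All continuous
#' coordinates used in this package (skeletons, rays, centerlines) are
#' 0-based voxel indices, so integer coordinates land exactly on voxel
#' centres.
#'
#' @param data a numeric, integer or logical 3D array.
#' @param voxel_size a [voxel_size()] (or length-3 numeric), um per voxel.
#' @return an object of class `vb_volume`: list with `data` and `voxel_size`.
#' @export
vb_volume <- function(data, voxel_size = c(1, 1, 2)) {
  if (length(dim(data)) != 3)
    stop("volume data must have rank exactly 3")
  structure(list(data = data, voxel_size = as_voxel_size(voxel_size)),
            class = "vb_volume")
}

#' @export
print.vb_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vb_volume %d x %d x %d (x,y,z), voxel %g x %g x %g um, range [%g, %g]>\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.vb_volume <- function(x) dim(x$data)

as_vb_volume <- function(x, voxel_size = c(1, 1, 2)) {
  if (inherits(x, "vb_volume")) x else vb_volume(x, voxel_size)
}

#' Read a 3D volume from TIFF or NRRD
#'
#' Multi-page TIFF stacks (page = z-slice, rows = y, columns = x) and raw
#' little-endian NRRD are supported; the format is chosen by file
#' extension.  NRRD `space directions`/`spacings` carry the voxel size; TIFF
#' has no standard voxel-size tag, so `voxel_size` (or the 1 x 1 x 2 um
#' default, with a warning) is used.
#'
#' 8-bit files are returned on the 0..255 integer scale; float files as
#' stored (probability maps are expected in \[0, 1\]).
#'
#' @param path file path ending in `.tif`, `.tiff` or `.nrrd`.
#' @param voxel_size optional voxel size override for TIFF input.
#' @return a [vb_volume()].
#' @export
read_volume <- function(path, voxel_size = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(dim(pages[[1]])) != 2)
      stop("expected single-channel pages (rank-3 volume)")
    bits <- attr(pages[[1]], "bits.per.sample")
    # 8-bit integer TIFFs come back scaled to [0,1]; restore the 8-bit
    # scale (32-bit pages are float and kept as stored)
    scale <- if (!is.null(bits) && bits >= 32) 1 else 255
    ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]]); nz <- length(pages)
    arr <- array(0, dim = c(nx, ny, nz))
    for (z in seq_len(nz)) arr[, , z] <- t(pages[[z]]) * scale
    if (scale == 255) arr <- round(arr)
    if (is.null(voxel_size)) {
      warning("TIFF carries no voxel size; assuming 1 x 1 x 2 um")
      voxel_size <- voxel_size()
    }
    vb_volume(arr, voxel_size)
  } else if (ext == "nrrd") {
    read_nrrd(path)
  } else stop("unsupported volume format: .", ext)
}

#' Write a 3D volume to TIFF or NRRD
#'
#' Integer-valued volumes within 0..255 are written as 8-bit (lossless
#' round-trip); anything else as 32-bit float.  For TIFF, float data are
#' stored as-is when within \[0, 1\] and the voxel size is not embedded
#' (NRRD keeps it in the header).
#'
#' @param vol a [vb_volume()] or 3D array.
#' @param path output path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  vol <- as_vb_volume(vol)
  ext <- tolower(tools::file_ext(path))
  arr <- vol$data
  eightbit <- all(arr >= 0 & arr <= 255) && all(arr == round(arr))
  if (ext %in% c("tif", "tiff")) {
    nz <- dim(arr)[3]
    if (eightbit) {
      pages <- lapply(seq_len(nz), function(z) t(arr[, , z]) / 255)
      tiff::writeTIFF(pages, path, bits.per.sample = 8)
    } else {
      if (any(arr < 0 | arr > 1))
        stop("float TIFF output expects values in [0, 1]")
      pages <- lapply(seq_len(nz), function(z) t(arr[, , z]))
      tiff::writeTIFF(pages, path, bits.per.sample = 32)
    }
  } else if (ext == "nrrd") {
    write_nrrd(vol, path, eightbit = eightbit)
  } else stop("unsupported volume format: .", ext)
  invisible(path)
}

# --- minimal NRRD (format revision 4, raw encoding, little endian) ---------

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD000", magic)) stop("not an NRRD file: ", path)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || line == "") break
    if (grepl("^#", line)) next
    kv <- strsplit(line, ": ?", fixed = FALSE)[[1]]
    hdr[[tolower(kv[1])]] <- paste(kv[-1], collapse = ": ")
  }
  sizes <- as.integer(strsplit(hdr$sizes, " +")[[1]])
  if (length(sizes) != 3) stop("only rank-3 NRRD volumes are supported")
  type <- hdr$type
  vs <- NULL
  if (!is.null(hdr[["space directions"]])) {
    m <- regmatches(hdr[["space directions"]],
                    gregexpr("-?[0-9.eE+]+", hdr[["space directions"]]))[[1]]
    m <- as.numeric(m)
    if (length(m) == 9) vs <- c(m[1], m[5], m[9])
  } else if (!is.null(hdr$spacings)) {
    vs <- as.numeric(strsplit(hdr$spacings, " +")[[1]])
  }
  if (is.null(vs)) {
    warning("NRRD carries no voxel size; assuming 1 x 1 x 2 um")
    vs <- c(1, 1, 2)
  }
  n <- prod(sizes)
  data <- switch(type,
    "uint8"  = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    "uchar"  = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    "float"  = readBin(con, "numeric", n, size = 4, endian = "little"),
    "double" = readBin(con, "numeric", n, size = 8, endian = "little"),
    stop("unsupported NRRD type: ", type))
  vb_volume(array(data, dim = sizes), vs)
}

write_nrrd <- function(vol, path, eightbit) {
  arr <- vol$data
  vs <- vol$voxel_size
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    "# written by vesselbench",
    sprintf("type: %s", if (eightbit) "uint8" else "float"),
    "dimension: 3",
    "space: left-posterior-superior",
    sprintf("sizes: %d %d %d", dim(arr)[1], dim(arr)[2], dim(arr)[3]),
    sprintf("space directions: (%g,0,0) (0,%g,0) (0,0,%g)", vs[1], vs[2], vs[3]),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    "")
  writeLines(hdr, con, sep = "\n")
  if (eightbit) {
    writeBin(as.integer(arr), con, size = 1)
  } else {
    writeBin(as.numeric(arr), con, size = 4, endian = "little")
  }
  invisible(path)
}

# physical (um) distance helpers ---------------------------------------------

phys_dist <- function(a, b, vs) {
  d <- (a - b) * as.numeric(vs)[seq_along(a)]
  sqrt(sum(d * d))
}

# Trilinear interpolation of a volume at continuous 0-based (x,y,z) points.
# Out-of-bounds samples return `fill` and are flagged.
trilinear <- function(vol, pts, fill = 0) {
  arr <- vol$data
  d <- dim(arr)
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  n <- nrow(pts)
  vals <- rep(fill, n)
  oob <- rep(FALSE, n)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  oob <- x < 0 | y < 0 | z < 0 | x > d[1] - 1 | y > d[2] - 1 | z > d[3] - 1
  inb <- which(!oob)
  if (length(inb)) {
    x0 <- pmin(floor(x[inb]), d[1] - 2); x0 <- pmax(x0, 0)
    y0 <- pmin(floor(y[inb]), d[2] - 2); y0 <- pmax(y0, 0)
    z0 <- pmin(floor(z[inb]), d[3] - 2); z0 <- pmax(z0, 0)
    fx <- x[inb] - x0; fy <- y[inb] - y0; fz <- z[inb] - z0
    if (d[1] == 1) { x0 <- 0; fx <- 0 }
    if (d[2] == 1) { y0 <- 0; fy <- 0 }
    if (d[3] == 1) { z0 <- 0; fz <- 0 }
    idx <- function(i, j, k) arr[cbind(i + 1, j + 1, k + 1)]
    x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
    z1 <- pmin(z0 + 1, d[3] - 1)
    vals[inb] <-
      idx(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
      idx(x1, y0, z0) * fx       * (1 - fy) * (1 - fz) +
      idx(x0, y1, z0) * (1 - fx) * fy       * (1 - fz) +
      idx(x1, y1, z0) * fx       * fy       * (1 - fz) +
      idx(x0, y0, z1) * (1 - fx) * (1 - fy) * fz +
      idx(x1, y0, z1) * fx       * (1 - fy) * fz +
      idx(x0, y1, z1) * (1 - fx) * fy       * fz +
      idx(x1, y1, z1) * fx       * fy       * fz
  }
  list(values = vals, oob = oob)
}

# Anisotropy-aware squared distance transforms (0-based voxel grid).
# dist_to_background: inside-foreground distance (used as a radius proxy);
# dist_to_foreground: used for ball dilation/erosion.
edt <- function(mask, voxel_size = c(1, 1, 1), to = c("background", "foreground")) {
  to <- match.arg(to)
  d <- dim(mask)
  src <- if (to == "background") !mask else mask
  f <- ifelse(src, 0, Inf)
  out <- .edt_sq_cpp(as.numeric(f), as.integer(d), as.numeric(voxel_size)[1:3])
  array(sqrt(out), dim = d)
}

dilate_ball <- function(mask, radius, voxel_size = c(1, 1, 1)) {
  edt(mask, voxel_size, to = "foreground") <= radius
}

erode_ball <- function(mask, radius, voxel_size = c(1, 1, 1)) {
  !(edt(!mask, voxel_size, to = "foreground") <= radius)
}

label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- .cc_label_cpp(as.logical(mask), as.integer(d), as.integer(connectivity))
  array(lab, dim = d)
}
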