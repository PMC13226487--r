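# shared fixture suite, built once per test run
.fx_cache <- new.env(parent = emptyenv())

fixture_suite <- function() {
  if (is.null(.fx_cache$fx)) .fx_cache$fx <- make_fixture_suite()
  .fx_cache$fx
}

# random tree skeleton with coordinates on a fixed-precision grid
# (so SWC round-trips are exactly representable)
random_tree_skeleton <- function(n = 50, seed = 1) {
  set.seed(seed)
  parent <- c(-1L, vapply(2:n, function(i) sample.int(i - 1L, 1), integer(1)))
  nodes <- data.frame(
    id = 1:n, type = 2L,
    x = round(runif(n, 0, 100), 4),
    y = round(runif(n, 0, 100), 4),
    z = round(runif(n, 0, 50), 4),
    radius = round(runif(n, 0.5, 8), 4),
    parent = parent)
  skeleton(nodes)
}

# simple chain skeleton along x
chain_skeleton <- function(n = 10, y = 0, z = 0, r = 2, x0 = 0) {
  skeleton(data.frame(id = 1:n, type = 2L, x = x0 + seq_len(n) - 1,
                      y = y, z = z, radius = r,
                      parent = c(-1L, 1:(n - 1))))
}

unit_vec <- function(v) v / sqrt(sum(v^2))

# total index-space polyline length of all parent-child segments
skeleton_segments_length <- function(sk) {
  nodes <- sk$nodes
  pidx <- match(nodes$parent, nodes$id)
  ok <- !is.na(pidx)
  sum(sqrt((nodes$x[ok] - nodes$x[pidx[ok]])^2 +
           (nodes$y[ok] - nodes$y[pidx[ok]])^2 +
           (nodes$z[ok] - nodes$z[pidx[ok]])^2))
}

# Y-shaped skeleton: stem along +x, two limbs at +-45 degrees in the xy-plane
y_skeleton <- function(stem = 10, limb = 8) {
  s <- data.frame(id = 1:stem, type = 2L, x = seq_len(stem) - 1, y = 0, z = 0,
                  radius = 2, parent = c(-1L, 1:(stem - 1)))
  l1 <- data.frame(id = stem + 1:limb, type = 2L,
                   x = stem - 1 + seq_len(limb), y = seq_len(limb), z = 0,
                   radius = 2,
                   parent = c(stem, stem + seq_len(limb - 1)))
  l2 <- data.frame(id = stem + limb + 1:limb, type = 2L,
                   x = stem - 1 + seq_len(limb), y = -seq_len(limb), z = 0,
                   radius = 2,
                   parent = c(stem, stem + limb + seq_len(limb - 1)))
  skeleton(rbind(s, l1, l2))
}
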