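---
title: "Methods: synthetic vascular benchmarks and reconstruction metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic vascular benchmarks and reconstruction metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`vesselbench` implements the computational core of a
"segment-first, then reconstruct" pipeline for 3D light-microscopy
vasculature (fMOST-style acquisitions: 8-bit volumes at an anisotropic
1 × 1 × 2 µm voxel size), together with the evaluation metrics used to
benchmark such pipelines.  Because real whole-brain acquisitions are
terabyte-scale and annotation is interactive, every component here is
exercised against *synthetic tubular phantoms* with exact ground truth.
This vignette records the models, parameter choices and numerical
decisions, and what the phantom-based tests do and do not demonstrate
about real data.

# Coordinate and data conventions

Volumes are R arrays of dimension `(nx, ny, nz)`; the voxel with 0-based
spatial coordinates `(x, y, z)` sits at `data[x+1, y+1, z+1]`.  All
continuous coordinates (skeleton nodes, rays, centerline samples) are
0-based voxel indices, so integer coordinates coincide with voxel centres.
Physical distances multiply coordinate differences by the voxel size
componentwise before taking the Euclidean norm.  Radii are stored in
micrometres.  Skeletons follow SWC semantics (id, type, x, y, z, radius,
parent); since SWC trees cannot encode cycles, anastomoses are carried as
*fusion links* — unordered node-id pairs serialized as `#FUSION i j`
comment lines, which ordinary SWC readers skip, keeping the files valid
forests.

# The phantom generator

`generate_skeleton()` grows random vessel trees by stepwise extension:
one-voxel steps whose direction is perturbed by Gaussian noise of scale
`tortuosity`, bifurcating with per-step probability `branch_prob`, with
child radii drawn as a 0.6–0.95 fraction of the parent radius and clamped
to `radius_range`.  Tips advance in round-robin order so a bifurcation's
branches grow concurrently, and growth stops at the (radius-inset) volume
boundary or when the per-tree step budget is spent.  `render_volume()`
marks a voxel foreground iff its *physical* distance to the skeleton
polyline is at most the locally interpolated radius — anisotropy is
handled at render time, so phantoms are correct under 1 × 1 × 2 µm without
resampling.  Vessels thicker than `hollow_radius_threshold` (default 8 µm)
are rendered hollow in the image: voxels closer to the centerline than
`lumen_fraction × radius` stay at background level, while the binary mask
remains solid.  The lumen test uses the distance to the *whole* polyline
(not per segment), otherwise the spherical end caps of neighbouring
segments would spuriously paint the lumen as wall.  Intensities are
`background_level + foreground_intensity·wall + N(0, noise_sd)`, clipped
to [0, 255] and rounded.

Default emulation targets reflect the imaging regime the package
addresses: radii from 2 µm (capillaries) to 20 µm (trunk vessels), 8-bit
intensities with weak-signal regimes down to a foreground mean of ~10,
additive Gaussian read noise (σ = 5 by default; Poisson photon statistics
and the optical PSF are deliberately out of scope).  The five named
fixtures (`straight_tube`, `y_junction`, `hollow_trunk`,
`capillary_mesh`, `weak_signal`) are deterministic and carry exact
ground-truth skeletons; all quantitative tests run against them.  What
passing these tests shows is that each algorithm is *correct on clean
tubular geometry at realistic scale and contrast*; it does not establish
robustness to segmentation artefacts, touching vessels, or staining
inhomogeneity beyond the modelled hollow lumens.

Block curation mirrors the preprocessing of large acquisitions:
`tile_blocks()` spaces block origins evenly from 0 to `extent − b`
(blocks overlap whenever `k·b` exceeds the extent), and
`select_training_blocks()` clusters the blocks' normalised 256-bin gray
histograms by k-means and samples proportionally to cluster size
(largest-remainder rounding).  The canonical tiling of a 512-voxel extent
into 196-voxel blocks gives starts {0, 316} at two blocks per axis; the
published block *count* for that tiling is not reproducible by any integer
stride, so per-axis counts are an explicit parameter rather than a
hard-coded constant.  k-means uses `stats::kmeans` (Lloyd) with multiple
random starts under a fixed seed; determinism given the seed is the
contract, not a particular initialisation.

# Supervision maps and the region-weighted loss

Training a segmentation network from skeleton + radius annotations
requires a soft foreground map.  `render_probability_map()` places an
anisotropic Gaussian kernel at every resampled centerline point with

$$\sigma_p = \frac{r_p}{\sqrt{2\,\ln(1/0.404)}},$$

so that the kernel's 0.404 iso-level falls exactly at physical distance
$r_p$ — the vessel wall.  The kernel width "matched to the local radius"
is otherwise underdetermined; this choice makes the upper working
threshold coincide with the vessel boundary, which in turn makes the
region definitions of the loss self-consistent: $S_2$ (map > 0.404) is
the vessel interior and $S_1$ (map > 0.012, ≈ 2.97 σ ≈ 2.2 r) is the
surrounding transition halo.  Kernels combine by voxelwise *maximum* —
a sum would exceed 1 where kernels overlap, breaking probability
semantics — so the centerline value is exactly 1.  Kernels are truncated
at 3σ; the truncation error (< 0.012) stays below the lower threshold.
Zero-radius points contribute a single-voxel impulse.

The training loss is a sum of four mean-absolute-error terms between
prediction $y_p$ and ground truth $y_g$:

$$\mathcal{L} = \tfrac{1}{N}\lVert y_p-y_g\rVert_1
 + \tfrac{1}{\#S_1}\lVert (y_p-y_g)_{S_1}\rVert_1
 + \tfrac{1}{\#S_2}\lVert (y_p-y_g)_{S_2}\rVert_1
 + \tfrac{1}{\#S_2^*}\lVert (y_p-y_g)_{S_2^*}\rVert_1,$$

where $S_1, S_2$ threshold the ground truth at 0.012 and 0.404 and
$S_2^*$ thresholds the *prediction* at 0.404 (penalising false-positive
foreground).  Thresholding is strict (`>`).  Note the naming is
threshold-ordered: with 0.404 > 0.012, $S_2 \subseteq S_1$, i.e. $S_2$ is
the stricter (interior) set and $S_1$ the halo.  A term over an empty
region is defined as 0 (the 0/0 case is otherwise undefined); the four
terms are unweighted by default with optional weights.  `combined_loss()`
is a pure numeric function — the network architecture and training loop
are out of scope — and is verified against a brute-force voxel-loop
oracle to 1e-10.

# Dual-view ray geometry for radius annotation

A single screen projection cannot localise a vessel in 3D.  The
interactive measurement geometry is: click the vessel centre in two
different views; each click back-projects to a ray (orthographic camera
by default, perspective available — the camera model is a free choice and
orthographic matches parallel-projection volume viewers); the vessel
centre estimate $P_c$ is the midpoint of the common perpendicular of the
two rays, computed with parameters clamped to $t \ge 0$ since rays
emanate from a viewpoint.  Intensity profiles are sampled by trilinear
interpolation at unit-voxel steps along each ray through its
perpendicular foot, and an interval $[L_i]$ spanning the vessel is chosen
on each profile.  In the interactive workflow that selection is manual;
here it is automated deterministically by a full-width-at-half-maximum
rule (the maximal run around the profile peak at or above
(max + min)/2), which makes the operation testable.  The radius estimate
is

$$r = 0.25\,\bigl(L_1\,\lVert d_1 \odot s\rVert + L_2\,\lVert d_2 \odot s\rVert\bigr),$$

with $d_i$ the unit ray directions, $s$ the voxel size and $\odot$ the
componentwise product: each $L_i\lVert d_i \odot s\rVert$ is a measured
diameter in µm and the estimate is the mean radius of the two views,
implemented literally.  On the noiseless 3 µm straight-tube fixture the
whole chain (rays → FWHM → formula) recovers 3.25 µm; the 0.25 µm bias is
the expected half-voxel discretisation of an integer-length FWHM run and
sits well within the max(0.5 µm, 15 %) acceptance band.

# Hollow-lumen filling

Segmentations of thick vessels are frequently annular (dye lines only the
wall).  `fill_hollow()` implements: nearest-neighbour downsampling to half
size; min-max normalisation; Gaussian smoothing (σ = 2 on a 3×3×3
support); Otsu binarisation on a 256-bin histogram; morphological closing
with a radius-2 ball; a connected-background hole fill (6-connected
background components that do not reach the volume border become
foreground); nearest-neighbour upsampling; and a voxelwise OR with the
binarised input.  Closing alone cannot seal a long axial lumen at radius
2 — the hole fill is the minimal addition that achieves the stated
purpose, and the OR merge guarantees the output foreground is a superset
of the input.  Morphology uses exact Euclidean distance transforms
(dilation/erosion by EDT thresholding), so the ball structuring element is
not an approximation.  Nearest-neighbour upsampling keeps the mask binary;
trilinear with a 0.5 threshold is available behind a flag.  A
constant-intensity input (Otsu undefined) is returned unchanged with a
warning.  On the `hollow_trunk` fixture (10 µm trunk, 5 µm lumen) the
lumen fills completely and the traced centerline F1 rises from ≈0.13
(annulus: the tracer follows the wall) to ≈0.93.

# Centerline tracing

Two tracers operate on binary masks.  **Voxel scooping** propagates a
front from the most interior voxel of each connected component (the
distance-transform maximum): each iteration claims the next 26-connected
shell of unvisited foreground, partitions it into connected clusters, and
places one node per cluster at the cluster centroid (snapped to the
nearest cluster voxel if the centroid falls outside the mask — concave
clusters), with radius read from the distance transform.  A shell
splitting into several clusters is a bifurcation; a cluster adjacent to
two different previous-shell branches marks the meeting of two fronts —
an anastomosis — recorded as a fusion link rather than duplicate
coverage.  Every foreground voxel is visited exactly once (asserted).
**Thinning** removes simple border points (Bertrand–Malandain simpleness:
one 26-connected foreground component in the 26-neighbourhood and one
6-connected background component in the 18-neighbourhood seeded from the
6-neighbours) in six directional subiterations, keeping curve endpoints,
to a one-voxel-wide skeleton; skeleton voxels are then classified by
neighbour count (1 endpoint, ≥3 junction), junction clusters collapse to
their centroid, paths become edges and surviving cycles become fusion
links.  Both distance transforms default to voxel-index space with an
anisotropy-aware option.  `prune_spurs()` removes terminal edges shorter
than `min_len` nodes or physically shorter than `radius_factor` × the
branch-point radius, iterated to a fixed point — thick vessels otherwise
sprout false side branches whose length scales with the radius.  The
constants (26-connectivity, min_len = 5, radius_factor = 1.5) are package
choices exposed as parameters.

# Evaluation metrics

Matching is nearest-neighbour thresholding: a point matches when its
nearest neighbour in the other set is closer than `Thre` (3 voxels for
resampled centerlines, 5 for branch points).  Recall averages matches
over the ground-truth set, precision over the predicted set, F1 is their
harmonic mean.  Two printed-vs-prose ambiguities are resolved as flags:
distance is plain Euclidean in voxel-index space by default (`squared =
TRUE` gives the literal squared-norm reading, which the stated
threshold-to-µm correspondence contradicts) and comparison is strict `<`
(`inclusive = TRUE` gives `≤`).  Matching is not one-to-one, so duplicate
predictions can inflate precision; this mirrors the printed rule and is
documented rather than silently corrected.  Skeleton-level evaluation
resamples both skeletons at one-voxel arc-length steps first.

Graph abstraction treats bifurcations and endpoints (structural degree
counts parent, child *and* fusion links) as nodes and maximal degree-2
paths as edges; the handshake identity (Σ degree = 2·edges) is asserted,
and cycles appear as `edges − nodes + components ≥ 1`.  Branch angles
take, per branch point and incident edge, the unit vector (in physical
µm) to the 5th one-voxel-resampled point along the edge (≈5 µm — far
enough to escape junction blur, close enough to stay local); both
child–child and parent–child pairs are emitted, labelled, since either
convention appears in practice.  Vessel density divides a block into
64³-voxel cells (a 192³ block gives exactly 27), assigns each resampled
segment's physical length to the cell containing its midpoint — chosen
over clipping so total length is conserved exactly, which is asserted —
and reports mm of centerline per mm³ of tissue.  SNR is the mean signal
at skeleton points divided by the standard deviation of the background,
background being everything outside the mask dilated by 3 voxels.
`smartvision_candidates()` proposes review regions for topology
proofreading: windows containing ≥2 endpoints (possible broken
connection) or ≥1 branch point, merged into bounding boxes.

# Numerical choices and degenerate inputs

* Skeleton smoothing fixes endpoints and branch points exactly, applies a
  centred moving average (window 5) to edge interiors, then re-evaluates
  an interpolating B-spline (degree 3, chord-length collocation sites,
  clamped knot vector via knot averaging) at uniform arc-length sites.
  Window and degree are package defaults — no canonical values exist.
  Edges shorter than the window pass through unchanged; no point moves
  farther than window/2 voxels.
* Resampling includes both edge endpoints and rounds the segment count,
  keeping consecutive spacing within [0.5, 1.5] steps; zero-length edges
  collapse to a single point.
* Ray intersection flags parallel rays and returns the clamped boundary
  optimum when the unconstrained solution has a negative parameter.
* Flat intensity profiles (no vessel signal) raise an error rather than
  returning a spurious interval.
* Empty skeletons, empty masks, and empty point sets return flagged empty
  results rather than NaN; an empty ground truth makes recall 0 with a
  `degenerate` flag.
* SWC output prints 6 decimal digits; round-trips are bit-faithful for
  coordinates representable at that precision.

# Problem sizes

All tests and the acceptance script run on fixtures of 48–64 voxels per
axis (10³–10⁴ foreground voxels), 8³ volumes for oracle comparisons, and
≤200-point sets for matching oracles; the full suite completes in well
under a minute on one CPU.  These sizes were chosen so that brute-force
oracles (voxel loops, all-pairs distances, grid searches) remain exact
and fast; every algorithm is written to scale to full 512³ blocks, but
the package makes no performance claims at that scale.

# Known limitations

* The phantom's noise model is additive Gaussian only; no PSF, no
  shot noise, no intensity inhomogeneity along vessels.
* The voxel-scooping formulation is the standard shell-cluster reading of
  the method; published variants differ in cluster linking and radius
  refinement details.
* Non-one-to-one matching inflates precision in the presence of duplicate
  predictions (an optional one-to-one mode is a possible extension).
* `fill_hollow()` cannot distinguish a lumen open to the volume border
  from background; lumens must be enclosed cavities after closing.
* Radius estimation by FWHM assumes a roughly symmetric single-vessel
  profile; crossing vessels within the sampling extent bias the interval.
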