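# vesselbench

Synthetic benchmarks and evaluation tools for 3D vascular network
reconstruction from light-microscopy volumes.

## The problem

Reconstructing the brain's blood-vessel network from micron-resolution 3D
fluorescence imaging (fMOST-style acquisitions: 8-bit volumes, anisotropic
1 × 1 × 2 µm voxels) follows a *segment-first, then reconstruct* pipeline:
a binary vessel segmentation is produced first, then reduced to centerline
skeletons with radii and topology (branch points, endpoints, anastomoses).
Three properties of real cerebrovasculature make this hard: radii span an
order of magnitude (2 µm capillaries to 20 µm trunks) in one field of
view, thick vessels image as hollow annuli (dye lines only the wall), and
capillary beds are dense and low-contrast.  `vesselbench` provides, for
people building or evaluating such pipelines:

* **phantoms** — synthetic tubular volumes with exact ground-truth SWC
  skeletons, including hollow trunks, anastomoses (cycles) and
  weak-signal regimes;
* **annotation tooling** — skeleton smoothing, arc-length resampling,
  radius-matched Gaussian supervision maps, dual-view ray geometry for
  interactive radius measurement;
* **training loss** — the region-weighted L1 loss as a pure numeric
  function;
* **reconstruction** — hollow-lumen filling, voxel-scooping and
  thinning-based centerline tracers, spur pruning;
* **metrics** — centerline/branch-point matching (recall, precision, F1),
  graph statistics, branch angles, vessel density, intensity/SNR
  statistics, and review-region proposal.

## The core quantities

A predicted skeleton `P` is compared with ground truth `G` after
resampling both at one-voxel arc-length steps, under the matching rule

    I(p, S) = 1  iff  min_{q in S} ||p − q|| < Thre

with `Thre = 3` voxels for centerline points and `5` for branch points;
then

    Recall = Σ_{g∈G} I(g, P) / N_g,  Precision = Σ_{p∈P} I(p, G) / N_p,
    F1 = 2·R·P / (R + P).

Supervision maps place a Gaussian at each centerline point with
`σ = r / sqrt(2 ln(1/0.404))`, so the 0.404 iso-level sits exactly on the
vessel wall, and the training loss sums four mean-absolute-error terms:
global, over the ground-truth regions `S1 = {gt > 0.012}` and
`S2 = {gt > 0.404}`, and over the predicted foreground
`S2* = {pred > 0.404}`.  The dual-view radius estimate combines interval
lengths `L1, L2` measured along two viewing rays `d1, d2` as
`r = 0.25 (L1·|d1⊙s| + L2·|d2⊙s|)` with `s` the voxel size.  Vessel
density is centerline length per tissue volume (mm/mm³) on 64³-voxel
sub-blocks.  See `vignettes/vesselbench-methods.Rmd` for the full account.

## Worked example

Trace a noiseless 3 µm straight-tube phantom and score it against its
ground truth, then show why hollow trunks must be filled before tracing:

```r
library(vesselbench)
fx <- make_fixture_suite()

st <- fx$straight_tube
st$image
#> <vb_volume 48 x 32 x 16 (x,y,z), voxel 1 x 1 x 2 um, range [10, 130]>

sk <- voxel_scoop(st$mask)
sk
#> <skeleton: 46 nodes, 1 roots, 0 fusion links>
evaluate_skeleton(sk, st$skeleton, thre = 3)
#> <match: recall 1.0000, precision 1.0000, F1 1.0000 (Ng=44, Np=47)>

# a 10 um trunk segmented as an annulus (5 um hollow lumen)
ht <- fx$hollow_trunk
seg <- vb_volume(array(as.numeric(ht$image$data > 60),
                       dim = dim(ht$image$data)), ht$image$voxel_size)
evaluate_skeleton(prune_spurs(voxel_scoop(seg)), ht$skeleton)
#> <match: recall 0.1667, precision 0.1061, F1 0.1296 (Ng=36, Np=66)>
evaluate_skeleton(prune_spurs(voxel_scoop(fill_hollow(seg))), ht$skeleton)
#> <match: recall 0.9722, precision 0.8864, F1 0.9273 (Ng=36, Np=44)>
```

The annulus makes the tracer follow the wall (F1 0.13); filling the lumen
first recovers the centerline (F1 0.93).

A command-line wrapper over the same functions is installed at
`inst/cli/vesselbench.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/vesselbench.R", package="vesselbench"))')" \
    phantom --out fixtures/
```

with subcommands `phantom`, `maskgen`, `loss`, `radius`, `fill`, `trace`,
`eval`, `stats`.

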