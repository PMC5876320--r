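---
title: "Group-wise brain atlas construction and evaluation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-wise brain atlas construction and evaluation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(atlasforge)
```

# The problem

Digital brain atlases pair a grayscale *template* — a representative image of
a pan-neuropil reference stain such as nc82, whose contrast delineates
anatomical boundaries — with a voxel-wise *label image* assigning every
location to a named region. Two tasks hang off such an atlas:

* **segmentation** — warp the atlas labels into an individual brain's native
  space to annotate it automatically;
* **registration** — warp individual brains into the atlas space so their
  expression patterns can be compared voxel by voxel.

A template built from a single individual imports that individual's
morphological idiosyncrasies. A *group-wise* template, built by iteratively
co-registering and combining many individuals, is meant to remove that bias.
`atlasforge` implements the full construction and evaluation machinery —
registration engine, template loop, label fusion, overlap and surface-distance
metrics, convergence experiments — together with a synthetic phantom
generator so that every component can be exercised and validated end-to-end
without access to confocal data.

# The phantom population

`make_reference()` builds a shared anatomy: an ellipsoidal brain envelope
containing 14 neuropil-like regions — five bilateral pairs (medulla, lobula,
lobula plate, mushroom body, antennal lobe) mirrored about the mid-sagittal
plane and four midline bodies (ellipsoid body, noduli, fan-shaped body,
protocerebral bridge) — each an ellipsoid with a distinct base intensity, a
smooth low-frequency texture, and crisp boundaries. The default grid is
64 x 64 x 48 voxels at 1.2 x 1.2 x 1.1 um, the working resolution obtained
when 0.6 x 0.6 x 1.1 um confocal stacks are downsampled twofold in x and y
to make voxels nearly cubic; `voxel_diagonal(c(0.6, 0.6, 1.1))` is the
1.4 um yardstick used when judging "sub-voxel" accuracy.

`sample_population()` perturbs the reference per subject with, in order:

1. a random smooth diffeomorphism — a Gaussian-filtered stationary velocity
   field (sigma `warp_smoothness = 8` voxels) scaled to a maximum
   displacement of `warp_amplitude = 3` um and exponentiated by scaling and
   squaring, which makes its inverse available in closed form (the
   exponential of the negated velocity);
2. a small affine jitter (rotations up to 4 degrees, translations up to
   1.5 voxels, isotropic scale jitter of 2%);
3. a group-wise linear size factor, `female = 1.05` and `male = 0.95` by
   default, emulating the female-larger sexual size dimorphism of insect
   neuropils;
4. a smooth multiplicative intensity bias (5%) plus additive Gaussian noise
   (2% of dynamic range).

All draws derive from one seed; the ground-truth transform of every subject
is recorded so that registration error can be attributed exactly. Because the
generator's deformation model (stationary velocity fields) deliberately
differs from the registration engine's (greedy symmetric composition),
recovery tests are not self-confirming.

What the phantoms do **not** emulate: optical point-spread and z-attenuation,
staining chemistry variation, manual-delineation noise in the labels, and
true anatomical idiosyncrasy beyond smooth diffeomorphisms. The last two
omissions matter when interpreting atlas rankings (see *Limitations*).

# The registration engine

Subject-to-atlas registration is the composition of two native stages, the
same order used by standard atlas pipelines:

**Rigid stage.** `rigid_register()` maximises the mutual information of the
joint 32-bin intensity histogram (intensities clipped to their 0.5-99.5
percentile range) over rotations and translations about the volume centre,
by coordinate descent with a deterministic step-halving schedule, run
coarse-to-fine over a Gaussian image pyramid. On phantoms it recovers
translations to well under half a voxel and rotations to a few tenths of a
degree.

**Deformable stage.** `diffeo_register()` is a greedy symmetric scheme with
local cross-correlation as the similarity force. Both images are warped
toward a common midpoint by half-path displacement fields `u1`, `u2`; at
every iteration the windowed-correlation gradient force is computed on each
side (window half-width `cc_radius = 3` voxels), smoothed with a fluid-like
Gaussian (`sigma_update`), capped at `step = 0.25` voxel, accumulated by
composition, and the accumulated fields receive a light diffusion-like
smoothing (`sigma_total = 0.5` voxel). The forward map is assembled as
`u2 o u1^{-1}` (and the inverse as the mirrored composition), with the
half-field inversions refined by fixed-point iteration. The step cap of at
most 0.4 voxel keeps every incremental map invertible, so the composition
stays diffeomorphic: on phantom pairs the Jacobian determinant is positive
essentially everywhere and forward-inverse composition residuals stay well
under half a voxel.

Numerical conventions worth stating: voxel indices are 0-based; world
position = origin + index x spacing (um); displacement fields are stored in
world units on the output grid; all warping is backward mapping (pull-back)
with trilinear interpolation for intensities, nearest-neighbour for labels,
and background fill 0 outside the domain.

Two engine defaults were settled empirically on phantom recovery benchmarks
(known-warp label Dice): `sigma_update = 2` voxels recovers fine deformation
detail better than broader smoothing at these grid sizes, and rescaling the
whole force field so its peak step equals `step` ("max" update rule) proved
more accurate than per-voxel unit-flow normalisation, which overshoots in
low-contrast areas. Both remain configurable in `reg_config()`.

# Template construction and label fusion

`build_template()` follows the two-step strategy: all subjects are rigidly
aligned onto one subject chosen by a seeded draw and voxel-wise averaged into
a blurry initial template; then, for `outer_iters` refinement passes, every
subject is diffeomorphically registered onto the current template and the
co-registered intensities are recombined. Two combinations are provided:

* **mean** — voxel-wise average followed by Laplacian sharpening
  (`out = in - alpha L(in)`, 6-neighbour spacing-aware stencil, negative
  values clamped), the classic sharpened-average recipe;
* **median** — voxel-wise median with no sharpening, which is intrinsically
  robust: with up to half the subjects corrupted the median combination
  tracks the clean population, and it avoids the noise amplification the
  sharpening step introduces.

The template lives on the initial reference subject's grid throughout. The
final pass's transforms are reused by `fuse_labels()`, which warps every
subject's labels onto the template grid (nearest-neighbour) and takes a
per-voxel majority vote; ties break deterministically toward the smaller
label id, with background competing as an ordinary label.

# Evaluation metrics

For a region present in two label images on one grid:

* `dice()` — `2 |A n B| / (|A| + |B|)`;
* `mean_symmetric_surface_distance()` — the two directed mean
  boundary-to-nearest-boundary distances, averaged;
* `symmetric_hausdorff()` — the two directed max-of-min boundary distances,
  averaged.

"Boundary" means region voxels with at least one 6-connected face neighbour
outside the region (volume borders count), and distances are Euclidean in
world coordinates, so anisotropic grids are handled correctly. A region
absent from both images raises an error rather than returning a silent 0 or
1. The same implementations are checked exactly (distances to 1e-9 um)
against an independent brute-force all-pairs oracle on hundreds of random
volumes.

Trace scoring replaces region boundaries with 3D polylines resampled to 1 um
arc-length steps: `trace_distance()` is the mean symmetric nearest-point
distance, and `normalized_trace_distance()` divides by the template's
equivalent spherical radius `(3V / 4 pi)^{1/3}` (foreground volume V by Otsu
threshold unless a fixed threshold is given) to make scores comparable
across templates of different sizes.

`masked_overlap()` implements the brush-style spatial query: Dice of two
binarised patterns restricted to a mask, with explicit thresholds, plus a
companion filter retaining candidates whose overlap strictly exceeds 20% by
default.

# Experiment harnesses

`evaluate_segmentation()` registers each test subject onto the atlas once
and warps the atlas labels into the subject's native space through the
inverse field — one registration serves both directions because the engine
is symmetric. All three metrics are computed there, where absolute distances
are meaningful. `evaluate_registration()` warps every test subject's labels
into template space and computes Dice only, for every unordered pair of
subjects: in template space absolute distances would be confounded by
template size. Summaries report, per template, the mean over subjects (or
pairs) of region-averaged scores and the standard error of that mean across
subjects — the precision-versus-accuracy view `autoplot()` draws.

`incremental_convergence()` re-runs both tasks for atlases built from
n = 1, 2, ... subjects drawn in seeded random orders that alternate between
group tags, with the starting group balanced across repeats, and averages
over repeats.

`wilcoxon_signed_rank()` provides the paired test used for template
comparisons. For up to 25 non-zero differences the two-sided p comes from
the exact null distribution of the positive rank sum, computed by a dynamic
programme over doubled midranks — identical to enumerating all sign
assignments, and valid under ties, which the standard exact implementation
refuses; larger samples fall back to a normal approximation with continuity
and tie corrections. Degenerate all-zero inputs report p = 1 with a flag.

# Problem sizes and numerical choices

The test-suite and acceptance experiments run at deliberately modest sizes
chosen so the whole pipeline stays within desk-scale compute budgets while
every structure remains several voxels thick:

* metric oracle equivalence: 200 random volumes up to 20^3;
* transform recovery: 48 x 48 x 36-40 grids, 20 rigid trials;
* atlas comparison (10 template + 12 test): the full default
  64 x 64 x 48 grid;
* convergence: up to 6-8 template brains, 3 repeats, reduced grids.

Degenerate inputs are handled explicitly: constant images cannot be
registered or Otsu-thresholded (typed errors), empty masks and
absent-from-both regions raise errors instead of fabricated scores, and
field inversion reports its final residual if the fixed-point iteration
fails to contract.

# Known limitations

* Field-space recovery bounds are misleading on smooth anatomy: image
  contrast determines only the gradient-aligned component of a deformation
  (the aperture problem), so the tangential component of a synthetic warp is
  set by the regularizer, not the data, and vector-norm comparisons between
  recovered and true displacement fields stay at the scale of that
  unobservable component even when boundary alignment is sub-voxel. Recovery
  is therefore judged primarily by propagated-label overlap and boundary
  distances, with the raw field residual reported alongside.

* The phantom's inter-individual variation is a smooth random diffeomorphism
  of a single shared anatomy with noise-free, perfectly consistent labels.
  Real populations add unrecoverable idiosyncrasy and manual-delineation
  noise — precisely the error sources that group-wise averaging and majority
  voting are designed to suppress. Phantom experiments therefore understate
  the advantage of group-wise atlases over individual ones: an individual
  phantom atlas carries perfect labels and a morphology that deformable
  registration can almost fully absorb. The group-wise-versus-individual
  ranking on phantoms is correspondingly tighter than on real data, and at
  coarse grids (where the thinnest structures approach one voxel) majority
  voting erodes small regions enough to reverse it.
* The registration engine reproduces the contract of symmetric diffeomorphic
  registration (symmetry, invertibility, CC drive) at desk scale; its exact
  iteration schedules are not claimed to match any particular production
  implementation.
* Trace generation produces smooth composite Bezier curves; at small test
  grids the 30-120 um target arc length is envelope-limited.
* No optical simulation: conclusions about staining/acquisition robustness
  are out of reach of these phantoms by design.
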