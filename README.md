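# atlasforge

Group-wise brain atlas construction and evaluation on deformable phantoms.

`atlasforge` is an R implementation of the full methodology behind
statistical (group-wise) anatomical brain atlases, of the kind used to map
neuronal expression patterns in the adult *Drosophila* brain from nc82
(pan-neuropil) reference stains:

* grid-aware 3D image containers with NIfTI / multi-page TIFF I/O and
  SWC/CSV axonal-trace I/O;
* a native registration engine: rigid alignment by mutual-information
  ascent, then symmetric diffeomorphic refinement driven by local
  cross-correlation (greedy midpoint scheme, Gaussian fluid/diffusion
  regularisation, step-capped to stay invertible);
* iterative group-wise template construction ("average shaped brain") with
  sharpened-mean or voxel-median intensity combination, shape centering and
  per-voxel majority-vote label fusion;
* the evaluation mathematics: Dice coefficient, mean symmetric surface
  distance and symmetric Hausdorff distance over 6-connected region
  boundaries in world (micrometre) coordinates, trace distances normalised
  by the template's equivalent spherical radius, masked-overlap spatial
  queries with a 20% retention rule;
* experiment harnesses for the segmentation task (atlas labels into subject
  space) and the registration task (subjects into atlas space), incremental
  atlas-size convergence curves, exact Wilcoxon signed-rank statistics, and
  tidy tibble reports with `tidy()` / `glance()` / `autoplot()` methods;
* a synthetic phantom generator — a shared 14-region neuropil-like anatomy
  deformed per subject by random smooth diffeomorphisms with recorded exact
  ground truth — so the whole pipeline is testable end-to-end without any
  imaging data.

The core quantities are the region overlap

    Dice(R_i) = 2 |R_i^A ∩ R_i^B| / (|R_i^A| + |R_i^B|)

and the symmetric boundary distances: the mean (and, for the Hausdorff
variant, the maximum) Euclidean distance from each boundary point of
`R_i^A` to the closest boundary point of `R_i^B`, averaged over both
directions.

## Worked example

Build a small phantom population, a median-intensity group-wise atlas, and
score it on held-out subjects:

```r
library(atlasforge)

cfg <- phantom_config(dims = c(48, 48, 40), seed = 7)
pop <- sample_population(cfg, n = 8, splits = c(template = 5, test = 3))
split <- vapply(pop$subjects, function(s) s$split, character(1))

rc  <- reg_config(levels = 3, iterations = c(30, 20, 10), sigma_update = 2)
atl <- build_atlas(pop$subjects[split == "template"], "median", rc,
                   outer_iters = 2, seed = 7)
atl
#> <atlas> median-combined from 5 subject(s), 48 x 48 x 40 voxels

seg <- evaluate_segmentation(atl, pop$subjects[split == "test"], rc)
glance(seg)[, c("template", "dice_mean", "dice_sem", "msd_um_mean")]
#> # A tibble: 1 x 4
#>   template            dice_mean dice_sem msd_um_mean
#>   <chr>                   <dbl>    <dbl>       <dbl>
#> 1 groupwise_median_n5     0.843   0.0126       0.356
```

`dice_mean` is the Dice coefficient of the propagated atlas labels against
each subject's own labels, averaged over the 14 regions and the test
subjects (1 = perfect overlap); `msd_um_mean` is the corresponding mean
symmetric surface distance in micrometres — here well below the
1.39 um voxel diagonal of the emulated acquisition grid, i.e. sub-voxel
boundary accuracy. `autoplot(seg)` draws the mean-versus-1/s.e.m. view used
to compare templates, and `incremental_convergence()` produces the
Dice-versus-atlas-size curves.

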