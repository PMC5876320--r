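#' Atlas: template intensity plus fused anatomical labels
#'
#' @param template `scalar_image` defining the common coordinate space.
#' @param labels `label_image` on the template grid.
#' @param combination `"mean"` or `"median"` intensity combination used.
#' @param n_subjects number of subjects behind the template.
#' @param provenance list of subject ids, seeds, configuration.
#' @return An object of class `atlas`.
#' @export
atlas <- function(template, labels, combination = c("mean", "median"),
                  n_subjects = 1L, provenance = list()) {
  combination <- match.arg(combination)
  assert_same_grid(template, labels, "template and labels")
  if (n_subjects < 1L) af_stop("`n_subjects` must be >= 1", "argument")
  structure(list(template = template, labels = labels,
                 combination = combination, n_subjects = as.integer(n_subjects),
                 provenance = provenance),
            class = "atlas")
}

#' @export
print.atlas <- function(x, ...) {
  d <- img_dims(x$template)
  cat(sprintf("<atlas> %s-combined from %d subject(s), %d x %d x %d voxels\n",
              x$combination, x$n_subjects, d[1], d[2], d[3]))
  invisible(x)
}

#' Rigidly aligned initial average of a population
#'
#' One subject is chosen as reference by a seeded uniform draw; every other
#' subject is rigidly registered onto it (mutual information) and the
#' voxel-wise mean of the aligned intensities is returned on the reference
#' grid. This is the blurry starting template of the group-wise construction.
#'
#' @param subjects list of [subject_brain()]s (>= 1).
#' @param cfg a [reg_config()].
#' @param seed seed for the reference draw (default `cfg$seed`).
#' @return List with `average` (`scalar_image`), `reference_index`, and
#'   `rigids` (per-subject `rigid_transform`s, identity for the reference).
#' @export
initial_average <- function(subjects, cfg = reg_config(), seed = cfg$seed) {
  n <- length(subjects)
  if (n < 1L) af_stop("need at least one subject", "argument")
  set.seed(seed)
  ref_idx <- sample.int(n, 1L)
  ref <- subjects[[ref_idx]]$intensity
  rigids <- vector("list", n)
  acc <- array(0, img_dims(ref))
  for (i in seq_len(n)) {
    if (i == ref_idx) {
      rigids[[i]] <- rigid_transform()
      acc <- acc + ref$values
    } else {
      rt <- rigid_register(subjects[[i]]$intensity, ref, cfg)
      rigids[[i]] <- rt
      acc <- acc + resample_rigid(subjects[[i]]$intensity, ref, rt)$values
    }
  }
  list(average = scalar_image(acc / n, ref$spacing, ref$origin),
       reference_index = ref_idx, rigids = rigids)
}

combine_stack <- function(stack, combination, sharpen_alpha, spacing, origin) {
  if (combination == "mean") {
    m <- scalar_image(array(rowMeans(stack), dim = attr(stack, "dims3")),
                      spacing, origin)
    laplacian_sharpen(m, sharpen_alpha)
  } else {
    med <- apply(stack, 1L, median)
    scalar_image(array(med, dim = attr(stack, "dims3")), spacing, origin)
  }
}

#' Iterative group-wise template construction
#'
#' Starting from the rigidly aligned [initial_average()], repeats
#' `outer_iters` refinement passes: every subject is registered onto the
#' current template by symmetric diffeomorphic registration (with its rigid
#' transform as initialisation), the co-registered intensities are recombined
#' — voxel-wise mean followed by Laplacian sharpening, or voxel-wise median
#' with no sharpening — and the result becomes the next template. After every
#' pass except the last, the template is additionally warped by the inverse
#' of the mean forward deformation, which drives its morphology toward the
#' population mean shape (an *average shaped* brain) instead of the shape of
#' the initial reference subject; the last pass skips this shape update so
#' that the returned per-subject transforms stay consistent with the
#' returned template for label fusion. The template lives on the reference
#' subject's grid throughout.
#'
#' @param subjects list of [subject_brain()]s with intensity images.
#' @param combination `"mean"` (sharpened average) or `"median"`.
#' @param cfg a [reg_config()].
#' @param outer_iters number of refinement passes (default 4).
#' @param seed seed for the reference draw.
#' @param sharpen_alpha Laplacian sharpening strength for the mean
#'   combination.
#' @return List with `template` (`scalar_image`), `transforms` (per-subject
#'   [diffeo_transform()]s onto the template), `reference_index`, `rigids`.
#' @export
build_template <- function(subjects, combination = c("median", "mean"),
                           cfg = reg_config(), outer_iters = 4L,
                           seed = cfg$seed, sharpen_alpha = 0.3) {
  combination <- match.arg(combination)
  n <- length(subjects)
  if (n < 1L) af_stop("need at least one subject", "argument")
  if (n == 1L) {
    tpl <- subjects[[1]]$intensity
    t0 <- diffeo_transform(zero_field(tpl), zero_field(tpl))
    return(list(template = tpl, transforms = list(t0), reference_index = 1L,
                rigids = list(rigid_transform())))
  }
  ia <- initial_average(subjects, cfg, seed)
  template <- ia$average
  d3 <- img_dims(template)
  transforms <- vector("list", n)
  for (pass in seq_len(outer_iters)) {
    stack <- matrix(0, prod(d3), n)
    for (i in seq_len(n)) {
      transforms[[i]] <- tryCatch(
        diffeo_register(subjects[[i]]$intensity, template, cfg,
                        init = ia$rigids[[i]]),
        error = function(e) {
          af_stop(sprintf("registration failed for subject '%s': %s",
                          subjects[[i]]$id, conditionMessage(e)), "data")
        })
      stack[, i] <- apply_diffeo(transforms[[i]], subjects[[i]]$intensity,
                                 "to_fixed")$values
    }
    attr(stack, "dims3") <- d3
    template <- combine_stack(stack, combination, sharpen_alpha,
                              template$spacing, template$origin)
    if (pass < outer_iters) {
      # shape centering: move the template onto the population mean shape
      mean_u <- Reduce(`+`, lapply(transforms, function(t) {
        field_matrix(t$forward)
      })) / n
      mean_field <- matrix_field(mean_u, transforms[[1]]$forward)
      template <- warp_linear(template, invert_field(mean_field))
    }
  }
  list(template = template, transforms = transforms,
       reference_index = ia$reference_index, rigids = ia$rigids)
}

#' Majority-vote label fusion
#'
#' Warps each subject's label image onto the target grid with its transform
#' (nearest-neighbour) and takes the per-voxel most frequent label. Ties are
#' broken deterministically by the smallest label id; background (0)
#' participates as an ordinary label.
#'
#' @param label_images list of `label_image`s.
#' @param transforms list of [diffeo_transform()]s, one per label image.
#' @param target_grid image defining the output grid (the template).
#' @return The fused `label_image`.
#' @export
fuse_labels <- function(label_images, transforms, target_grid) {
  if (length(label_images) != length(transforms)) {
    af_stop("need one transform per label image", "argument")
  }
  n <- length(label_images)
  d3 <- img_dims(target_grid)
  votes <- matrix(0L, prod(d3), n)
  for (i in seq_len(n)) {
    warped <- apply_diffeo(transforms[[i]], label_images[[i]], "to_fixed")
    votes[, i] <- as.vector(warped$values)
  }
  fused <- cpp_majority_vote(votes)
  label_image(array(fused, d3), target_grid$spacing, target_grid$origin,
              label_images[[1]]$region_names)
}

#' Build a complete atlas (template + fused labels)
#'
#' Convenience wrapper around [build_template()] and [fuse_labels()]. A
#' single-subject "individual atlas" uses that subject's own intensity and
#' labels unchanged.
#'
#' @inheritParams build_template
#' @param id atlas identifier stored in the provenance.
#' @return An [atlas()].
#' @export
build_atlas <- function(subjects, combination = c("median", "mean"),
                        cfg = reg_config(), outer_iters = 4L, seed = cfg$seed,
                        sharpen_alpha = 0.3, id = NULL) {
  combination <- match.arg(combination)
  bt <- build_template(subjects, combination, cfg, outer_iters, seed,
                       sharpen_alpha)
  labs <- lapply(subjects, function(s) {
    if (is.null(s$labels)) af_stop("all subjects need label images", "argument")
    s$labels
  })
  fused <- fuse_labels(labs, bt$transforms, bt$template)
  atlas(bt$template, fused, combination, length(subjects),
        provenance = list(
          id = if (is.null(id)) sprintf("groupwise_%s_n%d", combination,
                                        length(subjects)) else id,
          subjects = vapply(subjects, function(s) s$id, character(1)),
          reference_index = bt$reference_index, seed = seed,
          outer_iters = outer_iters, config = unclass(cfg)))
}

#' Register a subject onto an atlas
#'
#' Rigid mutual-information alignment followed by symmetric diffeomorphic
#' refinement with local cross-correlation — one registration whose forward
#' direction serves the registration task (subject into atlas space) and
#' whose inverse serves the segmentation task (atlas labels into subject
#' space).
#'
#' @param atl an [atlas()] (or anything with a `$template` scalar image).
#' @param subject a [subject_brain()].
#' @param cfg a [reg_config()].
#' @return A [diffeo_transform()] with the rigid stage as `pre_rigid`.
#' @export
register_subject <- function(atl, subject, cfg = reg_config()) {
  rt <- rigid_register(subject$intensity, atl$template, cfg)
  diffeo_register(subject$intensity, atl$template, cfg, init = rt)
}

otsu_threshold <- function(values, nbins = 256L) {
  h <- tabulate(cut(values, breaks = nbins, labels = FALSE), nbins)
  p <- h / sum(h)
  mids <- seq(min(values), max(values), length.out = nbins + 1L)
  mids <- (mids[-1] + mids[-length(mids)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Equivalent spherical radius of a template's foreground
#'
#' Radius of the sphere whose volume equals the thresholded foreground volume
#' `V` (voxel count above threshold times voxel volume): `(3 V / 4 pi)^(1/3)`.
#' Used to normalise trace distances across templates of different sizes.
#'
#' @param img a `scalar_image`.
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param threshold threshold value when `threshold_method = "fixed"`.
#' @return Radius in micrometres.
#' @export
equivalent_spherical_radius <- function(img,
                                        threshold_method = c("otsu", "fixed"),
                                        threshold = NULL) {
  threshold_method <- match.arg(threshold_method)
  v <- as.numeric(img$values)
  thr <- if (threshold_method == "fixed") {
    if (is.null(threshold)) af_stop("`threshold` required for fixed method", "argument")
    threshold
  } else {
    if (sd(v) == 0) af_stop("cannot Otsu-threshold a constant image", "degenerate")
    otsu_threshold(v)
  }
  vol <- sum(v > thr) * voxel_volume(img)
  if (vol <= 0) af_stop("no foreground voxels above threshold", "degenerate")
  (3 * vol / (4 * pi))^(1 / 3)
}

#' Save an atlas bundle to a directory
#'
#' Writes `template.nii.gz`, `labels.nii.gz` and `provenance.json`.
#' @param atl an [atlas()].
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_atlas <- function(atl, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(atl$template, file.path(dir, "template.nii.gz"))
  write_volume(atl$labels, file.path(dir, "labels.nii.gz"))
  prov <- atl$provenance
  prov$combination <- atl$combination
  prov$n_subjects <- atl$n_subjects
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load an atlas bundle written by [write_atlas()]
#' @param dir directory holding the bundle.
#' @return An [atlas()].
#' @export
read_atlas <- function(dir) {
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"),
                              simplifyVector = TRUE)
  atlas(read_volume(file.path(dir, "template.nii.gz"), "intensity"),
        read_volume(file.path(dir, "labels.nii.gz"), "label"),
        combination = prov$combination,
        n_subjects = prov$n_subjects,
        provenance = prov[setdiff(names(prov), c("combination", "n_subjects"))])
}
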