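#' Phantom population configuration
#'
#' Describes the synthetic brain population the generator emulates: a shared
#' labelled anatomy (14 neuropil-like regions: 5 bilateral pairs and 4
#' midline bodies) perturbed per subject by a random smooth diffeomorphism,
#' a small affine jitter, a group-wise size factor (sexual size dimorphism),
#' and intensity bias plus noise.
#'
#' @param dims grid size, default `c(64, 64, 48)`.
#' @param spacing voxel spacing in micrometres, default `c(1.2, 1.2, 1.1)`
#'   (the working resolution of downsampled confocal stacks).
#' @param n_regions number of anatomical regions (only 14 is supported; the
#'   argument exists to record the convention).
#' @param warp_amplitude maximum displacement of the per-subject random
#'   diffeomorphism, micrometres.
#' @param warp_smoothness Gaussian sigma (voxels) of the velocity field.
#' @param affine_jitter list with `rot_deg` (max rotation, degrees),
#'   `trans_vox` (max translation, voxels), `scale` (scalar jitter range).
#' @param group_scale named numeric vector of linear size factors per group.
#' @param noise_sd additive Gaussian noise, as a fraction of dynamic range.
#' @param bias_amplitude amplitude of the smooth multiplicative bias field.
#' @param seed integer seed controlling everything the generator draws.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(dims = c(64L, 64L, 48L), spacing = c(1.2, 1.2, 1.1),
                           n_regions = 14L, warp_amplitude = 3,
                           warp_smoothness = 8,
                           affine_jitter = list(rot_deg = 4, trans_vox = 1.5,
                                                scale = c(0.98, 1.02)),
                           group_scale = c(female = 1.05, male = 0.95),
                           noise_sd = 0.02, bias_amplitude = 0.05,
                           seed = 1L) {
  if (any(dims < 32L)) {
    af_stop("grid too small to place the anatomy (need >= 32 voxels per axis)",
            "config")
  }
  if (warp_amplitude < 0 || warp_smoothness <= 0) {
    af_stop("warp amplitude must be >= 0 and smoothness > 0", "config")
  }
  if (any(group_scale <= 0)) af_stop("group scale factors must be > 0", "config")
  if (n_regions != 14L) {
    af_stop("the phantom anatomy defines exactly 14 regions", "config")
  }
  structure(
    list(dims = as.integer(dims), spacing = check_triple(spacing, "spacing", TRUE),
         n_regions = 14L, warp_amplitude = warp_amplitude,
         warp_smoothness = warp_smoothness, affine_jitter = affine_jitter,
         group_scale = group_scale, noise_sd = noise_sd,
         bias_amplitude = bias_amplitude, seed = as.integer(seed)),
    class = "phantom_config"
  )
}

#' Region table of the phantom anatomy
#'
#' Centres and semi-axes are expressed as fractions of the brain-envelope
#' semi-axes; bilateral structures appear as left/right mirror pairs about
#' the mid-sagittal plane.
#' @return A tibble with label ids, names and ellipsoid parameters.
#' @keywords internal
phantom_regions <- function() {
  bilateral <- function(name, cx, cy, cz, sx, sy, sz) {
    list(list(name = paste0(name, "_L"), c = c(-cx, cy, cz), s = c(sx, sy, sz)),
         list(name = paste0(name, "_R"), c = c(cx, cy, cz), s = c(sx, sy, sz)))
  }
  regions <- c(
    bilateral("medulla", 0.60, 0.00, 0.00, 0.28, 0.45, 0.50),
    bilateral("lobula", 0.30, -0.35, 0.10, 0.13, 0.18, 0.22),
    bilateral("lobula_plate", 0.30, 0.35, 0.10, 0.13, 0.18, 0.22),
    bilateral("mushroom_body", 0.22, 0.05, 0.45, 0.11, 0.25, 0.30),
    bilateral("antennal_lobe", 0.22, -0.60, -0.35, 0.14, 0.20, 0.22),
    list(list(name = "ellipsoid_body", c = c(0, 0.05, 0.00), s = c(0.11, 0.11, 0.13)),
         list(name = "noduli", c = c(0, -0.10, -0.22), s = c(0.07, 0.07, 0.08)),
         list(name = "fan_shaped_body", c = c(0, 0.05, 0.22), s = c(0.18, 0.11, 0.12)),
         list(name = "protocerebral_bridge", c = c(0, 0.45, 0.30), s = c(0.30, 0.08, 0.08)))
  )
  regions
}

envelope_geometry <- function(cfg) {
  extent <- (cfg$dims - 1) * cfg$spacing
  center <- extent / 2
  semi <- 0.46 * extent
  list(center = center, semi = semi)
}

#' Generate the phantom reference brain
#'
#' Builds the shared anatomy every phantom subject is deformed from: a
#' brain-shaped envelope holding the 14 parameterised neuropil-like regions,
#' each with a distinct base intensity and a smooth deterministic texture,
#' with crisp boundaries between regions. Deterministic given `cfg$seed`.
#'
#' @param cfg a [phantom_config()].
#' @return A list with elements `intensity` (`scalar_image`) and `labels`
#'   (`label_image` with 0 background + 14 regions).
#' @export
make_reference <- function(cfg = phantom_config()) {
  env <- envelope_geometry(cfg)
  # normalised coordinates in the envelope frame, range ~[-1, 1]
  grid <- world_coords(scalar_image(array(0, cfg$dims), cfg$spacing))
  u <- sweep(sweep(grid, 2, env$center, "-"), 2, env$semi, "/")
  r2_env <- rowSums(u^2 / c(1, 1, 1))
  inside <- rowSums(u^2) <= 1
  labels <- integer(nrow(u))
  regions <- phantom_regions()
  names_vec <- character(length(regions))
  for (k in seq_along(regions)) {
    rg <- regions[[k]]
    names_vec[k] <- rg$name
    q <- sweep(u, 2, rg$c, "-")
    in_rg <- rowSums(sweep(q, 2, rg$s, "/")^2) <= 1 & inside & labels == 0L
    if (!any(in_rg)) af_stop("region placement overflowed the envelope", "config")
    labels[in_rg] <- k
  }
  set.seed(cfg$seed)
  phase <- runif(3, 0, 2 * pi)
  texture <- 1 + 0.08 * sin(2 * pi * u[, 1] * 1.5 + phase[1]) *
    sin(2 * pi * u[, 2] * 1.3 + phase[2]) * sin(2 * pi * u[, 3] * 1.1 + phase[3])
  base <- numeric(nrow(u))
  base[inside] <- 30
  base[labels > 0L] <- 60 + 8 * labels[labels > 0L]
  vals <- base * texture
  img <- gaussian_smooth(scalar_image(array(vals, cfg$dims), cfg$spacing), 0.6)
  img$values[img$values < 0] <- 0
  lab <- label_image(array(labels, cfg$dims), cfg$spacing,
                     region_names = stats::setNames(names_vec, seq_along(regions)))
  list(intensity = img, labels = lab)
}

#' Random diffeomorphism with an exact inverse
#'
#' Draws a Gaussian-smoothed random stationary velocity field scaled to a
#' maximum magnitude of `cfg$warp_amplitude` micrometres and exponentiates it
#' by scaling and squaring (at least 6 squarings). The inverse is the
#' exponential of the negated velocity, so forward and inverse are consistent
#' to well below a twentieth of a voxel.
#'
#' @param cfg a [phantom_config()].
#' @param seed integer seed for the velocity draw.
#' @param amplitude optional override of `cfg$warp_amplitude` (um).
#' @return A [diffeo_transform()] whose forward/inverse fields live on the
#'   phantom grid.
#' @export
random_diffeo <- function(cfg = phantom_config(), seed = cfg$seed,
                          amplitude = cfg$warp_amplitude) {
  d <- cfg$dims
  n <- prod(d)
  like <- displacement_field(array(0, c(d, 3)), cfg$spacing)
  if (amplitude <= 0) {
    return(diffeo_transform(like, like, metadata = list(kind = "svf")))
  }
  set.seed(seed)
  v <- matrix(rnorm(n * 3), n, 3)
  v <- smooth_field_mat(v, d, cfg$warp_smoothness)
  mx <- max(sqrt(rowSums(v^2)))
  v <- v * (amplitude / mx)
  n_sq <- max(6L, ceiling(log2(amplitude / (0.25 * min(cfg$spacing)) + 1)))
  exp_field <- function(vel) {
    u <- matrix_field(vel / 2^n_sq, like)
    for (i in seq_len(n_sq)) u <- compose_fields(u, u)
    u
  }
  diffeo_transform(exp_field(v), exp_field(-v),
                   metadata = list(kind = "svf", squarings = n_sq))
}

# Ground-truth affine: sampling map A(x) = center + R (x - center) / scale + t.
# scale > 1 enlarges the subject relative to the reference.
true_affine_map <- function(aff, pts) {
  sweep(sweep(pts, 2, aff$center, "-") %*% t(aff$rotation) / aff$scale, 2,
        aff$center + aff$translation, "+")
}

true_affine_inverse <- function(aff, pts) {
  sweep(pts, 2, aff$center + aff$translation, "-") %*% aff$rotation * aff$scale +
    matrix(aff$center, nrow(pts), 3, byrow = TRUE)
}

#' Map reference-space points into a phantom subject
#'
#' Applies the recorded ground-truth transform of one subject so that points
#' follow the image content (the same sense as [map_points()]).
#'
#' @param gt one element of the population's `ground_truth$subjects` list.
#' @param pts n x 3 matrix, `trace`, or list of traces in reference space.
#' @return Points mapped into the subject's space.
#' @export
true_map_to_subject <- function(gt, pts) {
  if (inherits(pts, "trace")) {
    return(trace_polyline(true_map_to_subject(gt, pts$points), pts$id))
  }
  if (is.list(pts)) return(lapply(pts, function(p) true_map_to_subject(gt, p)))
  p <- true_affine_inverse(gt$affine, as.matrix(pts))
  p + sample_field(gt$diffeo$inverse, p)
}

#' A phantom subject brain
#' @param intensity `scalar_image` reference-stain channel.
#' @param labels optional `label_image` on the same grid.
#' @param traces optional list of `trace`s.
#' @param group group tag (e.g. `"female"`).
#' @param id identifier.
#' @return An object of class `subject_brain`.
#' @export
subject_brain <- function(intensity, labels = NULL, traces = NULL,
                          group = "none", id = "subject") {
  if (!is.null(labels)) assert_same_grid(intensity, labels, "intensity and labels")
  structure(list(intensity = intensity, labels = labels, traces = traces,
                 group = group, id = id),
            class = "subject_brain")
}

#' Sample a phantom population with recorded ground truth
#'
#' Each subject is the reference anatomy pulled through a composite
#' ground-truth transform (group-scaled affine jitter composed with a random
#' smooth diffeomorphism), with labels warped nearest-neighbour and intensity
#' perturbed by a smooth multiplicative bias field plus Gaussian noise.
#' When `splits` is given, subjects are assigned to the named splits
#' (stratified by group) and the assignment is redrawn until the splits'
#' mean brain volumes agree within 5%, so template and test sets have
#' comparable volume distributions.
#'
#' @param cfg a [phantom_config()].
#' @param n number of subjects.
#' @param groups group tags cycled over subjects, default
#'   `c("female", "male")` (alternating sexes).
#' @param traces optional list of reference-space `trace`s copied into every
#'   subject through its ground-truth transform.
#' @param splits optional named integer vector (summing to `n`) of split
#'   sizes, e.g. `c(template = 10, test = 12)`.
#' @return An object of class `phantom_population`: list with `subjects`
#'   (list of [subject_brain()]s, each carrying a `split` attribute when
#'   splits were requested), `reference`, `ground_truth`, and `cfg`.
#' @export
sample_population <- function(cfg = phantom_config(), n = 10L,
                              groups = c("female", "male"), traces = NULL,
                              splits = NULL) {
  if (n < 1L) af_stop("`n` must be >= 1", "argument")
  ref <- make_reference(cfg)
  grid_pts <- world_coords(ref$intensity)
  env <- envelope_geometry(cfg)
  dyn_range <- max(ref$intensity$values)
  set.seed(cfg$seed)
  subject_seeds <- sample.int(2^30, n)
  subjects <- vector("list", n)
  gts <- vector("list", n)
  volumes <- numeric(n)
  group_tags <- groups[(seq_len(n) - 1L) %% length(groups) + 1L]
  for (i in seq_len(n)) {
    set.seed(subject_seeds[i])
    aj <- cfg$affine_jitter
    ang <- runif(3, -1, 1) * aj$rot_deg * pi / 180
    tr <- runif(3, -1, 1) * aj$trans_vox * cfg$spacing
    sc <- cfg$group_scale[[group_tags[i]]] * runif(1, aj$scale[1], aj$scale[2])
    aff <- list(rotation = rigid_from_angles(ang)$rotation, scale = sc,
                translation = tr, center = env$center)
    dif <- random_diffeo(cfg, seed = subject_seeds[i] + 1L)
    # subject(x) = reference(A(x + d(x)))
    pts <- grid_pts + field_matrix(dif$forward)
    pts <- true_affine_map(aff, pts)
    ivals <- sample_image(ref$intensity, pts, "linear")
    lvals <- sample_image(ref$labels, pts, "nearest")
    if (cfg$bias_amplitude > 0 || cfg$noise_sd > 0) {
      raw <- cpp_gauss3(rnorm(length(ivals)), cfg$dims, rep(10, 3))
      bias <- 1 + cfg$bias_amplitude * raw / max(1e-12, max(abs(raw)))
      ivals <- ivals * bias + rnorm(length(ivals), 0, cfg$noise_sd * dyn_range)
      ivals[ivals < 0] <- 0
    }
    img <- scalar_image(array(ivals, cfg$dims), cfg$spacing)
    lab <- label_image(array(as.integer(round(lvals)), cfg$dims), cfg$spacing,
                       region_names = ref$labels$region_names)
    gt_i <- list(affine = aff, diffeo = dif, seed = subject_seeds[i])
    subj_traces <- if (!is.null(traces)) true_map_to_subject(gt_i, traces) else NULL
    subjects[[i]] <- subject_brain(img, lab, subj_traces, group_tags[i],
                                   sprintf("%s_%02d", substr(group_tags[i], 1, 1), i))
    gts[[i]] <- gt_i
    volumes[i] <- sum(lab$values > 0L) * voxel_volume(lab)
  }
  if (!is.null(splits)) {
    if (sum(splits) != n) af_stop("`splits` must sum to `n`", "argument")
    assignment <- balance_splits(splits, group_tags, volumes, cfg$seed)
    for (i in seq_len(n)) subjects[[i]]$split <- assignment[i]
  }
  structure(
    list(subjects = subjects, reference = ref,
         ground_truth = list(reference = ref, subjects = gts), cfg = cfg),
    class = "phantom_population"
  )
}

# Stratified split assignment, redrawn until split mean volumes agree to 5%.
balance_splits <- function(splits, group_tags, volumes, seed) {
  set.seed(seed + 7L)
  split_names <- rep(names(splits), splits)
  for (attempt in seq_len(100L)) {
    assignment <- character(length(group_tags))
    pool <- split_names
    # deal subjects group by group, keeping split proportions within groups
    for (g in unique(group_tags)) {
      idx <- which(group_tags == g)
      take <- sample(pool, length(idx))
      assignment[idx] <- take
      for (t in take) pool <- pool[-match(t, pool)]
    }
    means <- tapply(volumes, assignment, mean)
    if (length(means) < 2L ||
        (max(means) - min(means)) / mean(volumes) < 0.05) {
      return(assignment)
    }
  }
  af_stop("could not balance split volumes within 5% after 100 redraws",
          "config")
}

#' Generate smooth reference-space traces
#'
#' Draws tube-like composite Bezier polylines (arc length 30-120 um, resampled
#' at ~1 um steps) lying inside the phantom brain envelope, emulating manually
#' traced axonal projections. Deterministic given `seed`.
#'
#' @param cfg a [phantom_config()].
#' @param n_traces number of traces (>= 1).
#' @param seed integer seed.
#' @return List of `trace` objects in reference space.
#' @export
make_traces <- function(cfg = phantom_config(), n_traces = 3L,
                        seed = cfg$seed) {
  if (n_traces < 1L) af_stop("`n_traces` must be >= 1", "argument")
  env <- envelope_geometry(cfg)
  set.seed(seed)
  inside_env <- function(p) {
    all(rowSums(sweep(sweep(p, 2, env$center, "-"), 2, env$semi, "/")^2) <= 0.9)
  }
  out <- vector("list", n_traces)
  tt <- seq(0, 1, length.out = 200)
  bezier <- function(ctrl) {
    outer((1 - tt)^3, ctrl[1, ]) + outer(3 * tt * (1 - tt)^2, ctrl[2, ]) +
      outer(3 * tt^2 * (1 - tt), ctrl[3, ]) + outer(tt^3, ctrl[4, ])
  }
  arc_len <- function(p) sum(sqrt(rowSums(diff(p)^2)))
  draw_ctrl <- function() {
    # control points uniform in the 0.85-scaled envelope: the Bezier curve
    # stays inside their convex hull, hence inside the brain
    ctrl <- matrix(0, 4, 3)
    for (j in 1:4) {
      repeat {
        u <- runif(3, -0.85, 0.85)
        if (sum((u / 0.85)^2) <= 1) break
      }
      ctrl[j, ] <- env$center + u * env$semi
    }
    ctrl
  }
  for (i in seq_len(n_traces)) {
    best <- NULL
    for (attempt in seq_len(60L)) {
      ctrl <- draw_ctrl()
      p <- bezier(ctrl)
      len <- arc_len(p)
      if (len < 30) {
        # stretch about the centroid, clamped so the curve stays inside
        centroid <- colMeans(ctrl)
        for (s in c(30 / len * 1.05, 1.6, 1.3)) {
          cand <- sweep(sweep(ctrl, 2, centroid, "-") * s, 2, centroid, "+")
          pc <- bezier(cand)
          if (inside_env(pc)) { p <- pc; len <- arc_len(pc); break }
        }
      }
      if (len >= 30 && len <= 120 && inside_env(p)) { best <- p; break }
      if (is.null(best) && inside_env(p)) best <- p
    }
    pts <- resample_polyline(best, 1.0)
    out[[i]] <- trace_polyline(pts, sprintf("trace_%02d", i))
  }
  out
}

# Resample a polyline to uniform arc-length spacing (um).
resample_polyline <- function(p, step) {
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total < step) return(p[c(1, nrow(p)), , drop = FALSE])
  targets <- seq(0, total, by = step)
  if (targets[length(targets)] < total) targets <- c(targets, total)
  cbind(stats::approx(s, p[, 1], xout = targets)$y,
        stats::approx(s, p[, 2], xout = targets)$y,
        stats::approx(s, p[, 3], xout = targets)$y)
}
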