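#' Registration configuration
#'
#' Bundles every knob of the native registration engine. The symmetric
#' diffeomorphic stage follows a greedy midpoint scheme: both images are
#' warped toward a common midpoint, a local cross-correlation force field is
#' computed, smoothed with `sigma_update` (fluid-like regularisation), capped
#' at `step` voxels per iteration, accumulated by composition, and the total
#' field is smoothed with `sigma_total` (diffusion-like regularisation).
#' A step cap of at most 0.4 voxel preserves invertibility of each incremental
#' map, hence of the composed transform.
#'
#' @param levels number of resolution levels in the coarse-to-fine pyramid.
#' @param iterations integer vector of per-level iteration counts, coarsest
#'   first (recycled to `levels`).
#' @param mi_bins joint-histogram bins for mutual information.
#' @param cc_radius cubic window half-width (voxels) for local
#'   cross-correlation.
#' @param sigma_update Gaussian sigma (voxels) smoothing each update force.
#' @param sigma_total Gaussian sigma (voxels) smoothing the accumulated field.
#' @param step per-iteration update cap in voxels; must be <= 0.4.
#' @param update_rule `"max"` (default) rescales the whole force field so its
#'   peak magnitude equals `step` voxels; `"local"` advances every voxel with
#'   appreciable force by up to `step` voxels (unit-flow normalisation,
#'   faster but noisier).
#' @param seed integer seed for any seeded choice made by callers.
#' @return An object of class `reg_config`.
#' @export
reg_config <- function(levels = 4L, iterations = c(60L, 40L, 25L, 12L),
                       mi_bins = 32L, cc_radius = 3L, sigma_update = 3,
                       sigma_total = 0.5, step = 0.25,
                       update_rule = c("max", "local"), seed = 1L) {
  update_rule <- match.arg(update_rule)
  if (levels < 1L) af_stop("`levels` must be >= 1", "config")
  if (step > 0.4) {
    af_stop("`step` must be <= 0.4 voxel to preserve diffeomorphisms", "config")
  }
  if (mi_bins < 2L) af_stop("`mi_bins` must be >= 2", "config")
  if (cc_radius < 1L) af_stop("`cc_radius` must be >= 1", "config")
  structure(
    list(levels = as.integer(levels),
         iterations = rep_len(as.integer(iterations), levels),
         mi_bins = as.integer(mi_bins), cc_radius = as.integer(cc_radius),
         sigma_update = sigma_update, sigma_total = sigma_total,
         step = step, update_rule = update_rule, seed = as.integer(seed)),
    class = "reg_config"
  )
}

#' Symmetric diffeomorphic transform
#'
#' Pairs the forward and inverse dense displacement fields estimated by
#' [diffeo_register()], plus the rigid pre-transform when one was used. With
#' rigid map `T` and forward field `u`, the moving image warped onto the fixed
#' grid is `moving(T(x + u(x)))`; the inverse field realises the mirrored map.
#'
#' @param forward,inverse `displacement_field`s on the fixed grid.
#' @param pre_rigid optional `rigid_transform` applied after the field offset.
#' @param metadata list of per-level diagnostics.
#' @return An object of class `diffeo_transform`.
#' @export
diffeo_transform <- function(forward, inverse, pre_rigid = NULL,
                             metadata = list()) {
  structure(list(forward = forward, inverse = inverse, pre_rigid = pre_rigid,
                 metadata = metadata),
            class = "diffeo_transform")
}

#' @export
print.diffeo_transform <- function(x, ...) {
  m <- sqrt(rowSums(field_matrix(x$forward)^2))
  cat(sprintf("<diffeo_transform> mean |u| = %.3f um, max |u| = %.3f um%s\n",
              mean(m), max(m),
              if (is.null(x$pre_rigid)) "" else ", with rigid pre-transform"))
  invisible(x)
}

# ---- similarity metrics -----------------------------------------------------

#' Mutual information between two intensity images
#'
#' Shannon mutual information (nats) of the joint intensity histogram.
#' Intensities are clipped to their 0.5-99.5 percentile range per image
#' before binning, for robustness against hot pixels.
#'
#' @param a,b `scalar_image`s on the same grid.
#' @param bins number of bins per axis of the joint histogram.
#' @return Mutual information in nats (>= 0).
#' @export
mutual_information <- function(a, b, bins = 32L) {
  assert_same_grid(a, b)
  if (bins < 2L) af_stop("`bins` must be >= 2", "argument")
  mi_core(as.numeric(a$values), as.numeric(b$values), bins)
}

mi_core <- function(av, bv, bins) {
  ra <- quantile(av, c(0.005, 0.995), names = FALSE)
  rb <- quantile(bv, c(0.005, 0.995), names = FALSE)
  if (ra[1] == ra[2] || rb[1] == rb[2]) return(0)
  h <- cpp_joint_hist(av, bv, bins, ra[1], ra[2], rb[1], rb[2])
  p <- h / sum(h)
  px <- rowSums(p)
  py <- colSums(p)
  nz <- p > 0
  outer_p <- outer(px, py)
  max(0, sum(p[nz] * log(p[nz] / outer_p[nz])))
}

#' Local (windowed) cross-correlation
#'
#' Mean over voxels of the squared local correlation coefficient
#' `cov(a, b)^2 / (var(a) var(b))` computed in cubic windows of half-width
#' `radius` voxels. Windows where either image is locally flat contribute 0.
#' The score lies in `[0, 1]` and is invariant under affine intensity
#' rescaling of either image.
#'
#' @param a,b `scalar_image`s on the same grid.
#' @param radius window half-width in voxels (>= 1).
#' @return Mean squared local correlation in `[0, 1]`.
#' @export
local_cross_correlation <- function(a, b, radius = 3L) {
  assert_same_grid(a, b)
  if (radius < 1L) af_stop("`radius` must be >= 1", "argument")
  d <- img_dims(a)
  st <- cc_stats(as.numeric(a$values), as.numeric(b$values), d, radius)
  mean(cc_value(st))
}

# Windowed central moments via box sums: returns list with centred A, B, C
# (cross/auto covariance sums) plus centred residual arrays.
cc_stats <- function(av, bv, dims, radius) {
  n <- cpp_boxsum3(rep(1, length(av)), dims, radius)
  sa <- cpp_boxsum3(av, dims, radius)
  sb <- cpp_boxsum3(bv, dims, radius)
  saa <- cpp_boxsum3(av * av, dims, radius)
  sbb <- cpp_boxsum3(bv * bv, dims, radius)
  sab <- cpp_boxsum3(av * bv, dims, radius)
  ma <- sa / n
  mb <- sb / n
  list(A = sab - ma * sb, B = pmax(saa - ma * sa, 0), C = pmax(sbb - mb * sb, 0),
       ra = av - ma, rb = bv - mb)
}

cc_value <- function(st, eps = 1e-8) {
  denom <- st$B * st$C
  ifelse(denom > eps, pmin(st$A^2 / pmax(denom, eps), 1), 0)
}

# ---- pyramid ----------------------------------------------------------------

pyramid_shrink <- function(img) {
  sm <- gaussian_smooth(img, 1.0)
  d <- img_dims(img)
  ix <- seq(1L, d[1], by = 2L)
  iy <- seq(1L, d[2], by = 2L)
  iz <- seq(1L, d[3], by = 2L)
  scalar_image(sm$values[ix, iy, iz, drop = FALSE], img$spacing * 2, img$origin)
}

build_pyramid <- function(img, levels) {
  pyr <- vector("list", levels)
  pyr[[levels]] <- img
  if (levels > 1L) {
    for (l in rev(seq_len(levels - 1L))) {
      cand <- pyramid_shrink(pyr[[l + 1L]])
      if (any(img_dims(cand) < 4L)) cand <- pyr[[l + 1L]]  # floor at 4 voxels
      pyr[[l]] <- cand
    }
  }
  pyr
}

# ---- rigid registration -----------------------------------------------------

rigid_from_params <- function(theta, center) {
  rigid_from_angles(theta[1:3], theta[4:6], center)
}

resample_rigid <- function(moving, fixed, rt) {
  pts <- apply_rigid(rt, world_coords(fixed))
  scalar_image(array(sample_image(moving, pts, "linear"), img_dims(fixed)),
               fixed$spacing, fixed$origin)
}

#' Rigid registration by mutual-information ascent
#'
#' Finds the rigid transform (rotation + translation about the fixed-image
#' centre) maximising mutual information between the fixed image and the
#' resampled moving image, by multi-resolution coordinate descent with a
#' fixed, deterministic step-halving schedule.
#'
#' @param moving,fixed non-constant `scalar_image`s.
#' @param cfg a [reg_config()].
#' @return A `rigid_transform` mapping fixed-space points into moving space
#'   (backward mapping, suitable for resampling `moving` onto `fixed`).
#' @export
rigid_register <- function(moving, fixed, cfg = reg_config()) {
  for (im in list(moving, fixed)) {
    if (sd(im$values) == 0) {
      af_stop("cannot rigidly register a constant image", "degenerate")
    }
  }
  d <- img_dims(fixed)
  center <- fixed$origin + (d - 1) / 2 * fixed$spacing
  pyr_f <- build_pyramid(fixed, cfg$levels)
  pyr_m <- build_pyramid(moving, cfg$levels)
  theta <- rep(0, 6)
  for (l in seq_len(cfg$levels)) {
    f <- pyr_f[[l]]
    m <- pyr_m[[l]]
    frange <- quantile(f$values, c(0.005, 0.995), names = FALSE)
    mrange <- quantile(m$values, c(0.005, 0.995), names = FALSE)
    obj <- function(th) {
      rt <- rigid_from_params(th, center)
      cpp_mi_rigid(as.numeric(m$values), img_dims(m), m$spacing, m$origin,
                   as.numeric(f$values), img_dims(f), f$spacing, f$origin,
                   rt$rotation, rt$translation, rt$center, cfg$mi_bins,
                   frange, mrange)
    }
    step_r <- 0.06
    step_t <- 1.0 * min(f$spacing)
    tol_r <- 0.3 * pi / 180
    tol_t <- 0.12 * min(f$spacing)
    best <- obj(theta)
    while (step_r > tol_r || step_t > tol_t) {
      improved <- FALSE
      for (p in seq_len(6L)) {
        stp <- if (p <= 3L) step_r else step_t
        if ((p <= 3L && step_r <= tol_r) || (p > 3L && step_t <= tol_t)) next
        for (dir in c(1, -1)) {
          cand <- theta
          cand[p] <- cand[p] + dir * stp
          v <- obj(cand)
          while (v > best + 1e-9) {
            theta <- cand
            best <- v
            improved <- TRUE
            cand[p] <- cand[p] + dir * stp
            v <- obj(cand)
          }
        }
      }
      if (!improved) {
        step_r <- step_r / 2
        step_t <- step_t / 2
      }
    }
  }
  rigid_from_params(theta, center)
}

# ---- field algebra ----------------------------------------------------------

sample_field <- function(field, pts) {
  d <- dim(field$vectors)[1:3]
  idx <- sweep(sweep(pts, 2, field$origin, "-"), 2, field$spacing, "/")
  n <- prod(d)
  v <- matrix(field$vectors, n, 3)
  cbind(cpp_sample_linear(v[, 1], d, idx),
        cpp_sample_linear(v[, 2], d, idx),
        cpp_sample_linear(v[, 3], d, idx))
}

#' Compose two displacement fields
#'
#' Returns the field of the composite map `x -> x + g(x) + f(x + g(x))`, i.e.
#' the pull-back composition where `g` is applied first when sampling
#' (outermost in the chain of point maps).
#'
#' @param f,g `displacement_field`s on compatible grids.
#' @return The composed `displacement_field` on `g`'s grid.
#' @export
compose_fields <- function(f, g) {
  pts <- world_coords(g) + field_matrix(g)
  matrix_field(field_matrix(g) + sample_field(f, pts), g)
}

#' Invert a displacement field by fixed-point iteration
#'
#' Solves `u(x) = -f(x + u(x))` with at most `max_iter` sweeps, stopping when
#' the mean composition residual drops below `tol_vox` voxels.
#'
#' @param f a `displacement_field` whose displacements stay inside the domain.
#' @param max_iter iteration budget.
#' @param tol_vox convergence tolerance in voxels (mean residual).
#' @return The inverse `displacement_field`.
#' @export
invert_field <- function(f, max_iter = 30L, tol_vox = 0.05) {
  vox <- min(f$spacing)
  x <- world_coords(f)
  u <- matrix(0, nrow(x), 3)
  res <- Inf
  for (it in seq_len(max_iter)) {
    u_new <- -sample_field(f, x + u)
    u <- u_new
    res_vec <- u + sample_field(f, x + u)
    res <- mean(sqrt(rowSums(res_vec^2))) / vox
    if (res < tol_vox) break
  }
  if (!is.finite(res) || res > 1) {
    af_stop(sprintf("field inversion diverged (residual %.3f voxels)", res),
            "numeric")
  }
  matrix_field(u, f)
}

resample_field <- function(field, like) {
  # Move a displacement field (world-unit vectors) onto another grid.
  pts <- world_coords(like)
  d <- img_dims(like)
  displacement_field(array(sample_field(field, pts), c(d, 3)),
                     like$spacing, like$origin)
}

smooth_field_mat <- function(m, dims, sigma_vox) {
  if (sigma_vox <= 1e-8) return(m)
  s <- rep(sigma_vox, 3)
  cbind(cpp_gauss3(m[, 1], dims, s), cpp_gauss3(m[, 2], dims, s),
        cpp_gauss3(m[, 3], dims, s))
}

# ---- symmetric diffeomorphic registration -----------------------------------

cc_force <- function(fv, mv, grad_m, dims, radius) {
  st <- cc_stats(fv, mv, dims, radius)
  denom <- st$B * st$C
  ok <- denom > 1e-8
  coef <- numeric(length(fv))
  coef[ok] <- 2 * st$A[ok] / denom[ok] *
    (st$ra[ok] - st$A[ok] / st$C[ok] * st$rb[ok])
  grad_m * coef
}

#' Symmetric diffeomorphic registration (local cross-correlation)
#'
#' Estimates a smooth invertible deformation between `fixed` and `moving` by
#' a greedy symmetric midpoint scheme run coarse-to-fine: both images are
#' warped toward the midpoint, the local-CC force is evaluated on each side,
#' smoothed, capped at `cfg$step` voxels, and accumulated by composition; the
#' total half-fields are smoothed with `cfg$sigma_total` after every
#' iteration. The returned forward field maps the fixed grid into moving
#' space; the inverse is built from the mirrored half-path and refined by
#' fixed-point inversion.
#'
#' @param moving,fixed non-constant `scalar_image`s with identical grids
#'   (after the optional rigid initialisation).
#' @param cfg a [reg_config()].
#' @param init optional `rigid_transform` (from [rigid_register()]) applied
#'   to `moving` before the deformable stage and stored as `pre_rigid`.
#' @return A [diffeo_transform()].
#' @export
diffeo_register <- function(moving, fixed, cfg = reg_config(), init = NULL) {
  if (any(!is.finite(moving$values)) || any(!is.finite(fixed$values))) {
    af_stop("images must be finite everywhere", "data")
  }
  if (cfg$step > 0.4) af_stop("`step` must be <= 0.4 voxel", "config")
  moving_r <- if (is.null(init)) moving else resample_rigid(moving, fixed, init)
  assert_same_grid(moving_r, fixed)
  pyr_f <- build_pyramid(fixed, cfg$levels)
  pyr_m <- build_pyramid(moving_r, cfg$levels)
  u1 <- zero_field(pyr_f[[1]])  # half-map: mid grid -> fixed space
  u2 <- zero_field(pyr_f[[1]])  # half-map: mid grid -> moving space
  meta <- list(levels = cfg$levels, iterations = cfg$iterations, cc = numeric(0))
  for (l in seq_len(cfg$levels)) {
    f <- pyr_f[[l]]
    m <- pyr_m[[l]]
    if (!same_grid(f, scalar_image(array(0, dim(u1$vectors)[1:3]),
                                   u1$spacing, u1$origin))) {
      u1 <- resample_field(u1, f)
      u2 <- resample_field(u2, f)
    }
    dims <- img_dims(f)
    x <- world_coords(f)
    cap <- cfg$step * min(f$spacing)
    lev <- cpp_syn_level(as.numeric(f$values), as.numeric(m$values), dims,
                         f$spacing, field_matrix(u1), field_matrix(u2),
                         cfg$iterations[l], cfg$cc_radius, cfg$sigma_update,
                         cfg$sigma_total, cap,
                         as.integer(identical(cfg$update_rule, "local")))
    u1 <- matrix_field(lev$u1, u1)
    u2 <- matrix_field(lev$u2, u2)
    fw <- cpp_sample_linear(as.numeric(f$values), dims, world_to_index(f, x + field_matrix(u1)))
    mw <- cpp_sample_linear(as.numeric(m$values), dims, world_to_index(m, x + field_matrix(u2)))
    st <- cc_stats(fw, mw, dims, cfg$cc_radius)
    meta$cc <- c(meta$cc, mean(cc_value(st)))
  }
  fwd <- compose_fields(u2, invert_field(u1))
  inv <- compose_fields(u1, invert_field(u2))
  diffeo_transform(fwd, inv, pre_rigid = init, metadata = meta)
}

# ---- applying transforms ----------------------------------------------------

#' Resample an image through a diffeomorphic transform
#'
#' `direction = "to_fixed"` pulls a moving-space image onto the fixed grid
#' (the registration direction); `direction = "to_moving"` pulls a
#' fixed-space image (e.g. atlas labels) onto the moving grid via the inverse
#' field (the segmentation direction).
#'
#' @param transform a `diffeo_transform`.
#' @param img `scalar_image` or `label_image` to resample.
#' @param direction `"to_fixed"` or `"to_moving"`.
#' @param grid optional image supplying the output grid for `"to_moving"`
#'   (defaults to the transform's own grid).
#' @return The resampled image (labels keep nearest-neighbour sampling).
#' @export
apply_diffeo <- function(transform, img, direction = c("to_fixed", "to_moving"),
                         grid = NULL) {
  direction <- match.arg(direction)
  method <- if (inherits(img, "label_image")) "nearest" else "linear"
  fld <- transform$forward
  if (direction == "to_fixed") {
    pts <- world_coords(fld) + field_matrix(fld)
    pts <- apply_rigid(transform$pre_rigid, pts)
    out_spacing <- fld$spacing
    out_origin <- fld$origin
    d <- dim(fld$vectors)[1:3]
  } else {
    ref <- if (is.null(grid)) {
      scalar_image(array(0, dim(fld$vectors)[1:3]), fld$spacing, fld$origin)
    } else grid
    pts <- world_coords(ref)
    if (!is.null(transform$pre_rigid)) {
      pts <- apply_rigid(rigid_inverse(transform$pre_rigid), pts)
    }
    pts <- pts + sample_field(transform$inverse, pts)
    out_spacing <- ref$spacing
    out_origin <- ref$origin
    d <- img_dims(ref)
  }
  vals <- sample_image(img, pts, method)
  if (method == "nearest") {
    out <- array(as.integer(round(vals)), d)
    label_image(out, out_spacing, out_origin, img$region_names)
  } else {
    scalar_image(array(vals, d), out_spacing, out_origin)
  }
}

#' Map trace points through a registration
#'
#' Moves world points (e.g. axonal trace nodes living in the moving/subject
#' image) into fixed/template space so that they follow the image content
#' under the registration: the mapping is the inverse of the pull-back warp,
#' `x = Psi(T^{-1}(p))` with `Psi` the inverse displacement map.
#'
#' @param transform a `diffeo_transform` from registering subject (moving)
#'   onto template (fixed).
#' @param pts a `trace`, a list of traces, or an n x 3 point matrix in
#'   subject space.
#' @return The mapped object of the same type.
#' @export
map_points <- function(transform, pts) {
  if (inherits(pts, "trace")) {
    return(trace_polyline(map_points(transform, pts$points), pts$id))
  }
  if (is.list(pts)) return(lapply(pts, function(p) map_points(transform, p)))
  p <- as.matrix(pts)
  if (!is.null(transform$pre_rigid)) {
    p <- apply_rigid(rigid_inverse(transform$pre_rigid), p)
  }
  p + sample_field(transform$inverse, p)
}

#' Jacobian determinant map of a displacement field
#'
#' Finite-difference Jacobian of the map `x + u(x)`; positive values indicate
#' a locally orientation-preserving (fold-free) deformation.
#'
#' @param field a `displacement_field`.
#' @return A `scalar_image` of Jacobian determinants.
#' @export
jacobian_determinant <- function(field) {
  d <- dim(field$vectors)[1:3]
  J <- array(0, c(d, 3, 3))
  for (comp in 1:3) {
    g <- cpp_grad3(as.numeric(field$vectors[, , , comp]), d, field$spacing)
    for (ax in 1:3) J[, , , comp, ax] <- array(g[, ax], d)
  }
  for (ax in 1:3) J[, , , ax, ax] <- J[, , , ax, ax] + 1
  det_v <- J[, , , 1, 1] * (J[, , , 2, 2] * J[, , , 3, 3] - J[, , , 2, 3] * J[, , , 3, 2]) -
           J[, , , 1, 2] * (J[, , , 2, 1] * J[, , , 3, 3] - J[, , , 2, 3] * J[, , , 3, 1]) +
           J[, , , 1, 3] * (J[, , , 2, 1] * J[, , , 3, 2] - J[, , , 2, 2] * J[, , , 3, 1])
  scalar_image(det_v, field$spacing, field$origin)
}
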