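region_mask <- function(labels, region) labels$values == region

assert_region <- function(a, b, region) {
  ina <- any(a$values == region)
  inb <- any(b$values == region)
  if (!ina && !inb) {
    af_stop(sprintf("region %d is absent from both label images", region),
            "region")
  }
  c(ina, inb)
}

#' Dice overlap coefficient for one region
#'
#' `2 |A n B| / (|A| + |B|)` for the voxel sets carrying `region` in each
#' label image. A region present in only one image scores 0; a region absent
#' from both raises an undefined-region error rather than silently returning
#' a value.
#'
#' @param a,b `label_image`s on the same grid.
#' @param region integer label id.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b, region) {
  assert_same_grid(a, b)
  assert_region(a, b, region)
  ma <- region_mask(a, region)
  mb <- region_mask(b, region)
  2 * sum(ma & mb) / (sum(ma) + sum(mb))
}

#' Boundary points of a labelled region
#'
#' World coordinates (voxel centres) of region voxels having at least one
#' 6-connected face neighbour outside the region; voxels on the volume border
#' count as boundary.
#'
#' @param labels a `label_image`.
#' @param region integer label id (must be present).
#' @return An n x 3 matrix of world coordinates (micrometres).
#' @export
boundary_points <- function(labels, region) {
  if (!any(labels$values == region)) {
    af_stop(sprintf("region %d is absent from the label image", region),
            "region")
  }
  m <- region_mask(labels, region)
  interior <- shift_pad(m, 1, 1L) & shift_pad(m, 1, -1L) &
    shift_pad(m, 2, 1L) & shift_pad(m, 2, -1L) &
    shift_pad(m, 3, 1L) & shift_pad(m, 3, -1L)
  boundary <- m & !interior
  world_coords(labels)[as.vector(boundary), , drop = FALSE]
}

# Logical shift with FALSE fill (so the volume border is a region boundary).
shift_pad <- function(m, axis, by) {
  d <- dim(m)
  out <- array(FALSE, d)
  n <- d[axis]
  src <- seq_len(n) + by
  ok <- src >= 1L & src <= n
  if (axis == 1L) out[ok, , ] <- m[src[ok], , , drop = FALSE]
  else if (axis == 2L) out[, ok, ] <- m[, src[ok], , drop = FALSE]
  else out[, , ok] <- m[, , src[ok], drop = FALSE]
  out
}

boundary_pair <- function(a, b, region) {
  present <- assert_region(a, b, region)
  if (!all(present)) {
    af_stop(sprintf("region %d must be present in both images for distances",
                    region), "region")
  }
  list(a = boundary_points(a, region), b = boundary_points(b, region))
}

#' Mean symmetric surface distance for one region
#'
#' Average of the two directed mean distances between region boundaries:
#' for each boundary point of A, the Euclidean distance (world units, so
#' anisotropy-aware) to the closest boundary point of B, averaged; and the
#' mirror quantity; the two means are averaged.
#'
#' @inheritParams dice
#' @return Distance in micrometres (0 for identical regions).
#' @export
mean_symmetric_surface_distance <- function(a, b, region) {
  assert_same_grid(a, b)
  bp <- boundary_pair(a, b, region)
  d_ab <- mean(cpp_min_dists(bp$a, bp$b))
  d_ba <- mean(cpp_min_dists(bp$b, bp$a))
  (d_ab + d_ba) / 2
}

#' Symmetric Hausdorff distance for one region
#'
#' Average of the two directed Hausdorff (max-of-min) boundary distances.
#'
#' @inheritParams dice
#' @return Distance in micrometres.
#' @export
symmetric_hausdorff <- function(a, b, region) {
  assert_same_grid(a, b)
  bp <- boundary_pair(a, b, region)
  h_ab <- max(cpp_min_dists(bp$a, bp$b))
  h_ba <- max(cpp_min_dists(bp$b, bp$a))
  (h_ab + h_ba) / 2
}

#' All three region metrics for a set of regions
#'
#' @param a,b `label_image`s on the same grid.
#' @param regions integer label ids (default: all non-background labels
#'   present in either image).
#' @return A tibble with columns `region`, `dice`, `msd_um`, `hausdorff_um`,
#'   `size_a`, `size_b`. Distances are `NA` when the region is missing from
#'   one of the images.
#' @export
region_metrics <- function(a, b, regions = NULL) {
  assert_same_grid(a, b)
  if (is.null(regions)) {
    regions <- sort(setdiff(union(unique(as.vector(a$values)),
                                  unique(as.vector(b$values))), 0L))
  }
  purrr::map_dfr(regions, function(r) {
    present <- c(any(a$values == r), any(b$values == r))
    d <- if (any(present)) dice(a, b, r) else NA_real_
    if (all(present)) {
      bp <- boundary_pair(a, b, r)
      dab <- cpp_min_dists(bp$a, bp$b)
      dba <- cpp_min_dists(bp$b, bp$a)
      msd <- (mean(dab) + mean(dba)) / 2
      hd <- (max(dab) + max(dba)) / 2
    } else {
      msd <- NA_real_
      hd <- NA_real_
    }
    tibble::tibble(region = r, dice = d, msd_um = msd, hausdorff_um = hd,
                   size_a = sum(a$values == r), size_b = sum(b$values == r))
  })
}

#' Mean symmetric distance between two traces
#'
#' Traces are resampled to uniform ~1 um arc-length spacing, then the mean
#' symmetric nearest-point distance between the two point sets is returned.
#'
#' @param a,b `trace` objects (>= 2 points each).
#' @return Distance in micrometres.
#' @export
trace_distance <- function(a, b) {
  pa <- resample_polyline(a$points, 1.0)
  pb <- resample_polyline(b$points, 1.0)
  (mean(cpp_min_dists(pa, pb)) + mean(cpp_min_dists(pb, pa))) / 2
}

#' Trace distance normalised by a template's equivalent spherical radius
#'
#' Dividing by the radius of the sphere holding the template's foreground
#' volume makes distances comparable across templates of different sizes.
#'
#' @inheritParams trace_distance
#' @param radius equivalent spherical radius in micrometres (> 0).
#' @return Dimensionless normalised distance.
#' @export
normalized_trace_distance <- function(a, b, radius) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0) {
    af_stop("`radius` must be a positive scalar", "argument")
  }
  trace_distance(a, b) / radius
}

#' Masked Dice overlap between two binarised expression patterns
#'
#' Computes the Dice coefficient of `{pattern_a > thr_a}` and
#' `{pattern_b > thr_b}` restricted to the voxels where `mask > 0` — the
#' score behind brush-style spatial queries, where the mask is the drawn
#' search pattern. Binarisation thresholds are explicit; no automatic
#' threshold is applied.
#'
#' @param pattern_a,pattern_b `scalar_image`s on a shared grid.
#' @param mask `label_image` (or 0/1 `scalar_image`) on the same grid;
#'   must be non-empty.
#' @param thr_a,thr_b binarisation thresholds.
#' @return Dice coefficient in `[0, 1]`.
#' @export
masked_overlap <- function(pattern_a, pattern_b, mask, thr_a, thr_b) {
  assert_same_grid(pattern_a, pattern_b)
  assert_same_grid(pattern_a, mask, "patterns and mask")
  inside <- mask$values > 0
  if (!any(inside)) af_stop("`mask` is empty", "argument")
  a <- pattern_a$values > thr_a & inside
  b <- pattern_b$values > thr_b & inside
  if (!any(a) && !any(b)) {
    af_stop("both binarised patterns are empty inside the mask", "overlap")
  }
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Retain spatial-query candidates above an overlap threshold
#'
#' Companion filter to [masked_overlap()]: keeps the candidates whose masked
#' overlap score strictly exceeds `threshold` (default 20% overlap).
#'
#' @param scores named numeric vector of overlap scores.
#' @param threshold retention threshold (default 0.20).
#' @return The retained subset of `scores`, in decreasing order.
#' @export
filter_overlap_candidates <- function(scores, threshold = 0.20) {
  kept <- scores[scores > threshold]
  kept[order(kept, decreasing = TRUE)]
}
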