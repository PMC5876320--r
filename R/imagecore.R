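#' @useDynLib atlasforge, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort
#' @importFrom stats median quantile rnorm runif sd
NULL

af_stop <- function(msg, class) {
  abort(msg, class = c(paste0("af_error_", class), "af_error"))
}

check_triple <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 3L || any(!is.finite(x))) {
    af_stop(sprintf("`%s` must be a finite numeric triple", name), "argument")
  }
  if (positive && any(x <= 0)) {
    af_stop(sprintf("`%s` must be positive in all components", name), "argument")
  }
  as.numeric(x)
}

#' 3D intensity image on a regular anisotropic grid
#'
#' A `scalar_image` stores a 3D array of intensities together with its voxel
#' geometry: spacing in micrometres per voxel along x, y, z and the world
#' position (micrometres) of voxel index `(0, 0, 0)`. World position of voxel
#' index `(i, j, k)` (0-based) is `origin + c(i, j, k) * spacing`.
#'
#' @param values numeric 3D array of voxel intensities.
#' @param spacing positive numeric triple, micrometres per voxel.
#' @param origin numeric triple, world coordinates of the first voxel centre.
#' @return An object of class `scalar_image`.
#' @export
scalar_image <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    af_stop("`values` must be a 3D array", "argument")
  }
  structure(
    list(values = values * 1.0, spacing = check_triple(spacing, "spacing", TRUE),
         origin = check_triple(origin, "origin")),
    class = c("scalar_image", "af_image")
  )
}

#' 3D anatomical label image
#'
#' Like [scalar_image()] but voxel values are non-negative integer region
#' labels (0 = background, 1..K = anatomical regions). An optional
#' `region_names` vector maps label ids to region names.
#'
#' @param values integer 3D array of labels.
#' @inheritParams scalar_image
#' @param region_names optional named character vector (names = label ids).
#' @return An object of class `label_image`.
#' @export
label_image <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        region_names = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    af_stop("`values` must be a 3D array", "argument")
  }
  if (any(values < 0) || any(values != round(values))) {
    af_stop("labels must be non-negative integers", "argument")
  }
  storage.mode(values) <- "integer"
  structure(
    list(values = values, spacing = check_triple(spacing, "spacing", TRUE),
         origin = check_triple(origin, "origin"), region_names = region_names),
    class = c("label_image", "af_image")
  )
}

#' @export
print.af_image <- function(x, ...) {
  kind <- if (inherits(x, "label_image")) "label_image" else "scalar_image"
  d <- dim(x$values)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g um\n",
              kind, d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  if (inherits(x, "label_image")) {
    cat("  labels:", paste(sort(unique(as.vector(x$values))), collapse = " "), "\n")
  } else {
    cat(sprintf("  intensity range [%.4g, %.4g]\n",
                min(x$values), max(x$values)))
  }
  invisible(x)
}

img_dims <- function(img) dim(img$values)

#' Voxel volume of an image grid (cubic micrometres)
#' @param img a `scalar_image` or `label_image`.
#' @return Scalar, product of the spacing components.
#' @export
voxel_volume <- function(img) prod(img$spacing)

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

assert_same_grid <- function(a, b, what = "images") {
  if (!same_grid(a, b)) {
    af_stop(sprintf("%s must share one grid (dims, spacing, origin)", what),
            "geometry")
  }
}

#' World coordinates of every voxel centre
#'
#' @param img an image or displacement field.
#' @return An `n_voxels` x 3 matrix of world coordinates in micrometres,
#'   ordered like the flattened (column-major) value array.
#' @export
world_coords <- function(img) {
  d <- if (inherits(img, "displacement_field")) dim(img$vectors)[1:3]
       else dim(img$values)
  x <- img$origin[1] + img$spacing[1] * (seq_len(d[1]) - 1)
  y <- img$origin[2] + img$spacing[2] * (seq_len(d[2]) - 1)
  z <- img$origin[3] + img$spacing[3] * (seq_len(d[3]) - 1)
  cbind(rep.int(x, d[2] * d[3]),
        rep.int(rep(y, each = d[1]), d[3]),
        rep(z, each = d[1] * d[2]))
}

world_to_index <- function(img, pts) {
  sweep(sweep(pts, 2, img$origin, "-"), 2, img$spacing, "/")
}

#' Sample an image at arbitrary world points
#'
#' Backward-mapping sampler used by all warping operations. Points outside the
#' image domain return the background fill value 0.
#'
#' @param img a `scalar_image` or `label_image`.
#' @param pts n x 3 matrix of world coordinates (micrometres).
#' @param method `"linear"` (trilinear) or `"nearest"`.
#' @return Numeric vector of sampled values.
#' @export
sample_image <- function(img, pts, method = c("linear", "nearest")) {
  method <- match.arg(method)
  idx <- world_to_index(img, pts)
  if (method == "linear") {
    cpp_sample_linear(as.numeric(img$values), dim(img$values), idx)
  } else {
    cpp_sample_nearest(as.numeric(img$values), dim(img$values), idx)
  }
}

# ---- displacement fields and rigid transforms -------------------------------

#' Dense displacement field
#'
#' Stores one world-space displacement vector (micrometres) per voxel of the
#' grid it lives on. Warping is backward mapping: the warped image at world
#' point `x` samples the source image at `x + field(x)` (plus an optional
#' rigid pre-map).
#'
#' @param vectors numeric 4D array `c(nx, ny, nz, 3)` of displacements (um).
#' @inheritParams scalar_image
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(vectors, spacing = c(1, 1, 1),
                               origin = c(0, 0, 0)) {
  if (!is.array(vectors) || length(dim(vectors)) != 4L || dim(vectors)[4] != 3L) {
    af_stop("`vectors` must be a 4D array with last dimension 3", "argument")
  }
  if (any(!is.finite(vectors))) {
    af_stop("displacement field must be finite everywhere", "data")
  }
  structure(
    list(vectors = vectors * 1.0,
         spacing = check_triple(spacing, "spacing", TRUE),
         origin = check_triple(origin, "origin")),
    class = "displacement_field"
  )
}

#' Zero displacement field on an image grid
#' @param img image defining the grid.
#' @return A `displacement_field` of all-zero vectors.
#' @export
zero_field <- function(img) {
  d <- img_dims(img)
  displacement_field(array(0, c(d, 3)), img$spacing, img$origin)
}

field_matrix <- function(field) {
  d <- dim(field$vectors)
  matrix(field$vectors, nrow = prod(d[1:3]), ncol = 3)
}

matrix_field <- function(m, like) {
  d <- dim(like$vectors)[1:3]
  displacement_field(array(m, c(d, 3)), like$spacing, like$origin)
}

#' Rigid transform (rotation + translation about a centre)
#'
#' Maps a world point `x` to `R (x - c) + c + t`. The rotation matrix must be
#' orthonormal with determinant +1.
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation numeric triple (micrometres).
#' @param center numeric triple, rotation centre (micrometres).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9) {
    af_stop("`rotation` must be a proper orthonormal 3x3 matrix", "argument")
  }
  structure(
    list(rotation = rotation, translation = check_triple(translation, "translation"),
         center = check_triple(center, "center")),
    class = "rigid_transform"
  )
}

#' Build a rigid transform from Euler angles
#' @param angles rotation angles about x, y, z in radians (applied z, y, x).
#' @param translation translation triple (um).
#' @param center rotation centre (um).
#' @return A `rigid_transform`.
#' @export
rigid_from_angles <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                              center = c(0, 0, 0)) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  rigid_transform(rx %*% ry %*% rz, translation, center)
}

#' Apply a rigid transform to world points
#' @param rt a `rigid_transform` (or `NULL` for the identity).
#' @param pts n x 3 matrix of world points (um).
#' @return Transformed n x 3 matrix.
#' @export
apply_rigid <- function(rt, pts) {
  if (is.null(rt)) return(pts)
  sweep(sweep(pts, 2, rt$center, "-") %*% t(rt$rotation), 2,
        rt$center + rt$translation, "+")
}

#' Invert a rigid transform
#' @param rt a `rigid_transform`.
#' @return The inverse `rigid_transform` (same centre).
#' @export
rigid_inverse <- function(rt) {
  rigid_transform(t(rt$rotation),
                  -as.vector(t(rt$rotation) %*% rt$translation), rt$center)
}

# ---- warping ----------------------------------------------------------------

warp_core <- function(img, field, rigid, method) {
  pts <- world_coords(field)
  pts <- apply_rigid(rigid, pts) + field_matrix(field)
  vals <- sample_image(img, pts, method)
  d <- dim(field$vectors)[1:3]
  array(vals, d)
}

#' Warp an intensity image through a displacement field
#'
#' Backward mapping with trilinear interpolation: the output at world point
#' `x` is the input sampled at `T(x) + field(x)`, where `T` is an optional
#' rigid pre-transform. Out-of-domain samples are filled with 0 (background).
#'
#' @param img `scalar_image` to resample.
#' @param field `displacement_field` on the output grid.
#' @param rigid optional `rigid_transform` applied before the field offset.
#' @return A `scalar_image` on the field's grid.
#' @export
warp_linear <- function(img, field, rigid = NULL) {
  if (!inherits(img, "scalar_image")) af_stop("`img` must be a scalar_image", "argument")
  scalar_image(warp_core(img, field, rigid, "linear"), field$spacing, field$origin)
}

#' Warp a label image (nearest-neighbour)
#'
#' As [warp_linear()] but with nearest-neighbour sampling, so the output
#' contains only label values present in the input (plus background 0).
#'
#' @param labels `label_image` to resample.
#' @inheritParams warp_linear
#' @return A `label_image` on the field's grid.
#' @export
warp_nearest <- function(labels, field, rigid = NULL) {
  if (!inherits(labels, "label_image")) af_stop("`labels` must be a label_image", "argument")
  out <- warp_core(labels, field, rigid, "nearest")
  storage.mode(out) <- "integer"
  label_image(out, field$spacing, field$origin, labels$region_names)
}

# ---- geometry and filtering --------------------------------------------------

#' Length of the voxel diagonal
#'
#' Euclidean norm of the voxel spacing triple; the conventional yardstick for
#' "sub-voxel" registration accuracy on anisotropic grids.
#'
#' @param spacing positive numeric triple (micrometres per voxel).
#' @return Diagonal length in micrometres.
#' @export
#' @examples
#' voxel_diagonal(c(0.6, 0.6, 1.1)) # ~1.39 um
voxel_diagonal <- function(spacing) {
  spacing <- check_triple(spacing, "spacing", positive = TRUE)
  sqrt(sum(spacing^2))
}

#' Downsample an image along x and y
#'
#' Intensity images are block-averaged over `factor` x `factor` tiles; label
#' images are stride-sampled (taking the first voxel of each tile) so that no
#' fractional or mixed labels can arise. Spacing along x and y is multiplied
#' by `factor`; z is untouched.
#'
#' @param img a `scalar_image` or `label_image`.
#' @param factor positive integer downsampling factor.
#' @return Image of the same kind on the coarser grid.
#' @export
downsample_xy <- function(img, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor)) {
    af_stop("`factor` must be a positive integer", "argument")
  }
  factor <- as.integer(factor)
  d <- img_dims(img)
  if (d[1] < factor || d[2] < factor) {
    af_stop("image too small for requested downsampling factor", "argument")
  }
  new_spacing <- img$spacing * c(factor, factor, 1)
  if (factor == 1L) return(img)
  if (inherits(img, "label_image")) {
    ix <- seq(1L, by = factor, length.out = d[1] %/% factor)
    iy <- seq(1L, by = factor, length.out = d[2] %/% factor)
    vals <- img$values[ix, iy, , drop = FALSE]
    label_image(vals, new_spacing, img$origin, img$region_names)
  } else {
    vals <- cpp_block_mean_xy(as.numeric(img$values), d, factor)
    scalar_image(array(vals, c(d[1] %/% factor, d[2] %/% factor, d[3])),
                 new_spacing, img$origin)
  }
}

shift_arr <- function(a, axis, by) {
  # Shift with edge replication (Neumann boundary).
  d <- dim(a)
  idx <- pmin(pmax(seq_len(d[axis]) + by, 1L), d[axis])
  if (axis == 1L) a[idx, , , drop = FALSE]
  else if (axis == 2L) a[, idx, , drop = FALSE]
  else a[, , idx, drop = FALSE]
}

discrete_laplacian <- function(img) {
  a <- img$values
  s2 <- img$spacing^2
  (shift_arr(a, 1, 1L) - 2 * a + shift_arr(a, 1, -1L)) / s2[1] +
    (shift_arr(a, 2, 1L) - 2 * a + shift_arr(a, 2, -1L)) / s2[2] +
    (shift_arr(a, 3, 1L) - 2 * a + shift_arr(a, 3, -1L)) / s2[3]
}

#' Laplacian sharpening
#'
#' Unsharp-masking step used on mean-combined templates:
#' `out = in - alpha * L(in)` with `L` the 6-neighbour discrete Laplacian
#' (spacing-aware, edge-replicated). Negative results are clamped to 0 to keep
#' intensities physical.
#'
#' @param img a `scalar_image`.
#' @param alpha non-negative sharpening strength.
#' @return Sharpened `scalar_image`.
#' @export
laplacian_sharpen <- function(img, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0) {
    af_stop("`alpha` must be a non-negative scalar", "argument")
  }
  if (alpha == 0) return(img)
  out <- img$values - alpha * discrete_laplacian(img)
  out[out < 0] <- 0
  scalar_image(out, img$spacing, img$origin)
}

#' Gaussian smoothing of an intensity image
#' @param img a `scalar_image`.
#' @param sigma_vox smoothing sigma in voxels (scalar or triple).
#' @return Smoothed `scalar_image`.
#' @export
gaussian_smooth <- function(img, sigma_vox) {
  sigma_vox <- rep_len(as.numeric(sigma_vox), 3L)
  vals <- cpp_gauss3(as.numeric(img$values), img_dims(img), sigma_vox)
  scalar_image(array(vals, img_dims(img)), img$spacing, img$origin)
}

# ---- file I/O ---------------------------------------------------------------

is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)
is_tiff_path <- function(path) grepl("\\.tiff?$", path, ignore.case = TRUE)

#' Read a 3D volume from NIfTI or TIFF
#'
#' NIfTI (.nii / .nii.gz) carries spacing and origin in its header. Multi-page
#' TIFF stores no spacing, so a JSON sidecar `<file>.json` with
#' `{"spacing_um": [x, y, z]}` (optionally `"origin_um"`) is required.
#' Label volumes are read without interpolation or any dtype coercion that
#' changes values.
#'
#' @param path file to read.
#' @param kind `"intensity"` or `"label"`.
#' @return A `scalar_image` or `label_image`.
#' @export
read_volume <- function(path, kind = c("intensity", "label")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    af_stop(sprintf("cannot read volume: no such file '%s'", path), "format")
  }
  if (is_nifti_path(path)) {
    nii <- tryCatch(RNifti::readNifti(path), error = function(e) {
      af_stop(sprintf("unreadable NIfTI file '%s': %s", path, conditionMessage(e)),
              "format")
    })
    vals <- as.array(nii)
    d <- dim(vals)
    if (length(d) == 2L) d <- c(d, 1L)
    vals <- array(as.numeric(vals), d)  # strip NIfTI header attributes
    # header geometry is float32; round to its 7 significant decimal digits
    spacing <- signif(RNifti::pixdim(nii)[1:3], 7)
    xf <- try(RNifti::xform(nii), silent = TRUE)
    origin <- if (!inherits(xf, "try-error") && attr(xf, "code") > 0) {
      signif(as.numeric(xf[1:3, 4]), 7)
    } else c(0, 0, 0)
    origin[origin == 0] <- 0  # normalise -0
  } else if (is_tiff_path(path)) {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = (kind == "label")),
                      error = function(e) {
      af_stop(sprintf("unreadable TIFF file '%s': %s", path, conditionMessage(e)),
              "format")
    })
    if (!is.list(pages)) pages <- list(pages)
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) {
      af_stop(sprintf("TIFF '%s' has no spacing metadata: sidecar '%s' missing",
                      path, sidecar), "metadata")
    }
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(meta$spacing_um) || length(meta$spacing_um) != 3L) {
      af_stop(sprintf("sidecar '%s' lacks a 3-component spacing_um", sidecar),
              "metadata")
    }
    spacing <- as.numeric(meta$spacing_um)
    origin <- if (!is.null(meta$origin_um)) as.numeric(meta$origin_um) else c(0, 0, 0)
    vals <- array(0, c(dim(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) vals[, , k] <- pages[[k]]
    if (kind == "intensity" && !is.null(meta$scale)) vals <- vals * meta$scale
  } else {
    af_stop(sprintf("unsupported volume format: '%s'", path), "format")
  }
  if (kind == "label") {
    if (any(vals != round(vals))) {
      af_stop(sprintf("label volume '%s' contains non-integer values", path),
              "format")
    }
    storage.mode(vals) <- "integer"
    label_image(vals, spacing, origin)
  } else {
    scalar_image(vals, spacing, origin)
  }
}

#' Write a 3D volume to NIfTI or TIFF
#'
#' The NIfTI writer records spacing in `pixdim` and origin in an axis-aligned
#' sform. The TIFF writer emits one page per z-slice plus the JSON spacing
#' sidecar that [read_volume()] expects; intensity data are rescaled to
#' `[0, 1]` for storage (scale recorded in the sidecar), labels are stored as
#' 16-bit integers exactly.
#'
#' @param img a `scalar_image` or `label_image`.
#' @param path destination (.nii, .nii.gz, .tif, .tiff).
#' @return `path`, invisibly.
#' @export
write_volume <- function(img, path) {
  is_label <- inherits(img, "label_image")
  if (is_nifti_path(path)) {
    vals <- img$values
    nii <- RNifti::asNifti(vals)
    RNifti::pixdim(nii) <- img$spacing
    xf <- diag(c(img$spacing, 1))
    xf[1:3, 4] <- img$origin
    RNifti::qform(nii) <- structure(xf, code = 2L)
    RNifti::writeNifti(nii, path,
                       datatype = if (is_label) "int32" else "double")
  } else if (is_tiff_path(path)) {
    d <- img_dims(img)
    meta <- list(spacing_um = img$spacing, origin_um = img$origin)
    if (is_label) {
      mx <- max(img$values)
      if (mx > 65535L) af_stop("label values exceed 16-bit TIFF range", "format")
      pages <- lapply(seq_len(d[3]), function(k) img$values[, , k] / 65535)
      tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    } else {
      rng <- max(img$values)
      scale <- if (rng > 0) rng else 1
      meta$scale <- scale
      pages <- lapply(seq_len(d[3]), function(k) img$values[, , k] / scale)
      tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    }
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else {
    af_stop(sprintf("unsupported volume format: '%s'", path), "format")
  }
  invisible(path)
}

# ---- traces -----------------------------------------------------------------

#' Axonal trace: an ordered 3D polyline
#'
#' @param points n x 3 matrix of world coordinates (micrometres), n >= 2.
#' @param id identifier string.
#' @return An object of class `trace`.
#' @export
trace_polyline <- function(points, id = "trace") {
  points <- as.matrix(points)
  if (nrow(points) < 2L || ncol(points) != 3L || any(!is.finite(points))) {
    af_stop("a trace needs >= 2 finite 3D points", "argument")
  }
  dimnames(points) <- NULL
  structure(list(points = points, id = as.character(id)), class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace '%s'> %d points, length %.1f um\n", x$id,
              nrow(x$points), trace_length(x)))
  invisible(x)
}

#' Arc length of a trace (micrometres)
#' @param trace a `trace`.
#' @return Total polyline length.
#' @export
trace_length <- function(trace) {
  p <- trace$points
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Read traces from SWC or CSV
#'
#' SWC files use the standard 7-column node records (id, type, x, y, z,
#' radius, parent); one trace per file, points kept in file order. CSV files
#' need an `x,y,z` header and may hold several traces distinguished by an
#' optional `id` column. An empty file yields an empty list.
#'
#' @param path file to read.
#' @return A list of `trace` objects.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) {
    af_stop(sprintf("cannot read traces: no such file '%s'", path), "format")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (grepl("\\.swc$", path, ignore.case = TRUE)) {
    body <- lines[!grepl("^\\s*#", lines)]
    if (length(body) == 0L) return(list())
    pts <- matrix(0, length(body), 3)
    for (i in seq_along(body)) {
      f <- strsplit(trimws(body[i]), "\\s+")[[1]]
      xyz <- suppressWarnings(as.numeric(f[3:5]))
      if (length(f) < 7L || any(is.na(xyz))) {
        af_stop(sprintf("malformed SWC record at line %d of '%s'",
                        which(lines == body[i])[1], path), "parse")
      }
      pts[i, ] <- xyz
    }
    id <- sub("\\.swc$", "", basename(path), ignore.case = TRUE)
    return(list(trace_polyline(pts, id)))
  }
  # CSV
  if (length(lines) == 0L) return(list())
  header <- tolower(strsplit(lines[1], ",")[[1]])
  cx <- match(c("x", "y", "z"), trimws(header))
  if (any(is.na(cx))) {
    af_stop(sprintf("CSV '%s' must have an x,y,z header", path), "parse")
  }
  ci <- match("id", trimws(header))
  if (length(lines) == 1L) return(list())
  rows <- strsplit(lines[-1], ",")
  pts <- matrix(0, length(rows), 3)
  ids <- character(length(rows))
  for (i in seq_along(rows)) {
    f <- trimws(rows[[i]])
    xyz <- suppressWarnings(as.numeric(f[cx]))
    if (any(is.na(xyz))) {
      af_stop(sprintf("malformed CSV row at line %d of '%s'", i + 1L, path),
              "parse")
    }
    pts[i, ] <- xyz
    ids[i] <- if (!is.na(ci)) f[ci] else "trace"
  }
  split_idx <- split(seq_len(nrow(pts)), factor(ids, levels = unique(ids)))
  lapply(names(split_idx), function(nm) {
    trace_polyline(pts[split_idx[[nm]], , drop = FALSE], nm)
  })
}

#' Write traces to SWC or CSV
#'
#' SWC output writes one file per trace when `path` names a single trace, or
#' refuses multiple traces (use CSV for collections). Round-trips exactly with
#' [read_traces()].
#'
#' @param traces a `trace` or list of `trace` objects.
#' @param path destination file (.swc for one trace, .csv for any number).
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "trace")) traces <- list(traces)
  if (grepl("\\.swc$", path, ignore.case = TRUE)) {
    if (length(traces) != 1L) {
      af_stop("SWC holds a single trace; use CSV for collections", "argument")
    }
    p <- traces[[1]]$points
    rows <- sprintf("%d 2 %.9g %.9g %.9g 1.0 %d", seq_len(nrow(p)),
                    p[, 1], p[, 2], p[, 3],
                    c(-1L, seq_len(nrow(p) - 1L)))
    writeLines(c("# SWC trace export", rows), path)
  } else {
    rows <- unlist(lapply(traces, function(tr) {
      sprintf("%s,%.9g,%.9g,%.9g", tr$id, tr$points[, 1], tr$points[, 2],
              tr$points[, 3])
    }))
    writeLines(c("id,x,y,z", rows), path)
  }
  invisible(path)
}
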