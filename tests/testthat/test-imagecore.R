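test_that("NIfTI round-trip preserves values, spacing and origin", {
  img <- random_scalar(c(8, 8, 8), spacing = c(0.6, 0.6, 1.1), seed = 3)
  img$origin <- c(5, -2, 1.5)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(img, path)
  back <- read_volume(path, "intensity")
  expect_equal(back$values, img$values, tolerance = 1e-12)
  expect_equal(back$spacing, c(0.6, 0.6, 1.1))
  expect_equal(back$origin, c(5, -2, 1.5))
})

test_that("label volumes round-trip exactly through NIfTI and TIFF", {
  arr <- array(0L, c(6, 5, 4))
  arr[2, 3, 1] <- 3L
  arr[5, 1, 4] <- 7L
  lab <- label_image(arr, c(1.2, 1.2, 1.1))
  for (ext in c(".nii.gz", ".tif")) {
    path <- withr::local_tempfile(fileext = ext)
    write_volume(lab, path)
    back <- read_volume(path, "label")
    expect_s3_class(back, "label_image")
    expect_identical(sort(unique(as.vector(back$values))), c(0L, 3L, 7L))
    expect_identical(back$values, lab$values)
    expect_equal(back$spacing, lab$spacing)
  }
})

test_that("TIFF intensity round-trip works and missing sidecar errors", {
  img <- random_scalar(c(5, 6, 3), spacing = c(2, 1, 0.5), seed = 9)
  path <- withr::local_tempfile(fileext = ".tif")
  write_volume(img, path)
  back <- read_volume(path, "intensity")
  expect_equal(back$values, img$values, tolerance = 1e-6)
  expect_equal(back$spacing, img$spacing)
  file.remove(paste0(path, ".json"))
  expect_error(read_volume(path, "intensity"), class = "af_error_metadata")
  expect_error(read_volume("no/such/file.nii"), class = "af_error_format")
})

test_that("voxel diagonal matches closed forms and the printed geometry", {
  expect_equal(voxel_diagonal(c(3, 4, 1e-12)), 5, tolerance = 1e-9)
  expect_equal(voxel_diagonal(c(1, 1, 1)), sqrt(3))
  # acquisition spacing of the reference dataset rounds to 1.4 um
  expect_equal(round(voxel_diagonal(c(0.6, 0.6, 1.1)), 1), 1.4)
  expect_error(voxel_diagonal(c(1, -1, 1)), class = "af_error_argument")
})

test_that("downsample_xy block-averages intensity and strides labels", {
  img <- scalar_image(array(5, c(4, 4, 1)), c(0.6, 0.6, 1.1))
  down <- downsample_xy(img, 2)
  expect_equal(dim(down$values), c(2, 2, 1))
  expect_equal(as.vector(down$values), rep(5, 4))
  expect_equal(down$spacing, c(1.2, 1.2, 1.1))
  expect_identical(downsample_xy(img, 1), img)

  # block averaging preserves the global mean on exact multiples
  r <- random_scalar(c(8, 12, 5), seed = 5)
  expect_equal(mean(downsample_xy(r, 2)$values), mean(r$values),
               tolerance = 1e-6)

  lab <- random_labels(c(9, 9, 3), n_labels = 4, seed = 2)
  dl <- downsample_xy(lab, 3)
  expect_s3_class(dl, "label_image")
  expect_true(all(dl$values %in% lab$values))
  expect_equal(dl$values, lab$values[c(1, 4, 7), c(1, 4, 7), , drop = FALSE])
  expect_error(downsample_xy(img, 0), class = "af_error_argument")
})

test_that("warp_linear is the identity under the zero field", {
  img <- random_scalar(c(10, 9, 8), spacing = c(1.2, 1.2, 1.1), seed = 7)
  out <- warp_linear(img, zero_field(img))
  expect_equal(out$values, img$values, tolerance = 1e-6)
})

test_that("warp_linear shifts exactly by one voxel and fills outside with 0", {
  img <- random_scalar(c(10, 9, 8), spacing = c(1.2, 1.2, 1.1), seed = 8)
  f <- zero_field(img)
  f$vectors[, , , 1] <- 1.2
  out <- warp_linear(img, f)
  expect_equal(out$values[1:9, , ], img$values[2:10, , ], tolerance = 1e-9)
  expect_equal(out$values[10, , ], array(0, c(9, 8)))

  far <- zero_field(img)
  far$vectors[, , , 1] <- 1000
  expect_true(all(warp_linear(img, far)$values == 0))
})

test_that("warp_nearest never invents labels and handles half-voxel shifts", {
  lab <- random_labels(c(8, 8, 6), n_labels = 1, seed = 4)
  expect_identical(warp_nearest(lab, zero_field(lab))$values, lab$values)
  set.seed(11)
  f <- zero_field(lab)
  f$vectors[] <- runif(length(f$vectors), -3, 3)
  out <- warp_nearest(lab, f)
  expect_true(all(out$values %in% c(0L, unique(as.vector(lab$values)))))

  half <- zero_field(lab)
  half$vectors[, , , 2] <- 0.4  # under half a voxel: nearest is the same voxel
  expect_identical(warp_nearest(lab, half)$values, lab$values)
})

test_that("laplacian sharpening matches the hand-applied 6-neighbour stencil", {
  img <- random_scalar(c(6, 6, 6), seed = 10)
  expect_identical(laplacian_sharpen(img, 0), img)
  const <- scalar_image(array(7, c(5, 5, 5)))
  expect_equal(laplacian_sharpen(const, 2.5)$values, const$values)

  imp <- scalar_image(array(0, c(5, 5, 5)))
  imp$values[3, 3, 3] <- 6
  sh <- laplacian_sharpen(imp, 1)
  # centre: 6 - 1 * (-36); face neighbours: 0 - 6 clamped to 0
  expect_equal(sh$values[3, 3, 3], 42)
  expect_equal(sh$values[4, 3, 3], 0)
  expect_equal(sh$values[3, 2, 3], 0)
  expect_equal(sh$values[4, 4, 3], 0)  # diagonal untouched
  expect_error(laplacian_sharpen(imp, -1), class = "af_error_argument")
})

test_that("traces round-trip through SWC and CSV", {
  pts <- matrix(c(0, 0, 0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12), 5, 3,
                byrow = TRUE)
  tr <- trace_polyline(pts, "t1")
  swc <- withr::local_tempfile(fileext = ".swc")
  write_traces(tr, swc)
  back <- read_traces(swc)
  expect_length(back, 1)
  expect_equal(back[[1]]$points, pts)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_traces(list(tr, trace_polyline(pts[1:2, ], "t2")), csv)
  both <- read_traces(csv)
  expect_length(both, 2)
  expect_equal(both[[1]]$points, pts)
  expect_equal(both[[2]]$id, "t2")
})

test_that("trace reading handles empty and malformed files", {
  empty <- withr::local_tempfile(fileext = ".swc")
  writeLines(character(0), empty)
  expect_identical(read_traces(empty), list())

  bad <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 2 0 0 0 1 -1", "2 2 oops 0 0 1 1"), bad)
  expect_error(read_traces(bad), "line 2", class = "af_error_parse")
})
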