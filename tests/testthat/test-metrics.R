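test_that("dice matches hand-counted overlaps and handles degenerate regions", {
  lab <- block_labels()
  expect_equal(dice(lab, lab, 1), 1)
  expect_equal(dice(lab, lab, 2), 1)

  # 3x3x1 square against itself shifted by one voxel: 2*6 / 18
  a <- array(0L, c(8, 8, 1)); a[3:5, 3:5, 1] <- 1L
  b <- array(0L, c(8, 8, 1)); b[4:6, 3:5, 1] <- 1L
  A <- label_image(a); B <- label_image(b)
  expect_equal(dice(A, B, 1), 2 * 6 / 18)

  disj <- array(0L, c(8, 8, 1)); disj[1, 1, 1] <- 1L
  expect_equal(dice(A, label_image(disj), 1), 0)
  expect_error(dice(A, B, 9), class = "af_error_region")
})

test_that("boundary_points follows the 6-connectivity convention", {
  one <- array(0L, c(5, 5, 5)); one[3, 2, 4] <- 1L
  bp <- boundary_points(label_image(one, c(2, 1, 0.5)), 1)
  expect_equal(nrow(bp), 1)
  expect_equal(as.vector(bp), c(2 * 2, 1 * 1, 3 * 0.5))

  cube <- array(0L, c(7, 7, 7)); cube[3:5, 3:5, 3:5] <- 1L
  expect_equal(nrow(boundary_points(label_image(cube), 1)), 26)

  sheet <- array(0L, c(6, 6, 3)); sheet[2:5, 2:5, 2] <- 1L
  expect_equal(nrow(boundary_points(label_image(sheet), 1)), 16)
  expect_error(boundary_points(label_image(cube), 5), class = "af_error_region")
})

test_that("surface distances match enumerated point sets", {
  # identical regions
  lab <- block_labels()
  expect_equal(mean_symmetric_surface_distance(lab, lab, 1), 0)
  expect_equal(symmetric_hausdorff(lab, lab, 2), 0)

  # two single-voxel regions 3 um apart
  a <- array(0L, c(9, 3, 3)); a[2, 2, 2] <- 1L
  b <- array(0L, c(9, 3, 3)); b[5, 2, 2] <- 1L
  A <- label_image(a); B <- label_image(b)
  expect_equal(mean_symmetric_surface_distance(A, B, 1), 3)
  expect_equal(symmetric_hausdorff(A, B, 1), 3)

  # singleton vs pair along z, 5 um apart: d = (0 + 2.5)/2, h = (0 + 5)/2
  a2 <- array(0L, c(3, 3, 7)); a2[2, 2, 2] <- 1L
  b2 <- array(0L, c(3, 3, 7)); b2[2, 2, 2] <- 1L; b2[2, 2, 7] <- 1L
  A2 <- label_image(a2, c(1, 1, 1)); B2 <- label_image(b2, c(1, 1, 1))
  expect_equal(mean_symmetric_surface_distance(A2, B2, 1), 1.25)
  expect_equal(symmetric_hausdorff(A2, B2, 1), 2.5)
})

test_that("region metrics agree exactly with the brute-force oracle", {
  set.seed(99)
  for (case in 1:20) {
    d <- sample(6:14, 3, replace = TRUE)
    sp <- runif(3, 0.5, 2)
    arr_a <- array(sample(0:2, prod(d), replace = TRUE, prob = c(0.7, 0.2, 0.1)), d)
    arr_b <- array(sample(0:2, prod(d), replace = TRUE, prob = c(0.7, 0.2, 0.1)), d)
    A <- label_image(arr_a, sp)
    B <- label_image(arr_b, sp)
    for (r in 1:2) {
      if (!any(arr_a == r) || !any(arr_b == r)) next
      o <- oracle_region_metrics(arr_a, arr_b, r, sp)
      expect_equal(dice(A, B, r), o$dice, tolerance = 1e-12)
      expect_equal(mean_symmetric_surface_distance(A, B, r), o$msd,
                   tolerance = 1e-9)
      expect_equal(symmetric_hausdorff(A, B, r), o$hausdorff, tolerance = 1e-9)
    }
  }
})

test_that("region metrics are symmetric, scale-covariant, and ordered", {
  set.seed(7)
  d <- c(10, 10, 8)
  arr_a <- array(sample(0:1, prod(d), replace = TRUE, prob = c(0.8, 0.2)), d)
  arr_b <- array(sample(0:1, prod(d), replace = TRUE, prob = c(0.8, 0.2)), d)
  for (s in c(1, 2.5)) {
    A <- label_image(arr_a, c(1, 1.5, 0.8) * s)
    B <- label_image(arr_b, c(1, 1.5, 0.8) * s)
    expect_equal(dice(A, B, 1), dice(B, A, 1))
    expect_equal(mean_symmetric_surface_distance(A, B, 1),
                 mean_symmetric_surface_distance(B, A, 1))
    expect_equal(symmetric_hausdorff(A, B, 1), symmetric_hausdorff(B, A, 1))
    expect_lte(mean_symmetric_surface_distance(A, B, 1),
               symmetric_hausdorff(A, B, 1))
  }
  A1 <- label_image(arr_a, c(1, 1.5, 0.8))
  B1 <- label_image(arr_b, c(1, 1.5, 0.8))
  A2 <- label_image(arr_a, 2 * c(1, 1.5, 0.8))
  B2 <- label_image(arr_b, 2 * c(1, 1.5, 0.8))
  expect_equal(dice(A2, B2, 1), dice(A1, B1, 1))
  expect_equal(mean_symmetric_surface_distance(A2, B2, 1),
               2 * mean_symmetric_surface_distance(A1, B1, 1))
  expect_equal(symmetric_hausdorff(A2, B2, 1),
               2 * symmetric_hausdorff(A1, B1, 1))
})

test_that("hausdorff shift is bounded by the translation norm", {
  a <- array(0L, c(12, 8, 8)); a[4:6, 3:5, 3:5] <- 1L
  b <- array(0L, c(12, 8, 8)); b[6:8, 3:5, 3:5] <- 1L  # shifted 2 voxels in x
  A <- label_image(a, c(1.5, 1, 1))
  B <- label_image(b, c(1.5, 1, 1))
  expect_lte(symmetric_hausdorff(A, B, 1), 2 * 1.5 + 1e-9)
})

test_that("trace distances follow closed forms", {
  line <- function(offset = c(0, 0, 0)) {
    trace_polyline(cbind(seq(0, 20, by = 2), 0, 0) +
                     matrix(offset, 11, 3, byrow = TRUE))
  }
  expect_equal(trace_distance(line(), line()), 0)
  expect_equal(trace_distance(line(), line(c(0, 4, 0))), 4)
  expect_equal(trace_distance(line(), line(c(0, 4, 0))) / 100,
               normalized_trace_distance(line(), line(c(0, 4, 0)), 100))
  expect_equal(trace_distance(line(), line(c(0, 4, 0))),
               trace_distance(line(c(0, 4, 0)), line()))
  expect_error(normalized_trace_distance(line(), line(), -1),
               class = "af_error_argument")
})

test_that("masked overlap implements the spatial-query semantics", {
  d <- c(10, 10, 4)
  set.seed(5)
  pat <- scalar_image(array(runif(prod(d)), d))
  mask <- label_image(array(1L, d))
  expect_equal(masked_overlap(pat, pat, mask, 0.5, 0.5), 1)

  kept <- filter_overlap_candidates(c(a = 0.15, b = 0.25, c = 0.60), 0.20)
  expect_length(kept, 2)
  expect_named(kept, c("c", "b"))
  expect_length(filter_overlap_candidates(c(0.2, 0.1)), 0)  # strict threshold

  # mask that excludes all foreground of both patterns -> undefined overlap
  m2 <- label_image(array(0L, d))
  m2$values[1, 1, 1] <- 1L
  lowpat <- scalar_image(array(0, d))
  expect_error(masked_overlap(lowpat, lowpat, m2, 0.5, 0.5),
               class = "af_error_overlap")
  expect_error(masked_overlap(pat, pat, label_image(array(0L, d)), 0.5, 0.5),
               class = "af_error_argument")
})
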