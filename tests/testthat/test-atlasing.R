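test_that("initial average handles single and identical subjects", {
  ref <- tiny_reference()
  s1 <- subject_brain(ref$intensity, ref$labels, id = "s1")
  ia1 <- initial_average(list(s1), lean_reg())
  expect_equal(ia1$average$values, ref$intensity$values)

  subs <- list(s1, subject_brain(ref$intensity, ref$labels, id = "s2"),
               subject_brain(ref$intensity, ref$labels, id = "s3"))
  ia <- initial_average(subs, lean_reg())
  rng <- diff(range(ref$intensity$values))
  expect_lt(max(abs(ia$average$values - ref$intensity$values)), 1e-4 * rng)
  expect_error(initial_average(list()), class = "af_error_argument")
})

test_that("rigid alignment sharpens the average of two shifted phantoms", {
  ref <- tiny_reference()$intensity
  f <- zero_field(ref)
  f$vectors[, , , 1] <- 3 * ref$spacing[1]
  shifted <- warp_linear(ref, f)
  subs <- list(subject_brain(ref, id = "a"), subject_brain(shifted, id = "b"))
  ia <- initial_average(subs, lean_reg(), seed = 1)
  naive <- scalar_image((ref$values + shifted$values) / 2, ref$spacing)
  grad_mag <- function(img) {
    g <- atlasforge:::cpp_grad3(as.numeric(img$values), dim(img$values),
                                img$spacing)
    mean(sqrt(rowSums(g^2)))
  }
  expect_gt(grad_mag(ia$average), grad_mag(naive))
})

test_that("template construction is idempotent on identical subjects", {
  ref <- tiny_reference()
  subs <- lapply(1:3, function(i) {
    subject_brain(ref$intensity, ref$labels, id = paste0("s", i))
  })
  rng <- diff(range(ref$intensity$values))
  for (comb in c("median", "mean")) {
    bt <- build_template(subs, comb, lean_reg(), outer_iters = 1L)
    expect_lt(mean(abs(bt$template$values - ref$intensity$values)), 0.01 * rng)
    mags <- sqrt(rowSums(atlasforge:::field_matrix(bt$transforms[[1]]$forward)^2))
    expect_lt(mean(mags), 0.5 * min(ref$intensity$spacing))
  }
})

test_that("voxel-wise combination follows the documented median/mean rules", {
  stack <- matrix(c(10, 20, 90), nrow = 1)
  attr(stack, "dims3") <- c(1L, 1L, 1L)
  med <- atlasforge:::combine_stack(stack, "median", 0.3, c(1, 1, 1), c(0, 0, 0))
  expect_equal(as.vector(med$values), 20)
  # even count: mean of the two middle values
  stack2 <- matrix(c(10, 20, 40, 90), nrow = 1)
  attr(stack2, "dims3") <- c(1L, 1L, 1L)
  med2 <- atlasforge:::combine_stack(stack2, "median", 0.3, c(1, 1, 1), c(0, 0, 0))
  expect_equal(as.vector(med2$values), 30)
})

test_that("median combination resists a contaminated subject, mean does not", {
  ref <- tiny_reference()$intensity
  set.seed(17)
  corrupt <- scalar_image(array(runif(length(ref$values), 0, 200),
                                dim(ref$values)), ref$spacing)
  stack <- cbind(matrix(rep(as.numeric(ref$values), 4), ncol = 4),
                 as.numeric(corrupt$values))
  attr(stack, "dims3") <- dim(ref$values)
  med <- atlasforge:::combine_stack(stack, "median", 0.3, ref$spacing, ref$origin)
  avg <- atlasforge:::combine_stack(stack, "mean", 0.3, ref$spacing, ref$origin)
  rms <- function(img) sqrt(mean((img$values - ref$values)^2))
  expect_lt(rms(med), rms(avg))
})

test_that("majority voting fuses labels with the documented tie-break", {
  mk <- function(v) label_image(array(as.integer(v), c(1, 1, 1)))
  grid <- scalar_image(array(0, c(1, 1, 1)))
  idt <- diffeo_transform(zero_field(grid), zero_field(grid))
  fuse <- function(vals) {
    fuse_labels(lapply(vals, mk), rep(list(idt), length(vals)), grid)$values[1]
  }
  expect_equal(fuse(c(3, 3, 3)), 3)
  expect_equal(fuse(c(1, 1, 2)), 1)
  expect_equal(fuse(c(1, 2)), 1)      # tie -> smallest label id
  expect_equal(fuse(c(0, 2)), 0)      # background competes as a label
  expect_error(fuse_labels(list(mk(1)), list(), grid),
               class = "af_error_argument")
})

test_that("fused labels never contain labels absent from the inputs", {
  ref <- tiny_reference()
  cfg <- tiny_cfg(seed = 91)
  labs <- list(ref$labels, warp_nearest(ref$labels,
                                        random_diffeo(cfg, seed = 7)$forward))
  idt <- diffeo_transform(zero_field(ref$intensity), zero_field(ref$intensity))
  fused <- fuse_labels(labs, list(idt, idt), ref$intensity)
  expect_true(all(fused$values %in% 0:14))
})

test_that("registering the template to its own atlas is a near-identity", {
  ref <- tiny_reference()
  atl <- atlas(ref$intensity, ref$labels, "median", 1)
  subj <- subject_brain(ref$intensity, ref$labels, id = "self")
  tr <- register_subject(atl, subj, lean_reg())
  mags <- sqrt(rowSums(atlasforge:::field_matrix(tr$forward)^2))
  expect_lt(mean(mags), 0.1 * min(ref$intensity$spacing))

  # label closure through the inverse direction
  seg <- apply_diffeo(tr, atl$labels, "to_moving", grid = subj$labels)
  expect_true(all(seg$values %in% atl$labels$values))
})

test_that("equivalent spherical radius matches closed-form volumes", {
  s <- (4 * pi / 3)^(1 / 3)
  one <- array(0, c(3, 3, 3))
  one[2, 2, 2] <- 10
  img <- scalar_image(one, c(s, s, s))
  expect_equal(equivalent_spherical_radius(img, "fixed", threshold = 5), 1)

  filled <- array(0, c(5, 5, 5))
  filled[2:4, 2:4, 2:4] <- 10  # 27 voxels -> V = 36 pi
  img27 <- scalar_image(filled, c(s, s, s))
  expect_equal(equivalent_spherical_radius(img27, "fixed", threshold = 5), 3)

  img2 <- scalar_image(filled, 2 * c(s, s, s))
  expect_equal(equivalent_spherical_radius(img2, "fixed", threshold = 5), 6)

  expect_error(equivalent_spherical_radius(img, "fixed", threshold = 100),
               class = "af_error_degenerate")
  expect_error(equivalent_spherical_radius(scalar_image(array(1, c(4, 4, 4)))),
               class = "af_error_degenerate")
})

test_that("atlas bundles round-trip through disk", {
  ref <- tiny_reference()
  atl <- atlas(ref$intensity, ref$labels, "median", 3,
               provenance = list(id = "demo", subjects = c("a", "b", "c")))
  dir <- withr::local_tempdir()
  write_atlas(atl, dir)
  back <- read_atlas(dir)
  expect_equal(back$template$values, atl$template$values, tolerance = 1e-12)
  expect_identical(back$labels$values, atl$labels$values)
  expect_equal(back$combination, "median")
  expect_equal(back$n_subjects, 3)
  expect_equal(back$provenance$id, "demo")
})
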