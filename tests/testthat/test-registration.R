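test_that("mutual information has the expected degenerate and closed forms", {
  const <- scalar_image(array(5, c(8, 8, 4)))
  other <- random_scalar(c(8, 8, 4), seed = 1)
  expect_equal(mutual_information(const, other), 0)

  # identical two-valued images with equal frequencies: MI = H(X) = ln 2
  half <- array(rep(c(0, 100), each = 128), c(8, 8, 4))
  two <- scalar_image(half)
  expect_equal(mutual_information(two, two, bins = 2), log(2), tolerance = 1e-9)

  a <- random_scalar(c(8, 8, 8), seed = 2)
  b <- random_scalar(c(8, 8, 8), seed = 3)
  expect_equal(mutual_information(a, b), mutual_information(b, a))
  expect_gte(mutual_information(a, b), 0)
  expect_error(mutual_information(a, random_scalar(c(4, 4, 4))),
               class = "af_error_geometry")
})

test_that("local cross-correlation is affine-invariant and bounded", {
  a <- random_scalar(c(12, 12, 10), seed = 4)
  expect_equal(local_cross_correlation(a, a, 2), 1, tolerance = 1e-9)
  b <- a
  b$values <- 2 * a$values + 7
  expect_equal(local_cross_correlation(a, b, 2), 1, tolerance = 1e-9)

  # independent noise decorrelates in windows of radius 3
  vals <- sapply(1:10, function(s) {
    local_cross_correlation(random_scalar(c(12, 12, 12), seed = 100 + s),
                            random_scalar(c(12, 12, 12), seed = 200 + s), 3)
  })
  expect_lt(max(vals), 0.2)
})

test_that("rigid self-registration stays at the identity", {
  ref <- tiny_reference()$intensity
  rt <- rigid_register(ref, ref, lean_reg())
  expect_lt(sqrt(sum(rt$translation^2)), 0.25 * min(ref$spacing))
  angle <- acos(pmin(1, (sum(diag(rt$rotation)) - 1) / 2)) * 180 / pi
  expect_lt(angle, 0.5)
  expect_error(rigid_register(scalar_image(array(1, c(8, 8, 8))), ref),
               class = "af_error_degenerate")
})

test_that("rigid registration recovers known translations and rotations", {
  ref <- tiny_reference()$intensity
  d <- dim(ref$values)
  center <- ref$origin + (d - 1) / 2 * ref$spacing

  rt_true <- rigid_transform(diag(3), c(3 * ref$spacing[1], 0, 0), center)
  moving <- atlasforge:::resample_rigid(ref, ref, rt_true)
  rt_hat <- rigid_register(moving, ref, lean_reg())
  err <- sqrt(sum((rt_hat$translation - rigid_inverse(rt_true)$translation)^2))
  expect_lt(err, 0.5 * min(ref$spacing))

  rt_rot <- rigid_from_angles(c(0, 0, 8 * pi / 180), c(0, 0, 0), center)
  moving2 <- atlasforge:::resample_rigid(ref, ref, rt_rot)
  rh2 <- rigid_register(moving2, ref, lean_reg())
  rel <- t(rh2$rotation) %*% rigid_inverse(rt_rot)$rotation
  angle_err <- acos(pmin(1, (sum(diag(rel)) - 1) / 2)) * 180 / pi
  expect_lt(angle_err, 1)
})

test_that("field composition has the zero field as identity element", {
  cfg <- tiny_cfg(seed = 6)
  f <- random_diffeo(cfg, seed = 6)$forward
  z <- displacement_field(array(0, dim(f$vectors)), f$spacing, f$origin)
  expect_equal(compose_fields(f, z)$vectors, f$vectors, tolerance = 1e-9)
  expect_equal(compose_fields(z, f)$vectors, f$vectors, tolerance = 1e-9)
})

test_that("inverting a constant shift yields the negated shift", {
  img <- random_scalar(c(16, 16, 12), spacing = c(1.2, 1.2, 1.1))
  f <- zero_field(img)
  f$vectors[, , , 1] <- 2.0
  f$vectors[, , , 3] <- -1.5
  inv <- invert_field(f)
  interior <- as.vector(array(seq_len(prod(dim(img$values))), dim(img$values))[4:13, 4:13, 4:9])
  m <- atlasforge:::field_matrix(inv)[interior, ]
  expect_lt(max(abs(m[, 1] + 2.0)), 0.05 * 1.1)
  expect_lt(max(abs(m[, 2])), 0.05 * 1.1)
  expect_lt(max(abs(m[, 3] - 1.5)), 0.05 * 1.1)
})

test_that("map_points through a zero-field transform is the identity", {
  img <- random_scalar(c(8, 8, 8))
  t0 <- diffeo_transform(zero_field(img), zero_field(img))
  pts <- matrix(runif(15, 1, 6), 5, 3)
  expect_equal(map_points(t0, pts), pts, tolerance = 1e-12)
  tr <- trace_polyline(pts)
  expect_equal(map_points(t0, tr)$points, pts, tolerance = 1e-12)
})

test_that("diffeomorphic self-registration stays near the identity", {
  ref <- tiny_reference()$intensity
  tr <- diffeo_register(ref, ref, lean_reg())
  mags <- sqrt(rowSums(atlasforge:::field_matrix(tr$forward)^2))
  expect_lt(mean(mags), 0.1 * min(ref$spacing))
})

test_that("diffeo registration improves similarity, is symmetric and fold-free", {
  cfg <- tiny_cfg(seed = 13)
  ref <- make_reference(cfg)
  dt <- random_diffeo(cfg, seed = 14)
  moving <- warp_linear(ref$intensity, dt$forward)
  rc <- lean_reg()
  tr <- diffeo_register(moving, ref$intensity, rc)

  cc_before <- local_cross_correlation(ref$intensity, moving, rc$cc_radius)
  warped <- apply_diffeo(tr, moving, "to_fixed")
  cc_after <- local_cross_correlation(ref$intensity, warped, rc$cc_radius)
  expect_gt(cc_after, cc_before)

  # swapping fixed and moving mirrors the transform
  tr_sw <- diffeo_register(ref$intensity, moving, rc)
  disc <- sqrt(rowSums((atlasforge:::field_matrix(tr$forward) -
                          atlasforge:::field_matrix(tr_sw$inverse))^2))
  fg <- as.vector(ref$intensity$values > 10)
  expect_lt(mean(disc[fg]) / min(cfg$spacing), 1)

  # fold-free on the interior
  jd <- jacobian_determinant(tr$forward)$values
  interior <- jd[3:30, 3:30, 3:30]
  expect_gte(mean(interior > 0), 0.995)

  # inverse consistency
  comp <- compose_fields(tr$forward, tr$inverse)
  res <- sqrt(rowSums(atlasforge:::field_matrix(comp)^2)) / min(cfg$spacing)
  expect_lt(mean(res), 0.5)
})

test_that("registration is deterministic for identical inputs", {
  cfg <- tiny_cfg(seed = 21)
  ref <- make_reference(cfg)
  moving <- warp_linear(ref$intensity, random_diffeo(cfg, seed = 22)$forward)
  rc <- reg_config(levels = 2, iterations = c(10, 5))
  t1 <- diffeo_register(moving, ref$intensity, rc)
  t2 <- diffeo_register(moving, ref$intensity, rc)
  expect_identical(t1$forward$vectors, t2$forward$vectors)
  r1 <- rigid_register(moving, ref$intensity, rc)
  r2 <- rigid_register(moving, ref$intensity, rc)
  expect_identical(r1$rotation, r2$rotation)
  expect_identical(r1$translation, r2$translation)
})

test_that("config validation rejects diffeomorphism-breaking steps", {
  expect_error(reg_config(step = 0.5), class = "af_error_config")
  expect_error(reg_config(levels = 0), class = "af_error_config")
  img <- random_scalar(c(8, 8, 8))
  bad <- img
  bad$values[1] <- NA
  expect_error(diffeo_register(bad, img), class = "af_error_data")
})
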