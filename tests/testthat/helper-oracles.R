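# Independent brute-force oracles, written against the documented
# conventions only (6-connected face boundaries, voxel-centre world
# coordinates, all-pairs Euclidean distances). They share no code with the
# package implementations they check.

oracle_boundary <- function(arr, region, spacing, origin = c(0, 0, 0)) {
  d <- dim(arr)
  pts <- NULL
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (arr[i, j, k] != region) next
    nb <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k), c(i, j + 1, k),
               c(i, j, k - 1), c(i, j, k + 1))
    on_boundary <- FALSE
    for (q in nb) {
      if (any(q < 1) || any(q > d)) { on_boundary <- TRUE; break }
      if (arr[q[1], q[2], q[3]] != region) { on_boundary <- TRUE; break }
    }
    if (on_boundary) {
      pts <- rbind(pts, origin + (c(i, j, k) - 1) * spacing)
    }
  }
  pts
}

oracle_all_pairs_min <- function(a, b) {
  # for each row of a, min distance to rows of b (direct differences)
  vapply(seq_len(nrow(a)), function(i) {
    sqrt(min(colSums((t(b) - a[i, ])^2)))
  }, numeric(1))
}

oracle_region_metrics <- function(arr_a, arr_b, region, spacing) {
  ma <- arr_a == region
  mb <- arr_b == region
  dice <- 2 * sum(ma & mb) / (sum(ma) + sum(mb))
  ba <- oracle_boundary(arr_a, region, spacing)
  bb <- oracle_boundary(arr_b, region, spacing)
  dab <- oracle_all_pairs_min(ba, bb)
  dba <- oracle_all_pairs_min(bb, ba)
  list(dice = dice,
       msd = (mean(dab) + mean(dba)) / 2,
       hausdorff = (max(dab) + max(dba)) / 2)
}

# Exact Wilcoxon signed-rank p by full enumeration of all 2^n sign
# assignments (two-sided, midranks, the same p definition the package
# documents).
oracle_wilcoxon_exact <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
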