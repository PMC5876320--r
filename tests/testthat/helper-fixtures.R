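# Shared fixtures. Everything is generated in code; expensive objects are
# memoised so several test files can reuse them within one run.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- force(expr)
  fixture_env[[key]]
}

# Small, fast phantom configuration used throughout the unit tests. The grid
# is the smallest the anatomy supports; the vignette documents the scaling.
tiny_cfg <- function(seed = 1L, ...) {
  phantom_config(dims = c(32L, 32L, 32L), seed = seed, ...)
}

tiny_reference <- function() memo("tiny_reference", make_reference(tiny_cfg()))

# Lean registration settings for pipeline-level tests.
lean_reg <- function(...) {
  reg_config(levels = 3L, iterations = c(20L, 12L, 6L), ...)
}

random_scalar <- function(dims = c(8L, 8L, 8L), spacing = c(1, 1, 1),
                          seed = 1L) {
  set.seed(seed)
  scalar_image(array(runif(prod(dims), 0, 100), dims), spacing)
}

random_labels <- function(dims = c(8L, 8L, 8L), spacing = c(1, 1, 1),
                          n_labels = 3L, seed = 1L) {
  set.seed(seed)
  label_image(array(sample(0:n_labels, prod(dims), replace = TRUE), dims),
              spacing)
}

# A blocky two-region label volume where both regions are compact.
block_labels <- function(dims = c(12L, 12L, 8L), spacing = c(1, 1, 1)) {
  a <- array(0L, dims)
  a[3:6, 3:6, 3:5] <- 1L
  a[8:10, 7:10, 4:6] <- 2L
  label_image(a, spacing)
}
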