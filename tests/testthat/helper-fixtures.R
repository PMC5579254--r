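# Small shared fixtures, all generated in code.

tiny_spec <- function(seed = 1L, ...) {
  cohort_spec(n_young = 4L, n_old = 4L, grid = c(8L, 8L, 4L),
              rng_seed = seed, ...)
}

# A two-block design on a voxel-by-frame matrix: frames 1:4 and 5:8.
two_block_design <- function(tr = 1) {
  block_design(data.frame(label = "fixation", onset = c(0, 4),
                          duration = 4), tr)
}

# Deterministic masks for component classification on an 8x8x4 grid.
test_masks <- function() make_grid_masks(c(8L, 8L, 4L))

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual / expected - 1) < tol),
              label = sprintf("max rel dev %.4g < %g",
                              max(abs(actual / expected - 1)), tol))
}
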