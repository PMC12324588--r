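# Shared fixtures: small stacks built in code.

tiny_meta <- function(n_bins = 8, period = 12.5, harmonic = 1) {
  flim_meta(n_bins = n_bins, period = period, harmonic = harmonic)
}

# Uniform mono-exponential stack: every pixel carries the same decay.
mono_stack <- function(tau, total = 200, shape = c(4, 4),
                       meta = flim_meta(256, period = 12.5)) {
  tr <- exp(-bin_centers(meta) / tau)
  tr <- tr * total / sum(tr)
  x <- matrix(tr, nrow = prod(shape), ncol = meta$n_bins, byrow = TRUE)
  attr(x, "pixdim") <- shape
  unflatten(x, meta)
}

# Stack from an explicit pixel-by-bin matrix (row-major pixel order).
stack_from_matrix <- function(x, shape, meta) {
  x <- as.matrix(x)
  attr(x, "pixdim") <- shape
  unflatten(x, meta)
}

expect_all_equal <- function(a, b, tol = 1e-12) {
  expect_lt(max(abs(a - b)), tol)
}
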