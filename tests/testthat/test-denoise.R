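test_that("NC factors are the floored row/column means", {
  x <- rbind(c(0, 2), c(4, 10))
  f <- compute_nc_factors(x)
  expect_equal(unname(f$row_factors), c(1, 7))
  expect_equal(unname(f$col_factors), c(2, 6))
  fc <- compute_nc_factors(matrix(3, 5, 4))
  expect_true(all(fc$row_factors == 3) && all(fc$col_factors == 3))
  f0 <- compute_nc_factors(matrix(0, 3, 3))
  expect_true(all(f0$row_factors == 1e-6) && all(f0$col_factors == 1e-6))
  expect_error(compute_nc_factors(matrix(-1, 2, 2)), "non-negative")
})

test_that("NC scaling normalizes constants and inverts exactly", {
  xc <- matrix(5, 4, 3)
  expect_all_equal(apply_nc(xc, compute_nc_factors(xc)), matrix(1, 4, 3))
  set.seed(1)
  for (i in 1:5) {
    x <- matrix(rexp(24, 1 / 10), 6, 4)
    f <- compute_nc_factors(x)
    expect_all_equal(invert_nc(apply_nc(x, f), f), x, tol = 1e-10)
  }
  expect_error(apply_nc(matrix(1, 2, 2), compute_nc_factors(matrix(1, 3, 3))),
               "conform")
})

test_that("NC scaling flattens Poisson variance under a product-mean model", {
  set.seed(2)
  a <- seq(2, 40, length.out = 10)
  b <- seq(1, 20, length.out = 10)
  mu <- outer(a, b) / mean(outer(a, b))
  mu <- mu * 8  # means spanning ~two orders of magnitude
  reps <- 400
  v <- matrix(0, 10, 10)
  f <- compute_nc_factors(mu)
  for (r in seq_len(reps)) {
    x <- matrix(rpois(100, mu), 10, 10)
    xs <- apply_nc(x, f)
    v <- v + (xs - apply_nc(mu, f))^2
  }
  v <- v / reps
  expect_lt(max(v) / min(v), 2)
})

test_that("rank-k PCA reconstruction matches a brute-force eigen oracle", {
  # exactly rank-1 input is recovered exactly with k = 1
  u <- c(1, 2, 3, 4, 5); w <- c(2, -1, 0.5)
  x1 <- outer(u, w)
  pr1 <- pca_reconstruct(x1, 1)
  expect_all_equal(pr1$reconstruction, x1, tol = 1e-9)
  # k = n_bins reproduces the input to machine precision
  set.seed(3)
  x <- matrix(rnorm(15, 5), 5, 3)
  expect_all_equal(pca_reconstruct(x, 3)$reconstruction, x, tol = 1e-9)
  # k = 2 equals the best rank-2 approximation from the covariance eigen
  pr2 <- pca_reconstruct(x, 2)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  ev <- eigen(crossprod(xc), symmetric = TRUE)
  v2 <- ev$vectors[, 1:2]
  oracle <- sweep(xc %*% v2 %*% t(v2), 2, mu, `+`)
  expect_all_equal(pr2$reconstruction, oracle, tol = 1e-9)
  # explained variance: non-increasing, sums to 1, matches eigenvalues
  expect_true(all(diff(pr2$explained_variance) <= 1e-12))
  expect_equal(sum(pr2$explained_variance), 1)
  expect_equal(pr2$explained_variance,
               pmax(ev$values, 0) / sum(pmax(ev$values, 0)))
  expect_error(pca_reconstruct(x, 0), "k")
  expect_error(pca_reconstruct(x, 4), "k")
})

test_that("top-k retains more variance than any other k-subset (Eckart-Young)", {
  set.seed(4)
  x <- matrix(rexp(48), 8, 6)
  ev <- pca_reconstruct(x, 3)$explained_variance
  top <- sum(ev[1:3])
  other <- combn(6, 3, function(s) sum(ev[s]))
  expect_true(all(top >= other - 1e-12))
})

test_that("the identity configuration reproduces the input stack", {
  meta <- tiny_meta(8)
  set.seed(5)
  st <- stack_from_matrix(matrix(rpois(20 * 8, 6), 20, 8), c(4, 5), meta)
  cfg <- denoise_config(n_components = 8, nc_scheme = "none",
                        clip_negative = FALSE, threshold = 0)
  out <- nc_pca_denoise(st, cfg)
  expect_all_equal(out$reconstructed$counts, st$counts, tol = 1e-8)
})

test_that("a noise-free single-lifetime stack is reproduced with k = 1", {
  st <- mono_stack(2.5, total = 300, shape = c(6, 6))
  out <- nc_pca_denoise(st, denoise_config(n_components = 1))
  expect_lt(max(abs(out$reconstructed$counts - st$counts)) / max(st$counts),
            1e-6)
})

test_that("NC-PCA with default k = 3 improves the median SNR on the phantom", {
  sim <- simulate_phantom(shape = c(96, 96), count_level = 200, seed = 9)
  cfg <- denoise_config()
  expect_equal(cfg$n_components, 3L)
  den <- nc_pca_denoise(sim$noisy, cfg)
  raw_maps <- pixel_snr_mse(sim$noisy, sim$truth)
  rec_maps <- pixel_snr_mse(den$reconstructed, sim$truth)
  expect_gt(snr_ratio(rec_maps, raw_maps), 0)
  expect_lt(mse_ratio(rec_maps, raw_maps), 1)
  # tidy/glance expose the variance bookkeeping
  td <- tidy(den)
  expect_equal(sum(td$retained), 3)
  expect_equal(glance(den)$variance_retained,
               sum(den$explained_variance[1:3]))
})

test_that("reconstructed decays are non-increasing at the 95% level", {
  sim <- simulate_phantom(shape = c(64, 64), count_level = 200, seed = 13)
  den <- nc_pca_denoise(sim$noisy)
  x <- flatten(den$reconstructed)
  lab <- as.vector(t(sim$phantom$labels))
  x <- x[lab > 0, , drop = FALSE]
  # smooth each trace, then ask that >=95% of steps are non-increasing
  # (up to a 0.1%-of-peak slack for residual ripple)
  frac_mono <- mean(vapply(seq_len(nrow(x)), function(i) {
    sm <- stats::filter(x[i, ], rep(1 / 21, 21), sides = 2)
    sm <- sm[!is.na(sm)]
    mean(diff(sm) <= 1e-3 * max(sm)) >= 0.95
  }, logical(1)))
  expect_gt(frac_mono, 0.95)
})

test_that("total-count thresholding uses at-or-below semantics", {
  meta <- tiny_meta(3)
  x <- rbind(c(2, 2, 1), c(5, 3, 2), c(6, 4, 2))  # totals 5, 10, 12
  st <- stack_from_matrix(x, c(1, 3), meta)
  th <- threshold_total_counts(st, 10)
  tot <- total_counts(th)
  expect_equal(as.vector(t(tot)), c(0, 0, 12))
  # theta = 0 on a strictly positive stack is the identity
  expect_identical(threshold_total_counts(st, 0)$counts, st$counts)
  # theta = max total zeroes the whole image
  expect_true(all(threshold_total_counts(st, 12)$counts == 0))
})

test_that("median filtering matches a brute-force windowed median", {
  meta <- tiny_meta(4)
  # field with one outlier in an otherwise constant G map
  x <- matrix(10, 9, 4)
  st <- stack_from_matrix(x, c(3, 3), meta)
  pf <- phasor_transform(st)
  pf$G[2, 2] <- 99
  f1 <- median_filter_phasor(pf, 1)
  expect_equal(f1$G, pf$G)  # kernel 1 is the identity
  f3 <- median_filter_phasor(pf, 3)
  expect_equal(f3$G[2, 2], pf$G[1, 1])
  expect_error(median_filter_phasor(pf, 4), "odd")

  # 5x5 ramp against explicit per-window sorting
  m <- matrix(seq_len(25) + 0.5, 5, 5)
  got <- flimpca:::masked_median_filter(m, 3)
  want <- matrix(NA_real_, 5, 5)
  for (r in 1:5) for (c in 1:5) {
    rs <- max(1, r - 1):min(5, r + 1)
    cs <- max(1, c - 1):min(5, c + 1)
    want[r, c] <- median(sort(as.vector(m[rs, cs])))
  }
  expect_equal(got, want)

  # masked pixels are excluded and stay masked
  mm <- m; mm[3, 3] <- NA
  gm <- flimpca:::masked_median_filter(mm, 3)
  expect_true(is.na(gm[3, 3]))
  expect_equal(gm[2, 2], median(as.vector(mm[1:3, 1:3]), na.rm = TRUE))

  # histogram mode filters counts and re-derives the peak
  ph <- phasor_histogram(phasor_transform(mono_stack(2.0)), bins = 16)
  hf <- median_filter_phasor(ph, 3)
  expect_equal(attr(hf, "median_filter")$mode, "histogram")
})
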