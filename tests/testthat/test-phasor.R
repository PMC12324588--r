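test_that("phasors of noise-free mono-exponentials match the closed form", {
  meta <- flim_meta(256, period = 12.5)
  w <- 2 * pi / 12.5
  for (tau in c(0.4, 1, 2.5, 3.4)) {
    pf <- phasor_transform(mono_stack(tau, meta = meta))
    g <- pf$G[1, 1]; s <- pf$S[1, 1]
    expect_lt(abs(g - 1 / (1 + (w * tau)^2)), 1e-3)
    expect_lt(abs(s - w * tau / (1 + (w * tau)^2)), 1e-3)
    # universal semicircle identity
    expect_lt(abs((g - 0.5)^2 + s^2 - 0.25), 1e-3)
  }
})

test_that("short-lifetime limit approaches (G, S) = (1, 0)", {
  meta <- flim_meta(4096, period = 12.5)
  pf <- phasor_transform(mono_stack(0.005, meta = meta, shape = c(1, 1)))
  expect_equal(pf$G[1, 1], 1, tolerance = 1e-2)
  expect_equal(pf$S[1, 1], 0, tolerance = 1e-1)
})

test_that("zero-total pixels are masked, not errored", {
  meta <- tiny_meta(4)
  x <- rbind(c(4, 2, 1, 1), rep(0, 4))
  pf <- phasor_transform(stack_from_matrix(x, c(1, 2), meta))
  expect_true(pf$mask[1, 1])
  expect_false(pf$mask[1, 2])
  expect_true(is.na(pf$G[1, 2]))
})

test_that("a mixed decay lands at the intensity-weighted phasor combination", {
  meta <- flim_meta(256, period = 12.5)
  t1 <- mono_stack(0.8, total = 150, shape = c(1, 1), meta = meta)
  t2 <- mono_stack(3.2, total = 50, shape = c(1, 1), meta = meta)
  mix <- flim_stack(t1$counts + t2$counts, meta)
  pm <- phasor_transform(mix)
  p1 <- phasor_transform(t1); p2 <- phasor_transform(t2)
  wgt <- 150 / 200
  expect_equal(pm$G[1, 1], wgt * p1$G[1, 1] + (1 - wgt) * p2$G[1, 1],
               tolerance = 1e-6)
  expect_equal(pm$S[1, 1], wgt * p1$S[1, 1] + (1 - wgt) * p2$S[1, 1],
               tolerance = 1e-6)
})

test_that("calibration maps the reference onto its theoretical point", {
  meta <- flim_meta(256, period = 12.5)
  ref <- phasor_transform(mono_stack(2.5, shape = c(3, 3), meta = meta))
  fld <- phasor_transform(mono_stack(1.0, shape = c(3, 3), meta = meta))
  # reference already at its theoretical point: identity factor
  cal <- calibrate(fld, ref, tau_ref = 2.5)
  expect_equal(attr(cal, "calibration")$modulation_ratio, 1, tolerance = 1e-3)
  expect_equal(attr(cal, "calibration")$phase_shift, 0, tolerance = 1e-3)
  # rotate both field and reference by a known phase; calibration undoes it
  rot <- function(pf, phi) {
    z <- complex(real = pf$G, imaginary = pf$S) * exp(1i * phi)
    pf$G <- matrix(Re(z), nrow(pf$G)); pf$S <- matrix(Im(z), nrow(pf$S))
    pf
  }
  phi <- 0.42
  cal2 <- calibrate(rot(fld, phi), rot(ref, phi), tau_ref = 2.5)
  expect_all_equal(cal2$G, cal$G, tol = 1e-9)
  expect_all_equal(cal2$S, cal$S, tol = 1e-9)
  # intensity and mask are untouched
  expect_identical(cal2$intensity, fld$intensity)
  expect_identical(cal2$mask, fld$mask)
  empty <- fld; empty$mask[] <- FALSE
  expect_error(calibrate(fld, empty, 2.5), "valid")
})

test_that("phasor histogram conserves counts and locates delta populations", {
  meta <- flim_meta(256, period = 12.5)
  pf <- phasor_transform(mono_stack(2.0, shape = c(5, 4), meta = meta))
  h <- phasor_histogram(pf, bins = 64)
  expect_equal(sum(h$counts) + h$overflow, 20)
  expect_equal(sum(h$counts > 0), 1)  # all pixels identical -> one bin
  th <- phasor_of_lifetime(2.0, meta)
  expect_equal(unname(h$peak["G"]), unname(th["G"]), tolerance = 1 / 64)
  # two delta populations -> exactly two nonzero bins
  x1 <- flatten(mono_stack(0.8, shape = c(2, 2), meta = meta))
  x2 <- flatten(mono_stack(3.2, shape = c(2, 2), meta = meta))
  both <- stack_from_matrix(rbind(x1, x2), c(2, 4), meta)
  h2 <- phasor_histogram(phasor_transform(both), bins = 64)
  expect_equal(sum(h2$counts > 0), 2)
  # out-of-range pixels land in the overflow tally
  h3 <- phasor_histogram(pf, g_range = c(0.9, 1), bins = 16)
  expect_equal(h3$overflow, 20)
})

test_that("FWHM estimators agree with Gaussian and triangular oracles", {
  gc <- seq(0, 1, length.out = 257)[-1] - 1 / 512
  mkhist <- function(y) {
    structure(list(counts = matrix(y, ncol = 1), g_centers = gc,
                   s_centers = 0.3, g_edges = seq(0, 1, length.out = 257),
                   s_edges = c(0, 0.6), peak = c(G = gc[which.max(y)], S = 0.3),
                   overflow = 0, n_valid = sum(y)), class = "phasor_histogram")
  }
  # exact Gaussian, sigma = 0.05 -> FWHM = 2.3548 * 0.05
  yg <- 1000 * exp(-(gc - 0.5)^2 / (2 * 0.05^2))
  expect_equal(as.numeric(fwhm_profile(mkhist(yg), "G", "interp")),
               2 * sqrt(2 * log(2)) * 0.05, tolerance = 0.01)
  expect_equal(as.numeric(fwhm_profile(mkhist(yg), "G", "gaussian")),
               2 * sqrt(2 * log(2)) * 0.05, tolerance = 0.01)
  # triangular profile of half-width w: interp FWHM = w
  wtri <- 0.2
  yt <- pmax(1 - abs(gc - 0.5) / wtri, 0) * 500
  expect_equal(as.numeric(fwhm_profile(mkhist(yt), "G", "interp")), wtri,
               tolerance = 0.01)
  # single-bin spike reports one bin width by convention
  ys <- rep(0, 256); ys[128] <- 10
  expect_equal(as.numeric(fwhm_profile(mkhist(ys), "G", "interp")), 1 / 256,
               tolerance = 1e-6)
  # the two estimators agree on a well-sampled unimodal profile
  f1 <- as.numeric(fwhm_profile(mkhist(yg), "G", "interp"))
  f2 <- as.numeric(fwhm_profile(mkhist(yg), "G", "gaussian"))
  expect_lt(abs(f1 - f2) / f1, 0.05)
})

test_that("separation distance is the symmetric G-peak difference", {
  meta <- flim_meta(256, period = 12.5)
  taus <- lifetimes_for_separation(0.31, 0.40, meta)
  h1 <- phasor_histogram(phasor_transform(mono_stack(taus[1], meta = meta)))
  h2 <- phasor_histogram(phasor_transform(mono_stack(taus[2], meta = meta)))
  expect_lt(abs(separation_distance(h1, h2) - 0.31), 1 / 256)
  expect_equal(separation_distance(h1, h2), separation_distance(h2, h1))
  expect_equal(separation_distance(h1, h1), 0)
})

test_that("fraction bound is 0/0.5/1 at the free point, midpoint and bound point", {
  meta <- flim_meta(256, period = 12.5)
  pars <- fb_params()
  p_free <- phasor_of_lifetime(pars$tau_free, meta)
  p_bound <- phasor_of_lifetime(pars$tau_bound, meta)
  mid <- (p_free + p_bound) / 2
  fld <- phasor_transform(mono_stack(2.0, shape = c(1, 3), meta = meta))
  fld$G[1, ] <- c(p_free["G"], mid["G"], p_bound["G"])
  fld$S[1, ] <- c(p_free["S"], mid["S"], p_bound["S"])
  fb <- fraction_bound(fld, pars)
  expect_equal(as.vector(fb), c(0, 0.5, 1), tolerance = 1e-12)
  # clamping pins noisy excursions into [0, 1] but keeps the raw values
  fld$G[1, 1] <- p_free["G"] - 0.2 * (p_bound["G"] - p_free["G"])
  fld$S[1, 1] <- p_free["S"] - 0.2 * (p_bound["S"] - p_free["S"])
  fb2 <- fraction_bound(fld, pars)
  expect_equal(fb2[1, 1], 0)
  expect_lt(attr(fb2, "unclamped")[1, 1], 0)
  fb3 <- fraction_bound(fld, fb_params(clamp = FALSE))
  expect_lt(fb3[1, 1], 0)
})

test_that("average phasor supports unweighted and intensity weighting", {
  meta <- tiny_meta(4)
  x <- rbind(c(4, 2, 1, 1), c(40, 20, 10, 10))
  pf <- phasor_transform(stack_from_matrix(x, c(1, 2), meta))
  pf$G[] <- c(0.4, 0.6); pf$S[] <- c(0.3, 0.5)
  un <- average_phasor(pf)
  expect_equal(unname(un), c(0.5, 0.4))
  wt <- average_phasor(pf, "intensity")
  expect_equal(unname(wt["G"]), (8 * 0.4 + 80 * 0.6) / 88)
  expect_equal(unname(wt["S"]), (8 * 0.3 + 80 * 0.5) / 88)
  pf$mask[] <- FALSE
  expect_error(average_phasor(pf), "valid")
})
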