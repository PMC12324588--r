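# Phasor analysis: the (G, S) transform of per-pixel decays, calibration
# against a single-lifetime reference, 2D histogram analytics (peak, FWHM,
# separation) and the NADH fraction-bound projection.
#
# With omega = 2*pi*harmonic / period and t_j the bin centers,
#   G = sum_j I_j cos(omega t_j) / sum_j I_j
#   S = sum_j I_j sin(omega t_j) / sum_j I_j.
# A mono-exponential decay of lifetime tau sits on the universal semicircle
# at G = 1/(1 + (omega tau)^2), S = omega tau / (1 + (omega tau)^2).

#' Theoretical phasor of a mono-exponential lifetime
#'
#' @param tau Lifetime in ns.
#' @param meta A [flim_meta()] supplying period and harmonic.
#' @return Named vector `c(G, S)` on the universal semicircle.
#' @export
phasor_of_lifetime <- function(tau, meta) {
  w <- 2 * pi * meta$harmonic / meta$period
  c(G = 1 / (1 + (w * tau)^2), S = w * tau / (1 + (w * tau)^2))
}

#' Phasor transform of a FLIM stack
#'
#' Maps every pixel decay onto its first-harmonic (or `harmonic`-th) Fourier
#' coordinates (G, S), normalized by the pixel's total counts.  Pixels with
#' zero total counts carry no phasor and are masked, not errored.
#'
#' @param stack A [flim_stack()].
#' @param harmonic Harmonic n >= 1; defaults to the stack metadata's value.
#' @return An object of class `phasor_field`: matrices `G`, `S`,
#'   `intensity` (total counts), logical `mask`, plus `harmonic` and `meta`.
#' @examples
#' ph <- make_phantom(shape = c(32, 32))
#' pf <- phasor_transform(render_ground_truth(ph))
#' range(pf$G[pf$mask])
#' @export
phasor_transform <- function(stack, harmonic = NULL) {
  stopifnot(inherits(stack, "flim_stack"))
  meta <- stack$meta
  if (is.null(harmonic)) harmonic <- meta$harmonic
  harmonic <- as.integer(harmonic)
  stopifnot(harmonic >= 1)
  w <- 2 * pi * harmonic / meta$period
  t_j <- bin_centers(meta)
  x <- flatten(stack)
  tot <- rowSums(x)
  ok <- tot > 0
  g <- s <- rep(NA_real_, length(tot))
  g[ok] <- (x[ok, , drop = FALSE] %*% cos(w * t_j)) / tot[ok]
  s[ok] <- (x[ok, , drop = FALSE] %*% sin(w * t_j)) / tot[ok]
  pd <- attr(x, "pixdim")
  tom <- function(v) matrix(v, pd[1], pd[2], byrow = TRUE)  # row-major back
  structure(list(G = tom(g), S = tom(s), intensity = tom(tot),
                 mask = tom(ok), harmonic = harmonic, meta = meta),
            class = "phasor_field")
}

#' @export
print.phasor_field <- function(x, ...) {
  cat(sprintf("<phasor_field> %d x %d, %d valid pixels, harmonic %d\n",
              nrow(x$G), ncol(x$G), sum(x$mask), x$harmonic))
  invisible(x)
}

#' Tidy a phasor field into a per-pixel tibble
#'
#' @param x A `phasor_field`.
#' @param ... Unused.
#' @return A tibble with `row`, `col`, `G`, `S`, `intensity` for valid
#'   pixels.
#' @export
tidy.phasor_field <- function(x, ...) {
  idx <- which(x$mask, arr.ind = TRUE)
  tibble::tibble(row = idx[, 1], col = idx[, 2],
                 G = x$G[idx], S = x$S[idx], intensity = x$intensity[idx])
}

#' Calibrate a phasor field against a single-lifetime reference
#'
#' Computes the complex factor (a phase rotation plus modulation scaling)
#' that maps the reference field's median phasor onto the theoretical
#' semicircle point of `tau_ref`, then applies that factor to every phasor
#' in `field`.  Intensity and mask are preserved exactly.
#'
#' @param field Phasor field to calibrate.
#' @param reference Phasor field of a spatially uniform single-lifetime
#'   sample (e.g. a calibration dye).
#' @param tau_ref Known lifetime of the reference in ns.
#' @return The calibrated `phasor_field`, with attribute `calibration`
#'   (list of `phase_shift` in radians and `modulation_ratio`).
#' @export
calibrate <- function(field, reference, tau_ref) {
  stopifnot(inherits(field, "phasor_field"), inherits(reference, "phasor_field"))
  if (!any(reference$mask)) stop("reference has no valid pixels", call. = FALSE)
  med <- complex(real = stats::median(reference$G[reference$mask]),
                 imaginary = stats::median(reference$S[reference$mask]))
  if (Mod(med) == 0) stop("reference median phasor is zero", call. = FALSE)
  th <- phasor_of_lifetime(tau_ref, reference$meta)
  fac <- complex(real = th["G"], imaginary = th["S"]) / med
  z <- complex(real = field$G, imaginary = field$S) * fac
  field$G <- matrix(Re(z), nrow(field$G), ncol(field$G))
  field$S <- matrix(Im(z), nrow(field$S), ncol(field$S))
  attr(field, "calibration") <- list(phase_shift = Arg(fac),
                                     modulation_ratio = Mod(fac))
  field
}

#' 2D phasor histogram
#'
#' Bins the valid pixels of a phasor field on a regular (G, S) grid.
#' Out-of-range pixels are tallied in `overflow`, never silently dropped,
#' so `sum(counts) + overflow` equals the number of valid pixels.
#'
#' @param field A `phasor_field`.
#' @param g_range,s_range Axis limits (defaults G in \[0, 1\], S in
#'   \[0, 0.6\]).
#' @param bins Bins per axis (default 256).
#' @return An object of class `phasor_histogram`: `counts` (G-bin x S-bin),
#'   `g_edges`, `s_edges`, `g_centers`, `s_centers`, `peak` (G, S of the
#'   maximum-count bin), `overflow`, `n_valid`.
#' @export
phasor_histogram <- function(field, g_range = c(0, 1), s_range = c(0, 0.6),
                             bins = 256L) {
  stopifnot(inherits(field, "phasor_field"), bins >= 2)
  g <- field$G[field$mask]; s <- field$S[field$mask]
  g_edges <- seq(g_range[1], g_range[2], length.out = bins + 1)
  s_edges <- seq(s_range[1], s_range[2], length.out = bins + 1)
  gi <- findInterval(g, g_edges, rightmost.closed = TRUE)
  si <- findInterval(s, s_edges, rightmost.closed = TRUE)
  inside <- gi >= 1 & gi <= bins & si >= 1 & si <= bins
  counts <- matrix(0L, bins, bins)
  if (any(inside)) {
    tab <- table(factor(gi[inside], levels = seq_len(bins)),
                 factor(si[inside], levels = seq_len(bins)))
    counts <- matrix(as.integer(tab), bins, bins)
  }
  g_centers <- (g_edges[-1] + g_edges[-(bins + 1)]) / 2
  s_centers <- (s_edges[-1] + s_edges[-(bins + 1)]) / 2
  pk <- arrayInd(which.max(counts), dim(counts))
  structure(
    list(counts = counts, g_edges = g_edges, s_edges = s_edges,
         g_centers = g_centers, s_centers = s_centers,
         peak = c(G = g_centers[pk[1]], S = s_centers[pk[2]]),
         overflow = sum(!inside), n_valid = length(g)),
    class = "phasor_histogram")
}

#' @export
print.phasor_histogram <- function(x, ...) {
  cat(sprintf(
    "<phasor_histogram> %d x %d bins, %d pixels (%d overflow), peak (%.3f, %.3f)\n",
    nrow(x$counts), ncol(x$counts), x$n_valid, x$overflow,
    x$peak["G"], x$peak["S"]))
  invisible(x)
}

# 1D profile through the maximum-count bin of a 2D histogram.
profile_through_peak <- function(hist, axis = c("G", "S")) {
  axis <- match.arg(axis)
  pk <- arrayInd(which.max(hist$counts), dim(hist$counts))
  if (axis == "G")
    list(x = hist$g_centers, y = hist$counts[, pk[2]])
  else
    list(x = hist$s_centers, y = hist$counts[pk[1], ])
}

# FWHM of a sampled 1D profile by linear interpolation of the two
# half-maximum crossings around the peak.
fwhm_interp <- function(x, y) {
  i0 <- which.max(y)
  half <- y[i0] / 2
  bw <- if (length(x) > 1) x[2] - x[1] else 1
  left <- NA_real_; right <- NA_real_
  if (i0 > 1) {
    below <- which(y[seq_len(i0 - 1)] < half)
    if (length(below)) {
      i <- max(below)  # crossing between i and i+1
      left <- x[i] + (half - y[i]) / (y[i + 1] - y[i]) * (x[i + 1] - x[i])
    }
  }
  if (i0 < length(y)) {
    below <- which(y[seq(i0 + 1, length(y))] < half) + i0
    if (length(below)) {
      i <- min(below)  # crossing between i-1 and i
      right <- x[i - 1] + (y[i - 1] - half) / (y[i - 1] - y[i]) * (x[i] - x[i - 1])
    }
  }
  if (is.na(left) && is.na(right))
    return(structure(bw, one_sided = TRUE))  # single-bin spike convention
  if (is.na(left))  return(structure(2 * (right - x[i0]), one_sided = TRUE))
  if (is.na(right)) return(structure(2 * (x[i0] - left), one_sided = TRUE))
  structure(right - left, one_sided = FALSE)
}

# Least-squares Gaussian fit; FWHM = 2*sqrt(2*log(2)) * sigma.
fwhm_gaussian <- function(x, y) {
  i0 <- which.max(y)
  w <- sum(y > max(y) / 2) * (if (length(x) > 1) x[2] - x[1] else 1)
  start <- list(a = max(y), mu = x[i0], sigma = max(w / 2.3548, 1e-6))
  fit <- try(minpack.lm::nlsLM(
    y ~ a * exp(-(x - mu)^2 / (2 * sigma^2)),
    data = data.frame(x = x, y = y), start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(fwhm_interp(x, y))
  2 * sqrt(2 * log(2)) * abs(stats::coef(fit)[["sigma"]])
}

#' Full width at half maximum of a phasor-histogram profile
#'
#' Extracts the 1D count profile through the maximum-count bin along the
#' chosen axis and measures its FWHM, either by linear interpolation of the
#' half-maximum crossings (`"interp"`) or by a least-squares Gaussian fit
#' (`"gaussian"`).  If the profile never falls below half maximum on one
#' side, the width is doubled from the available side and flagged with
#' attribute `one_sided`.  A single-bin spike reports one bin width.
#'
#' @param hist A [phasor_histogram()] with a nonzero peak.
#' @param axis `"G"` or `"S"`.
#' @param method `"interp"` (default) or `"gaussian"`.
#' @return FWHM in axis units.
#' @export
fwhm_profile <- function(hist, axis = c("G", "S"),
                         method = c("interp", "gaussian")) {
  stopifnot(inherits(hist, "phasor_histogram"))
  axis <- match.arg(axis); method <- match.arg(method)
  pr <- profile_through_peak(hist, axis)
  if (max(pr$y) <= 0) stop("histogram has no nonzero peak", call. = FALSE)
  if (method == "interp") fwhm_interp(pr$x, pr$y) else fwhm_gaussian(pr$x, pr$y)
}

#' G-axis separation of two phasor histograms
#'
#' The absolute difference of the G coordinates (bin centers) of the two
#' histograms' maximum-count bins - the working definition of the distance
#' between two lifetime states on the phasor plot.
#'
#' @param hist_a,hist_b [phasor_histogram()] objects with nonzero peaks.
#' @return `|G_peak(A) - G_peak(B)|`.
#' @export
separation_distance <- function(hist_a, hist_b) {
  stopifnot(inherits(hist_a, "phasor_histogram"),
            inherits(hist_b, "phasor_histogram"))
  if (max(hist_a$counts) <= 0 || max(hist_b$counts) <= 0)
    stop("both histograms need a nonzero peak", call. = FALSE)
  unname(abs(hist_a$peak["G"] - hist_b$peak["G"]))
}

#' Fraction-bound parameters for NADH phasor mapping
#'
#' @param tau_free Lifetime of free NADH in ns (default 0.4).
#' @param tau_bound Lifetime of protein-bound NADH in ns (default 3.4).
#' @param clamp Clamp the per-pixel fraction to \[0, 1\] (default `TRUE`);
#'   values outside that range are not physically possible and arise only
#'   from noise.
#' @return An object of class `fb_params`.
#' @export
fb_params <- function(tau_free = 0.4, tau_bound = 3.4, clamp = TRUE) {
  stopifnot(tau_free > 0, tau_bound > 0, tau_free != tau_bound)
  structure(list(tau_free = tau_free, tau_bound = tau_bound,
                 clamp = isTRUE(clamp)), class = "fb_params")
}

#' Per-pixel NADH fraction bound
#'
#' Projects each pixel's phasor onto the chord joining the theoretical
#' semicircle points of the free and bound NADH lifetimes (scalar projection
#' normalized by the chord length), so `fB = 0` at the free point and
#' `fB = 1` at the bound point, with mixtures falling linearly in between.
#'
#' @param field A calibrated `phasor_field`.
#' @param params An [fb_params()].
#' @return Matrix of per-pixel fB (NA where masked).  When clamping is on,
#'   the pre-clamp values are attached as attribute `unclamped` for QC.
#' @export
fraction_bound <- function(field, params = fb_params()) {
  stopifnot(inherits(field, "phasor_field"), inherits(params, "fb_params"))
  p_free <- phasor_of_lifetime(params$tau_free, field$meta)
  p_bound <- phasor_of_lifetime(params$tau_bound, field$meta)
  chord <- p_bound - p_free
  len2 <- sum(chord^2)
  fb <- ((field$G - p_free["G"]) * chord["G"] +
         (field$S - p_free["S"]) * chord["S"]) / len2
  fb[!field$mask] <- NA_real_
  if (params$clamp) {
    raw <- fb
    fb <- pmin(pmax(fb, 0), 1)
    attr(fb, "unclamped") <- raw
  }
  fb
}

#' Average phasor of a field
#'
#' Collapses a phasor field to a single (G, S) pair, either as the plain
#' arithmetic mean over valid pixels (default) or weighted by pixel
#' intensity.
#'
#' @param field A `phasor_field` with at least one valid pixel.
#' @param weighting `"unweighted"` or `"intensity"`.
#' @return Named vector `c(G, S)`.
#' @export
average_phasor <- function(field, weighting = c("unweighted", "intensity")) {
  stopifnot(inherits(field, "phasor_field"))
  weighting <- match.arg(weighting)
  if (!any(field$mask)) stop("no valid pixels to average", call. = FALSE)
  g <- field$G[field$mask]; s <- field$S[field$mask]
  if (weighting == "unweighted") {
    c(G = mean(g), S = mean(s))
  } else {
    w <- field$intensity[field$mask]
    c(G = sum(w * g) / sum(w), S = sum(w * s) / sum(w))
  }
}
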