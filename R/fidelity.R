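# Ground-truth fidelity metrics: per-pixel SNR (dB) and MSE maps across all
# time bins, their median-based ratio summaries, boxplot-style distribution
# summaries, and the data-preservation map that quantifies what phasor
# averaging would destroy.

#' Per-pixel SNR and MSE maps against a ground truth
#'
#' For each pixel, with `s` the ground-truth trace and `x` the test trace
#' over the N time bins:
#' `MSE = mean((x - s)^2)` and `SNR_dB = 10*log10(sum(s^2) / sum((x - s)^2))`
#' (signal energy over residual energy).  SNR is only defined where the
#' truth has nonzero energy; zero-residual pixels report a capped SNR of
#' +120 dB and are flagged.
#'
#' @param test,truth [flim_stack()] objects of identical shape and
#'   metadata.
#' @param snr_cap Cap in dB for (near-)zero-residual pixels (default 120).
#' @return An object of class `fidelity_maps`: matrices `snr_db`, `mse`,
#'   logical `valid` (truth energy > 0) and `capped`.
#' @export
pixel_snr_mse <- function(test, truth, snr_cap = 120) {
  stopifnot(inherits(test, "flim_stack"), inherits(truth, "flim_stack"))
  if (!identical(dim(test$counts), dim(truth$counts)))
    stop("test and truth stacks have different shapes", call. = FALSE)
  if (test$meta$n_bins != truth$meta$n_bins ||
      abs(test$meta$period - truth$meta$period) > 1e-9)
    stop("test and truth stacks have different metadata", call. = FALSE)
  d <- dim(test$counts)
  n <- d[3]
  # accumulate bin by bin: O(rows x cols) working memory even for large stacks
  sse <- sig2 <- matrix(0, d[1], d[2])
  for (j in seq_len(n)) {
    sj <- truth$counts[, , j]
    sse <- sse + (test$counts[, , j] - sj)^2
    sig2 <- sig2 + sj^2
  }
  mse <- sse / n
  valid <- sig2 > 0
  snr <- matrix(NA_real_, d[1], d[2])
  ok <- valid & sse > 0
  snr[ok] <- 10 * log10(sig2[ok] / sse[ok])
  capped <- valid & (!ok | snr > snr_cap)
  snr[capped] <- snr_cap
  snr[valid & snr > snr_cap] <- snr_cap
  structure(list(snr_db = snr, mse = mse, valid = valid, capped = capped),
            class = "fidelity_maps")
}

#' @export
print.fidelity_maps <- function(x, ...) {
  cat(sprintf(
    "<fidelity_maps> %d x %d; median SNR %.3g dB (%d valid), median MSE %.3g\n",
    nrow(x$mse), ncol(x$mse), stats::median(x$snr_db[x$valid]),
    sum(x$valid), stats::median(x$mse)))
  invisible(x)
}

#' SNR improvement ratio between two fidelity maps
#'
#' The difference (in dB) between the median per-pixel SNR of the test
#' reconstruction and that of the raw data, both over the same valid mask.
#'
#' @param test_maps,raw_maps [pixel_snr_mse()] results with identical
#'   valid masks.
#' @return SNR ratio in dB (positive means the test improves on raw).
#' @export
snr_ratio <- function(test_maps, raw_maps) {
  stopifnot(inherits(test_maps, "fidelity_maps"),
            inherits(raw_maps, "fidelity_maps"))
  if (!identical(test_maps$valid, raw_maps$valid))
    stop("fidelity maps have different valid masks", call. = FALSE)
  if (!any(test_maps$valid)) stop("no valid pixels", call. = FALSE)
  stats::median(test_maps$snr_db[test_maps$valid]) -
    stats::median(raw_maps$snr_db[raw_maps$valid])
}

#' MSE improvement ratio between two fidelity maps
#'
#' Median per-pixel MSE of the test reconstruction divided by that of the
#' raw data (all pixels); values below 1 mean improvement.
#'
#' @inheritParams snr_ratio
#' @return Dimensionless ratio.
#' @export
mse_ratio <- function(test_maps, raw_maps) {
  stopifnot(inherits(test_maps, "fidelity_maps"),
            inherits(raw_maps, "fidelity_maps"))
  denom <- stats::median(raw_maps$mse)
  if (denom <= 0) stop("raw median MSE is zero", call. = FALSE)
  stats::median(test_maps$mse) / denom
}

#' Data-preservation map under single-point phasor averaging
#'
#' If a per-pixel map (G or fraction bound) were collapsed to its mean, a
#' pixel "preserves" its value only if it already sits within `tolerance`
#' of that mean.  Returns the boolean map and the preserved fraction - the
#' quantity that exposes how much information single-point averaging
#' discards.
#'
#' @param values Numeric matrix (NA = invalid pixel).
#' @param tolerance Half-width of the preservation band in axis units;
#'   default one histogram bin of the unit G axis, 1/256.
#' @return List with `mask` (logical matrix, NA where invalid) and
#'   `preserved_fraction`.
#' @export
preservation_map <- function(values, tolerance = 1 / 256) {
  stopifnot(is.matrix(values) || is.numeric(values), tolerance >= 0)
  v <- as.matrix(values)
  ok <- is.finite(v)
  if (!any(ok)) stop("no valid pixels", call. = FALSE)
  vbar <- mean(v[ok])
  keep <- abs(v - vbar) <= tolerance
  keep[!ok] <- NA
  list(mask = keep, preserved_fraction = mean(keep[ok]))
}

#' Boxplot-style distribution summary
#'
#' Median, mean, SD (n-1 denominator), linearly interpolated quartiles and
#' 1.5 x IQR whiskers of a sample.  A single observation reports SD = 0 and
#' is flagged.
#'
#' @param values Numeric vector (NAs dropped); must leave n >= 1.
#' @return A one-row tibble with `n`, `median`, `mean`, `sd`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`, `sd_defined`.
#' @export
summarize_distribution <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 1) stop("empty input", call. = FALSE)
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr; hi <- q[3] + 1.5 * iqr
  sd_def <- length(v) > 1
  tibble::tibble(
    n = length(v), median = q[2], mean = mean(v),
    sd = if (sd_def) stats::sd(v) else 0,
    q1 = q[1], q3 = q[3],
    whisker_low = min(v[v >= lo]), whisker_high = max(v[v <= hi]),
    sd_defined = sd_def)
}

#' Regression slope through per-condition median pairs
#'
#' Ordinary least-squares line through `(x, y)` median pairs; a slope near
#' 1 indicates that medians are preserved across analysis methods.
#'
#' @param x_medians,y_medians Numeric vectors of equal length >= 2.
#' @return Named vector `c(slope, intercept)`.
#' @export
median_slope <- function(x_medians, y_medians) {
  if (length(x_medians) < 2 || length(x_medians) != length(y_medians))
    stop("need >= 2 (x, y) pairs of equal length", call. = FALSE)
  co <- stats::coef(stats::lm(y_medians ~ x_medians))
  c(slope = unname(co[2]), intercept = unname(co[1]))
}
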