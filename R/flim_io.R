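# Containers and I/O for time-domain FLIM photon-count stacks.
#
# A stack is a 3D array indexed (row, col, bin) of photon counts plus
# acquisition metadata.  Time bins tile exactly one laser repetition period;
# bin j (0-based) spans [j*dt, (j+1)*dt) and all trigonometric/decay kernels
# are evaluated at bin centers (j + 0.5)*dt to reduce discretization bias.

#' Acquisition metadata for a FLIM stack
#'
#' Describes the temporal axis of a time-correlated single-photon counting
#' (TCSPC) acquisition: the number of time bins, the bin width, the laser
#' repetition period and the phasor harmonic.  Bins are assumed to tile
#' exactly one repetition period, so `period == n_bins * bin_width`; supply
#' either `bin_width` or `period` and the other is derived.
#'
#' @param n_bins Number of time bins (>= 2).
#' @param period Laser repetition period T in ns (e.g. 12.5 ns for an
#'   80 MHz Ti:Sapphire source).
#' @param bin_width Width of one time bin in ns.  Defaults to
#'   `period / n_bins`.
#' @param harmonic Positive integer phasor harmonic (default 1).
#' @param frames Accumulated frame count, informational only.
#' @return An object of class `flim_meta`.
#' @examples
#' flim_meta(n_bins = 256, period = 12.5)
#' @export
flim_meta <- function(n_bins, period = NULL, bin_width = NULL, harmonic = 1L,
                      frames = NA_integer_) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L)
    stop("`n_bins` must be an integer >= 2", call. = FALSE)
  if (is.null(period) && is.null(bin_width))
    stop("supply `period` or `bin_width`", call. = FALSE)
  if (is.null(bin_width)) bin_width <- period / n_bins
  if (is.null(period)) period <- bin_width * n_bins
  if (bin_width <= 0 || period <= 0)
    stop("`bin_width` and `period` must be positive", call. = FALSE)
  if (abs(period - n_bins * bin_width) > 1e-9 * period)
    stop("bins must tile one repetition period: period == n_bins * bin_width",
         call. = FALSE)
  harmonic <- as.integer(harmonic)
  if (is.na(harmonic) || harmonic < 1L)
    stop("`harmonic` must be a positive integer", call. = FALSE)
  structure(
    list(n_bins = n_bins, bin_width = bin_width, period = period,
         harmonic = harmonic, frames = frames),
    class = "flim_meta")
}

#' @export
print.flim_meta <- function(x, ...) {
  cat(sprintf("<flim_meta> %d bins x %.6g ns (period %.6g ns), harmonic %d\n",
              x$n_bins, x$bin_width, x$period, x$harmonic))
  invisible(x)
}

# Bin-center times t_j = (j + 0.5) * dt, j = 0 .. n_bins - 1 (ns).
bin_centers <- function(meta) (seq_len(meta$n_bins) - 0.5) * meta$bin_width

#' FLIM photon-count stack
#'
#' Bundles a 3D non-negative array of photon counts indexed (row, col, bin)
#' with its acquisition metadata.  Raw data carry integer counts;
#' reconstructions may carry non-negative reals.
#'
#' @param counts 3D numeric array, `dim[3]` must equal `meta$n_bins`; all
#'   entries finite and non-negative.
#' @param meta A [flim_meta()] object.
#' @return An object of class `flim_stack`.
#' @examples
#' meta <- flim_meta(n_bins = 4, period = 12.5)
#' flim_stack(array(1, c(2, 3, 4)), meta)
#' @export
flim_stack <- function(counts, meta) {
  if (!inherits(meta, "flim_meta")) stop("`meta` must be a flim_meta", call. = FALSE)
  if (!is.array(counts) || length(dim(counts)) != 3L)
    stop("`counts` must be a 3D array (row, col, bin)", call. = FALSE)
  if (dim(counts)[3] != meta$n_bins)
    stop(sprintf("stack has %d bins but meta declares %d",
                 dim(counts)[3], meta$n_bins), call. = FALSE)
  if (!all(is.finite(counts)))
    stop("stack contains non-finite values", call. = FALSE)
  if (min(counts) < 0)
    stop("photon counts must be non-negative", call. = FALSE)
  structure(list(counts = counts, meta = meta), class = "flim_stack")
}

#' @export
print.flim_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<flim_stack> %d x %d pixels, %d bins; total %.4g photons\n",
              d[1], d[2], d[3], sum(x$counts)))
  invisible(x)
}

#' @export
dim.flim_stack <- function(x) dim(x$counts)

#' Flatten a stack to its pixel-by-bin data matrix
#'
#' Returns the `n_pixels x n_bins` matrix whose row i is the decay trace of
#' pixel i in row-major (row varies slowest) order.  The original 2D shape is
#' attached so [unflatten()] is an exact inverse.
#'
#' @param stack A [flim_stack()].
#' @return A numeric matrix with attribute `pixdim = c(rows, cols)`.
#' @seealso [unflatten()]
#' @export
flatten <- function(stack) {
  stopifnot(inherits(stack, "flim_stack"))
  d <- dim(stack$counts)
  # aperm so that pixels enumerate row-major: pixel index = (r-1)*cols + c
  x <- aperm(stack$counts, c(2, 1, 3))
  dim(x) <- c(d[1] * d[2], d[3])
  attr(x, "pixdim") <- d[1:2]
  x
}

#' Rebuild a stack from a flattened data matrix
#'
#' @param x Matrix as returned by [flatten()] (row-major pixel order).
#' @param pixdim Length-2 integer `(rows, cols)`; defaults to the `pixdim`
#'   attribute of `x`.
#' @param meta A [flim_meta()] for the rebuilt stack.
#' @return A [flim_stack()].
#' @export
unflatten <- function(x, meta, pixdim = attr(x, "pixdim")) {
  if (is.null(pixdim)) stop("`pixdim` missing", call. = FALSE)
  if (nrow(x) != prod(pixdim))
    stop("matrix rows do not match pixdim", call. = FALSE)
  a <- aperm(array(x, dim = c(pixdim[2], pixdim[1], ncol(x))), c(2, 1, 3))
  flim_stack(a, meta)
}

#' Per-pixel total photon counts
#'
#' Sums each pixel's trace over all time bins.
#'
#' @param stack A [flim_stack()].
#' @return A rows x cols numeric matrix of totals.
#' @export
total_counts <- function(stack) {
  d <- dim(stack$counts)
  tot <- matrix(0, d[1], d[2])
  for (j in seq_len(d[3])) tot <- tot + stack$counts[, , j]
  tot
}

#' Read a multi-page TIFF time series as a FLIM stack
#'
#' Page j of the TIFF is time bin j.  TIFF tags carry no reliable FLIM
#' metadata, so acquisition metadata comes either from `meta` or from the
#' JSON sidecar `<path>.json` written by [write_stack()]; any TIFF tags are
#' ignored.
#'
#' @param path Path to a multi-page grayscale TIFF.
#' @param meta A [flim_meta()]; if `NULL`, read from the sidecar.
#' @return A [flim_stack()].
#' @export
read_stack <- function(path, meta = NULL) {
  sidecar <- paste0(path, ".json")
  scale <- 1
  fmt <- "uint16"
  if (is.null(meta)) {
    if (!file.exists(sidecar))
      stop("no `meta` given and no sidecar found at ", sidecar, call. = FALSE)
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    meta <- flim_meta(n_bins = sc$n_bins, period = sc$period_ns,
                      harmonic = sc$harmonic,
                      frames = if (is.null(sc$frames)) NA_integer_ else sc$frames)
    if (!is.null(sc$intensity_scale)) scale <- sc$intensity_scale
    if (!is.null(sc$pixel_format)) fmt <- sc$pixel_format
  } else if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(sc$intensity_scale)) scale <- sc$intensity_scale
    if (!is.null(sc$pixel_format)) fmt <- sc$pixel_format
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = (fmt == "uint16"))
  if (length(pages) != meta$n_bins)
    stop(sprintf("TIFF page count mismatch: expected %d pages, found %d",
                 meta$n_bins, length(pages)), call. = FALSE)
  shp <- dim(pages[[1]])
  if (length(shp) != 2L)
    stop("multi-channel TIFF pages are not supported", call. = FALSE)
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1))))
    stop("TIFF pages have non-uniform shapes", call. = FALSE)
  a <- array(0, dim = c(shp[1], shp[2], meta$n_bins))
  for (j in seq_along(pages)) a[, , j] <- pages[[j]] * scale
  flim_stack(a, meta)
}

#' Write a FLIM stack as a multi-page TIFF plus JSON sidecar
#'
#' Integer stacks with maximum <= 65535 are written as uint16 pages
#' (bit-exact round trip); other stacks are written as float32 pages scaled
#' by their maximum, with the scale recorded in the sidecar, so the round
#' trip is exact to float32 precision.  The sidecar `<path>.json` carries the
#' acquisition metadata.
#'
#' @param stack A [flim_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "flim_stack"))
  cnt <- stack$counts
  integerish <- max(abs(cnt - round(cnt))) < 1e-9 && max(cnt) <= 65535
  d <- dim(cnt)
  if (integerish) {
    fmt <- "uint16"; scale <- 1
    pages <- lapply(seq_len(d[3]), function(j) round(cnt[, , j]) / 65535)
    bits <- 16L
  } else {
    fmt <- "float32"
    scale <- max(cnt)
    if (scale <= 0) scale <- 1
    pages <- lapply(seq_len(d[3]), function(j) cnt[, , j] / scale)
    bits <- 32L
  }
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = bits, reduce = FALSE)
  if (!isTRUE(ok > 0)) stop("failed to write TIFF at ", path, call. = FALSE)
  m <- stack$meta
  jsonlite::write_json(
    list(n_bins = m$n_bins, bin_width_ns = m$bin_width, period_ns = m$period,
         harmonic = m$harmonic, frames = m$frames,
         pixel_format = fmt, intensity_scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
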