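# NC-PCA denoising: Poisson-weighted scaling of the pixel-by-bin count
# matrix, SVD-based rank-k reconstruction, inverse scaling, and the
# thresholding / median-filter baselines (TPA, FPA).

#' Noise-correction factors for Poisson-weighted PCA
#'
#' Shot noise has variance equal to the mean count, so the raw count matrix
#' is heteroscedastic.  The default product-mean scheme divides each entry
#' by `sqrt(row_mean * col_mean)`; under a product-mean Poisson model this
#' approximately flattens the noise variance across the matrix.  Factors are
#' floored at a small positive constant so the scaling is always invertible,
#' and stored for exact inversion after PCA reconstruction.
#'
#' @param x Non-negative data matrix, pixels in rows and time bins in
#'   columns (see [flatten()]).
#' @param floor Minimum stored factor (default `1e-6`).
#' @return An object of class `nc_factors` with fields `row_factors`,
#'   `col_factors`, `floor`.
#' @export
compute_nc_factors <- function(x, floor = 1e-6) {
  stopifnot(is.matrix(x), floor > 0)
  if (min(x) < 0) stop("data matrix must be non-negative", call. = FALSE)
  structure(
    list(row_factors = pmax(rowMeans(x), floor),
         col_factors = pmax(colMeans(x), floor),
         floor = floor),
    class = "nc_factors")
}

#' Apply / invert the noise-correction scaling
#'
#' `apply_nc` computes `x[i, j] / sqrt(a_i * b_j)`; `invert_nc` is its exact
#' inverse.
#'
#' @param x Data matrix (pixels x bins).
#' @param factors An [compute_nc_factors()] result with conforming lengths.
#' @return The scaled (resp. unscaled) matrix; attributes of `x` (such as
#'   `pixdim`) are preserved.
#' @export
apply_nc <- function(x, factors) {
  .check_nc(x, factors)
  # row then column scaling avoids materializing the outer-product matrix
  out <- sweep(x / sqrt(factors$row_factors), 2, sqrt(factors$col_factors), `/`)
  attributes(out) <- attributes(x)
  out
}

#' @rdname apply_nc
#' @export
invert_nc <- function(x, factors) {
  .check_nc(x, factors)
  out <- sweep(x * sqrt(factors$row_factors), 2, sqrt(factors$col_factors), `*`)
  attributes(out) <- attributes(x)
  out
}

.check_nc <- function(x, factors) {
  stopifnot(is.matrix(x), inherits(factors, "nc_factors"))
  if (nrow(x) != length(factors$row_factors) ||
      ncol(x) != length(factors$col_factors))
    stop("NC factors do not conform to the data matrix", call. = FALSE)
}

# Anscombe variance-stabilizing transform pair (alternative NC scheme).
anscombe <- function(x) 2 * sqrt(x + 3 / 8)
anscombe_inv <- function(y) pmax((y / 2)^2 - 3 / 8, 0)

#' Rank-k PCA reconstruction of a data matrix
#'
#' Columns (time bins) are mean-centered across pixels, the centered matrix
#' is decomposed by economy SVD, and the reconstruction keeps the top `k`
#' singular triplets plus the column means.  When there are many more pixels
#' than bins the decomposition runs on the `n_bins x n_bins` cross-product
#' matrix, which is numerically equivalent and desk-scale in memory.
#'
#' @param x Data matrix (pixels x bins), typically NC-scaled.
#' @param k Number of components retained, `1 <= k <= ncol(x)`.
#' @return List with `reconstruction` (same shape as `x`),
#'   `explained_variance` (fraction of total variance per component, all
#'   components, non-increasing, summing to 1) and `k`.
#' @export
pca_reconstruct <- function(x, k) {
  stopifnot(is.matrix(x))
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > ncol(x))
    stop(sprintf("`k` must be in 1..%d", ncol(x)), call. = FALSE)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  if (nrow(x) > 4L * ncol(x)) {
    # eigendecomposition of the small cross-product matrix
    cp <- crossprod(xc)
    ev <- eigen(cp, symmetric = TRUE)
    lam <- pmax(ev$values, 0)
    v_k <- ev$vectors[, seq_len(k), drop = FALSE]
    xhat <- xc %*% v_k %*% t(v_k)
    sing2 <- lam
  } else {
    sv <- svd(xc)
    d_k <- sv$d
    xhat <- sv$u[, seq_len(k), drop = FALSE] %*%
      (d_k[seq_len(k)] * t(sv$v[, seq_len(k), drop = FALSE]))
    sing2 <- d_k^2
  }
  xhat <- sweep(xhat, 2, mu, `+`)
  tot <- sum(sing2)
  expl <- if (tot > 0) sing2 / tot else rep(0, length(sing2))
  attributes(xhat) <- attributes(x)
  list(reconstruction = xhat, explained_variance = expl, k = k)
}

#' Denoising configuration
#'
#' @param n_components Number of principal components `k` retained
#'   (default 3, which preserves the decay signal while discarding the noise
#'   subspace in typical FLIM stacks).
#' @param nc_scheme `"poisson-weighted"` (product-mean scaling, default),
#'   `"anscombe"` (variance-stabilizing square-root transform), or
#'   `"none"`.
#' @param clip_negative Clip negative reconstructed intensities to zero
#'   after inverse scaling (default `TRUE`; photon counts are non-negative).
#' @param threshold Minimum-total-count threshold applied after
#'   reconstruction; pixels with total counts at or below it are zeroed
#'   (default 0).
#' @return An object of class `denoise_config`.
#' @export
denoise_config <- function(n_components = 3L,
                           nc_scheme = c("poisson-weighted", "anscombe", "none"),
                           clip_negative = TRUE, threshold = 0) {
  nc_scheme <- match.arg(nc_scheme)
  stopifnot(threshold >= 0, n_components >= 1)
  structure(list(n_components = as.integer(n_components),
                 nc_scheme = nc_scheme,
                 clip_negative = isTRUE(clip_negative),
                 threshold = threshold),
            class = "denoise_config")
}

#' NC-PCA denoising of a FLIM stack
#'
#' The full pipeline: flatten to a pixel-by-bin matrix, compute and apply
#' the noise-correction scaling, reconstruct with the top `k` principal
#' components, invert the scaling, clip negatives, apply the minimum-count
#' threshold and rebuild the stack.  Deterministic.
#'
#' @param stack A [flim_stack()].
#' @param cfg A [denoise_config()].
#' @return An object of class `denoise_result`: `reconstructed`
#'   ([flim_stack()]), `factors` ([compute_nc_factors()] output or `NULL`),
#'   `explained_variance`, `k`, `config`.
#' @examples
#' ph <- make_phantom(shape = c(32, 32))
#' noisy <- add_poisson_noise(scale_to_total_counts(render_ground_truth(ph), 200))
#' res <- nc_pca_denoise(noisy)
#' res$explained_variance[1:3]
#' @export
nc_pca_denoise <- function(stack, cfg = denoise_config()) {
  stopifnot(inherits(stack, "flim_stack"), inherits(cfg, "denoise_config"))
  # the pipeline below is apply_nc/pca_reconstruct/invert_nc with in-place
  # rebinding, so peak memory stays at ~2 copies of the data matrix
  x <- flatten(stack)
  pd <- attr(x, "pixdim")
  factors <- NULL
  big <- length(x) > 2^25  # collect eagerly on full-frame stacks
  if (cfg$nc_scheme == "poisson-weighted") {
    factors <- compute_nc_factors(x)
    x <- x / sqrt(factors$row_factors)
    if (big) gc(FALSE)
    x <- sweep(x, 2, sqrt(factors$col_factors), `/`)
  } else if (cfg$nc_scheme == "anscombe") {
    x <- anscombe(x)
  }
  if (big) gc(FALSE)
  k <- cfg$n_components
  if (k > ncol(x)) stop(sprintf("`k` must be in 1..%d", ncol(x)), call. = FALSE)
  mu <- colMeans(x)
  x <- sweep(x, 2, mu)
  if (big) gc(FALSE)
  ev <- eigen(crossprod(x), symmetric = TRUE)
  sing2 <- pmax(ev$values, 0)
  v_k <- ev$vectors[, seq_len(k), drop = FALSE]
  scores <- x %*% v_k
  rm(x)
  if (big) gc(FALSE)
  xhat <- scores %*% t(v_k)
  rm(scores)
  xhat <- sweep(xhat, 2, mu, `+`)
  if (big) gc(FALSE)
  if (cfg$nc_scheme == "poisson-weighted") {
    xhat <- xhat * sqrt(factors$row_factors)
    if (big) gc(FALSE)
    xhat <- sweep(xhat, 2, sqrt(factors$col_factors), `*`)
  } else if (cfg$nc_scheme == "anscombe") {
    xhat <- anscombe_inv(xhat)
  }
  if (big) gc(FALSE)
  tot <- sum(sing2)
  pr <- list(explained_variance = if (tot > 0) sing2 / tot else rep(0, length(sing2)))
  if (cfg$clip_negative) xhat[xhat < 0] <- 0
  attr(xhat, "pixdim") <- pd
  out <- unflatten(xhat, stack$meta)
  if (cfg$threshold > 0) out <- threshold_total_counts(out, cfg$threshold)
  structure(list(reconstructed = out, factors = factors,
                 explained_variance = pr$explained_variance,
                 k = cfg$n_components, config = cfg),
            class = "denoise_result")
}

#' @export
print.denoise_result <- function(x, ...) {
  cat(sprintf("<denoise_result> k = %d (%s), %.2f%% variance retained\n",
              x$k, x$config$nc_scheme,
              100 * sum(x$explained_variance[seq_len(x$k)])))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-component variance of a denoising fit
#'
#' @param x A `denoise_result`.
#' @param ... Unused.
#' @return A tibble with `component`, `explained_variance`, `retained`.
#' @export
tidy.denoise_result <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$explained_variance),
    explained_variance = x$explained_variance,
    retained = seq_along(x$explained_variance) <= x$k)
}

#' @rdname tidy.denoise_result
#' @return `glance()`: a one-row tibble with `k`, `nc_scheme`,
#'   `variance_retained`, `threshold`.
#' @export
glance.denoise_result <- function(x, ...) {
  tibble::tibble(
    k = x$k, nc_scheme = x$config$nc_scheme,
    variance_retained = sum(x$explained_variance[seq_len(x$k)]),
    threshold = x$config$threshold)
}

#' Minimum-total-count thresholding (the TPA step)
#'
#' Pixels whose total counts over all bins are at or below `theta` are set
#' to zero in every time bin; all other pixels are untouched.
#'
#' @param stack A [flim_stack()].
#' @param theta Threshold in photons (>= 0); comparison is `<=`.
#' @return The thresholded [flim_stack()].
#' @export
threshold_total_counts <- function(stack, theta) {
  stopifnot(inherits(stack, "flim_stack"), theta >= 0)
  tot <- total_counts(stack)
  kill <- tot <= theta
  if (any(kill)) {
    cnt <- stack$counts
    cnt[array(rep(kill, dim(cnt)[3]), dim = dim(cnt))] <- 0
    stack <- flim_stack(cnt, stack$meta)
  }
  stack
}

# Brute-force masked windowed median of one matrix; NA-masked pixels are
# excluded from every window and stay NA in the output.
masked_median_filter <- function(m, kernel) {
  h <- (kernel - 1L) %/% 2L
  if (h == 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  shifts <- expand.grid(dr = -h:h, dc = -h:h)
  stackv <- matrix(NA_real_, nr * nc, nrow(shifts))
  for (s in seq_len(nrow(shifts))) {
    dr <- shifts$dr[s]; dc <- shifts$dc[s]
    src_r <- seq_len(nr) + dr
    src_c <- seq_len(nc) + dc
    ok_r <- src_r >= 1 & src_r <= nr
    ok_c <- src_c >= 1 & src_c <= nc
    sh <- matrix(NA_real_, nr, nc)
    sh[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
    stackv[, s] <- as.vector(sh)
  }
  out <- apply(stackv, 1, stats::median, na.rm = TRUE)
  out[is.na(as.vector(m))] <- NA_real_
  out[is.nan(out)] <- NA_real_
  matrix(out, nr, nc)
}

#' Median filtering in phasor space (the FPA step)
#'
#' Default mode filters the per-pixel G and S maps with a `kernel x kernel`
#' windowed median, excluding masked pixels from every window.  The
#' alternate mode filters the 2D phasor-histogram counts instead.  The mode
#' used is recorded in the output.
#'
#' @param x A `phasor_field` (see [phasor_transform()]) or a
#'   `phasor_histogram` (see [phasor_histogram()]).
#' @param kernel Odd window size >= 1; `kernel = 1` is the identity.
#' @return The filtered object, with attribute `median_filter` recording
#'   the kernel and mode.
#' @export
median_filter_phasor <- function(x, kernel = 3L) {
  kernel <- as.integer(kernel)
  if (is.na(kernel) || kernel < 1L || kernel %% 2L == 0L)
    stop("`kernel` must be an odd integer >= 1", call. = FALSE)
  if (inherits(x, "phasor_field")) {
    g <- x$G; s <- x$S
    g[!x$mask] <- NA_real_; s[!x$mask] <- NA_real_
    x$G <- masked_median_filter(g, kernel)
    x$S <- masked_median_filter(s, kernel)
    x$G[!x$mask] <- NA_real_; x$S[!x$mask] <- NA_real_
    attr(x, "median_filter") <- list(kernel = kernel, mode = "field")
    x
  } else if (inherits(x, "phasor_histogram")) {
    x$counts <- masked_median_filter(x$counts, kernel)
    pk <- arrayInd(which.max(x$counts), dim(x$counts))
    x$peak <- c(G = x$g_centers[pk[1]], S = x$s_centers[pk[2]])
    attr(x, "median_filter") <- list(kernel = kernel, mode = "histogram")
    x
  } else stop("`x` must be a phasor_field or phasor_histogram", call. = FALSE)
}
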