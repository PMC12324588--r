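# Per-pixel single-exponential lifetime fitting, used to validate
# reconstructions against dyes with a known mono-exponential decay.

#' Per-pixel single-exponential decay fit
#'
#' Fits `I(t) = A * exp(-t / tau) + c` to every pixel trace by
#' Levenberg-Marquardt nonlinear least squares.  Pixels with total counts at
#' or below `min_total` are skipped.  The fit domain starts at each trace's
#' global-maximum bin so rise/IRF bins are excluded.  Initialization:
#' `c0` = mean of the last 5% of bins, `A0` = first fitted bin minus `c0`,
#' `tau0` from the log-linear slope of the background-subtracted first
#' half-decay.  Non-convergence flags the pixel instead of erroring.
#'
#' @param stack A [flim_stack()].
#' @param min_total Skip threshold in photons (default 100).
#' @param fit_offset Fit the constant offset `c` (default `TRUE`); if
#'   `FALSE`, `c` is pinned to 0.
#' @param max_iter Iteration cap (default 200).
#' @param tol Relative convergence tolerance (default 1e-8).
#' @return An object of class `lifetime_map`: matrices `tau`, `amplitude`,
#'   `offset`, `residual_norm`, logical `converged` and `fitted`
#'   (pixels attempted).
#' @examples
#' meta <- flim_meta(64, period = 12.5)
#' tr <- 400 * exp(-bin_centers(meta) / 2.5)
#' st <- flim_stack(array(rep(tr, each = 4), c(2, 2, 64)), meta)
#' fit <- fit_single_exp(st)
#' fit$tau[1, 1]
#' @export
fit_single_exp <- function(stack, min_total = 100, fit_offset = TRUE,
                           max_iter = 200L, tol = 1e-8) {
  stopifnot(inherits(stack, "flim_stack"))
  x <- flatten(stack)
  t_j <- bin_centers(stack$meta)
  n <- ncol(x)
  tot <- rowSums(x)
  attempt <- tot > min_total
  np <- nrow(x)
  tau <- amp <- off <- rnorm_v <- rep(NA_real_, np)
  conv <- rep(FALSE, np)
  tail_idx <- seq(max(1, ceiling(0.95 * n)), n)
  for (i in which(attempt)) {
    y <- x[i, ]
    j0 <- which.max(y)
    yy <- y[j0:n]; tt <- t_j[j0:n]
    c0 <- mean(y[tail_idx])
    a0 <- max(yy[1] - c0, max(yy) * 0.1, 1e-6)
    # log-linear slope over the background-subtracted first half-decay
    ys <- yy - c0
    half <- which(ys <= a0 / 2)
    hl <- if (length(half)) min(half) else length(ys)
    hl <- max(hl, 3L)
    sel <- seq_len(min(hl, length(ys)))
    pos <- sel[ys[sel] > 0]
    tau0 <- if (length(pos) >= 2) {
      sl <- stats::coef(stats::lm(log(ys[pos]) ~ tt[pos]))[2]
      if (is.finite(sl) && sl < 0) -1 / sl else stack$meta$period / 4
    } else stack$meta$period / 4
    tau0 <- min(max(tau0, stack$meta$bin_width), 10 * stack$meta$period)
    df <- data.frame(tt = tt, yy = yy)
    fit <- if (fit_offset) {
      try(minpack.lm::nlsLM(
        yy ~ A * exp(-tt / tau) + c0p,
        data = df, start = list(A = a0, tau = tau0, c0p = c0),
        lower = c(0, 1e-4, -Inf),
        control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = tol)),
        silent = TRUE)
    } else {
      try(minpack.lm::nlsLM(
        yy ~ A * exp(-tt / tau),
        data = df, start = list(A = a0, tau = tau0),
        lower = c(0, 1e-4),
        control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = tol)),
        silent = TRUE)
    }
    if (!inherits(fit, "try-error")) {
      co <- stats::coef(fit)
      # reject fits pinned at the parameter bounds or with absurd lifetimes
      if (is.finite(co[["tau"]]) && co[["tau"]] > 2e-4 &&
          co[["tau"]] < 5 * stack$meta$period && co[["A"]] > 0) {
        tau[i] <- co[["tau"]]
        amp[i] <- co[["A"]]
        off[i] <- if (fit_offset) co[["c0p"]] else 0
        rnorm_v[i] <- sqrt(sum(stats::resid(fit)^2))
        conv[i] <- TRUE
      }
    }
  }
  pd <- attr(x, "pixdim")
  tom <- function(v) matrix(v, pd[1], pd[2], byrow = TRUE)
  structure(list(tau = tom(tau), amplitude = tom(amp), offset = tom(off),
                 residual_norm = tom(rnorm_v), converged = tom(conv),
                 fitted = tom(attempt)),
            class = "lifetime_map")
}

#' @export
print.lifetime_map <- function(x, ...) {
  cat(sprintf("<lifetime_map> %d/%d pixels converged; mean tau %.3g ns\n",
              sum(x$converged), sum(x$fitted),
              mean(x$tau[x$converged])))
  invisible(x)
}

#' Tidy a lifetime map into a per-pixel tibble
#'
#' @param x A `lifetime_map`.
#' @param ... Unused.
#' @return A tibble of converged pixels: `row`, `col`, `tau`, `amplitude`,
#'   `offset`, `residual_norm`.
#' @export
tidy.lifetime_map <- function(x, ...) {
  idx <- which(x$converged, arr.ind = TRUE)
  tibble::tibble(row = idx[, 1], col = idx[, 2], tau = x$tau[idx],
                 amplitude = x$amplitude[idx], offset = x$offset[idx],
                 residual_norm = x$residual_norm[idx])
}

#' @rdname tidy.lifetime_map
#' @return `glance()`: one-row tibble with `n_fitted`, `n_converged`,
#'   `converged_fraction`, `mean_tau`, `sd_tau`.
#' @export
glance.lifetime_map <- function(x, ...) {
  tv <- x$tau[x$converged]
  tibble::tibble(
    n_fitted = sum(x$fitted), n_converged = sum(x$converged),
    converged_fraction = if (sum(x$fitted) > 0) sum(x$converged) / sum(x$fitted) else NA_real_,
    mean_tau = mean(tv), sd_tau = stats::sd(tv))
}

#' Lifetime histogram with mean and FWHM
#'
#' Histograms the converged lifetimes of a [fit_single_exp()] map and
#' reports the arithmetic mean and the interpolated FWHM of the histogram
#' profile.
#'
#' @param map A `lifetime_map` with at least one converged pixel.
#' @param bins Number of bins (default 100).
#' @param range Lifetime range in ns (default `c(0, 6)`).
#' @return List with `mids`, `counts`, `mean`, `fwhm`, `n`.
#' @export
lifetime_histogram <- function(map, bins = 100L, range = c(0, 6)) {
  stopifnot(inherits(map, "lifetime_map"))
  tv <- map$tau[map$converged]
  if (!length(tv)) stop("no converged pixels", call. = FALSE)
  edges <- seq(range[1], range[2], length.out = bins + 1)
  h <- hist(pmin(pmax(tv, range[1]), range[2]), breaks = edges, plot = FALSE)
  list(mids = h$mids, counts = h$counts, mean = mean(tv),
       fwhm = as.numeric(fwhm_interp(h$mids, h$counts)), n = length(tv))
}
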