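# Synthetic FLIM phantom: a procedural cell-like label map whose structures
# carry distinct mono-exponential lifetimes, rendered into a noise-free
# 256-bin decay stack and corrupted with per-pixel Poisson shot noise.

#' Default phantom structure recipe
#'
#' Five cellular structures drawn inside an elliptical cell: nucleus,
#' vacuoles, mitochondria, ribosomes and cell wall.  Lifetimes are assigned
#' per component group, the way the phantom is composed from three overlays:
#' the cytoplasmic organelles (mitochondria + ribosomes) share one lifetime,
#' the nucleus + vacuoles share a second, and the cell wall carries a third,
#' spanning the NADH-relevant range.  Amplitudes (photons in the first time
#' bin, before any global count rescaling) make the mitochondria/ribosome
#' group the brightest and put the area-dominant nucleus/vacuole group near
#' the median pixel brightness - the count hierarchy of a typical two-photon
#' NADH image.  The cell fills the frame ellipse completely, so background
#' is confined to the frame corners.
#'
#' @return A data frame with columns `label`, `name`, `tau` (ns),
#'   `amplitude` (photons), `area_frac` (target fraction of the frame).
#' @export
default_structures <- function() {
  data.frame(
    label     = 1:5,
    name      = c("ribosomes", "mitochondria", "vacuoles", "nucleus", "cell_wall"),
    tau       = c(2.0, 2.0, 3.5, 3.5, 0.5),
    amplitude = c(6.85, 6.85, 2.73, 2.73, 11.0),
    area_frac = c(0.09, 0.085, 0.26, 0.26, 0.095)
  )
}

# Rasterize a filled ellipse into a logical mask.
ellipse_mask <- function(rows, cols, cy, cx, ry, rx, theta = 0) {
  r <- matrix(seq_len(rows), rows, cols) - cy
  c <- matrix(seq_len(cols), rows, cols, byrow = TRUE) - cx
  u <- r * cos(theta) + c * sin(theta)
  v <- -r * sin(theta) + c * cos(theta)
  (u / ry)^2 + (v / rx)^2 <= 1
}

#' Build the synthetic cell phantom
#'
#' Draws parameterized primitives (ellipses, an annulus, scattered dots) into
#' an integer label map (0 = background).  Overlaps are resolved by
#' precedence: structures are drawn in the order ribosomes, mitochondria,
#' vacuoles, nucleus, cell wall, and later structures win.  The dot and blob
#' placements are seeded, so the map is deterministic given `seed`.
#'
#' @param shape Integer `(rows, cols)`; default `c(540, 720)`.
#' @param structures Structure table as from [default_structures()]; rows
#'   with labels 1..5 are interpreted as ribosomes / mitochondria / vacuoles
#'   / nucleus / cell wall.  `tau` must be positive, `amplitude >= 0`.
#' @param meta A [flim_meta()]; default 256 bins over a 12.5 ns period.
#' @param seed Integer seed for the stochastic placements.
#' @return An object of class `flim_phantom`: `labels` (integer matrix),
#'   `structures`, `meta`, `seed`.
#' @examples
#' ph <- make_phantom(shape = c(64, 64))
#' table(ph$labels)
#' @export
make_phantom <- function(shape = c(540, 720), structures = default_structures(),
                         meta = flim_meta(256, period = 12.5), seed = 1L) {
  stopifnot(length(shape) == 2, all(shape >= 1))
  if (nrow(structures) > 0) {
    if (any(structures$tau <= 0)) stop("structure lifetimes must be positive", call. = FALSE)
    if (any(structures$amplitude < 0)) stop("structure amplitudes must be >= 0", call. = FALSE)
  }
  rows <- as.integer(shape[1]); cols <- as.integer(shape[2])
  labels <- matrix(0L, rows, cols)
  if (nrow(structures) == 0)
    return(structure(list(labels = labels, structures = structures,
                          meta = meta, seed = seed), class = "flim_phantom"))

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)

  cy <- rows * 0.5; cx <- cols * 0.5
  ry <- rows * 0.499; rx <- cols * 0.499
  rmat <- matrix(seq_len(rows), rows, cols)
  cmat <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  rn <- sqrt(((rmat - cy) / ry)^2 + ((cmat - cx) / rx)^2)  # normalized cell radius
  cell <- rn <= 1

  has <- function(nm) nm %in% structures$name
  lab <- function(nm) structures$label[structures$name == nm]
  frac_of <- function(nm) structures$area_frac[structures$name == nm]
  npix <- rows * cols

  # deterministic large structures first: cell wall annulus and nucleus
  wall_m <- nuc_m <- matrix(FALSE, rows, cols)
  if (has("cell_wall")) {
    # annulus inner radius chosen so the band area matches area_frac
    cell_area_frac <- pi * 0.499 * 0.499
    inner <- sqrt(max(1 - frac_of("cell_wall") / cell_area_frac, 0))
    wall_m <- cell & rn >= inner
  }
  nuc_c <- c(rows * 0.42, cols * 0.40); nuc_ry <- 0
  if (has("nucleus")) {
    ar <- 1.37  # rx/ry aspect
    nuc_ry <- sqrt(frac_of("nucleus") * npix / (pi * ar))
    nuc_m <- ellipse_mask(rows, cols, nuc_c[1], nuc_c[2], nuc_ry, nuc_ry * ar) &
      cell & !wall_m
  }

  # vacuoles: large circles on a ring, rejected away from the nucleus
  vac_m <- matrix(FALSE, rows, cols)
  if (has("vacuoles")) {
    n_vac <- 6L
    rad <- sqrt(frac_of("vacuoles") * npix / (n_vac * pi))
    target <- frac_of("vacuoles") * npix
    i <- 0L
    while (sum(vac_m) < target && i < 4L * n_vac) {
      i <- i + 1L
      r_i <- if (i <= n_vac) rad else rad * 0.7  # clipping losses made up
      for (try_i in 1:50) {                      # with smaller extra circles
        ang <- 2 * pi * (i - 1) / n_vac + runif(1, -0.25, 0.25)
        rad_pos <- runif(1, 0.5, 0.78)
        pr <- cy + rad_pos * ry * sin(ang)
        pc <- cx + rad_pos * rx * cos(ang)
        d_nuc <- sqrt((pr - nuc_c[1])^2 + ((pc - nuc_c[2]) / 1.37)^2)
        if (!has("nucleus") || d_nuc > nuc_ry + r_i * 1.05) break
      }
      vac_m <- (vac_m | ellipse_mask(rows, cols, pr, pc, r_i, r_i)) &
        cell & !wall_m & !nuc_m
    }
  }

  free <- cell & !wall_m & !nuc_m & !vac_m

  # mitochondria: elongated blobs added until their target area is covered
  mito_m <- matrix(FALSE, rows, cols)
  if (has("mitochondria")) {
    target <- frac_of("mitochondria") * npix
    scale <- sqrt(npix / (540 * 720))
    a <- max(3, 12 * scale); b <- max(1.5, 5 * scale)
    free_idx <- which(free)
    guard <- 0L
    while (sum(mito_m) < target && guard < 10000L) {
      guard <- guard + 1L
      ctr <- free_idx[sample.int(length(free_idx), 1L)]
      pr <- ((ctr - 1) %% rows) + 1
      pc <- ((ctr - 1) %/% rows) + 1
      th <- runif(1, 0, pi)
      mito_m <- mito_m | (ellipse_mask(rows, cols, pr, pc, a, b, th) & free)
    }
  }

  # ribosomes: dense scattered dots in the remaining cytoplasm
  ribo_m <- matrix(FALSE, rows, cols)
  if (has("ribosomes")) {
    target <- frac_of("ribosomes") * npix
    avail <- free & !mito_m
    avail_idx <- which(avail)
    off <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
    guard <- 0L
    while (sum(ribo_m) < target && guard < 60L && length(avail_idx) > 0) {
      guard <- guard + 1L
      n_batch <- max(100L, ceiling((target - sum(ribo_m)) / 4))
      ctr <- avail_idx[sample.int(length(avail_idx),
                                  min(n_batch, length(avail_idx)))]
      rr <- ((ctr - 1) %% rows) + 1
      cc <- ((ctr - 1) %/% rows) + 1
      for (o in seq_len(nrow(off))) {
        r2 <- pmin(pmax(rr + off[o, 1], 1), rows)
        c2 <- pmin(pmax(cc + off[o, 2], 1), cols)
        ribo_m[cbind(r2, c2)] <- TRUE
      }
      ribo_m <- ribo_m & avail
    }
  }

  if (has("ribosomes"))    labels[ribo_m] <- lab("ribosomes")
  if (has("mitochondria")) labels[mito_m] <- lab("mitochondria")
  if (has("vacuoles"))     labels[vac_m] <- lab("vacuoles")
  if (has("nucleus"))      labels[nuc_m] <- lab("nucleus")
  if (has("cell_wall"))    labels[wall_m] <- lab("cell_wall")

  structure(list(labels = labels, structures = structures, meta = meta,
                 seed = seed), class = "flim_phantom")
}

#' @export
print.flim_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<flim_phantom> %d x %d, %d structures, %.1f%% labelled\n",
              d[1], d[2], nrow(x$structures), 100 * mean(x$labels > 0)))
  invisible(x)
}

# save/restore .Random.seed so seeded helpers do not disturb the caller's RNG
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
}

#' Render the noise-free ground-truth stack of a phantom
#'
#' Each pixel with label l decays as `A_l * exp(-(j + 0.5) * dt / tau_l)`
#' over time bins j; background pixels are all-zero.
#'
#' @param phantom A [make_phantom()] result.
#' @return A [flim_stack()] of noise-free expected counts.
#' @export
render_ground_truth <- function(phantom) {
  stopifnot(inherits(phantom, "flim_phantom"))
  meta <- phantom$meta
  t_j <- bin_centers(meta)
  labs <- phantom$structures$label
  traces <- matrix(0, nrow = max(c(labs, 0L)) + 1L, ncol = meta$n_bins)
  for (i in seq_along(labs)) {
    traces[labs[i] + 1L, ] <-
      phantom$structures$amplitude[i] * exp(-t_j / phantom$structures$tau[i])
  }
  d <- dim(phantom$labels)
  a <- array(0, dim = c(d, meta$n_bins))
  idx <- phantom$labels + 1L
  for (j in seq_len(meta$n_bins)) a[, , j] <- traces[idx, j]
  flim_stack(a, meta)
}

#' Rescale a stack to a target total photon count
#'
#' Multiplies every count by one scalar so that a reference statistic of the
#' per-pixel total counts equals `target`: either the mean total over
#' nonzero pixels (default, the working definition of an image's "photon
#' count level") or the brightest pixel's total.
#'
#' @param stack A [flim_stack()] with at least one nonzero pixel.
#' @param target Target photons for the reference statistic (> 0).
#' @param reference `"mean-nonzero"` or `"brightest"`.
#' @return The rescaled [flim_stack()].
#' @export
scale_to_total_counts <- function(stack, target,
                                  reference = c("mean-nonzero", "brightest")) {
  stopifnot(inherits(stack, "flim_stack"), target > 0)
  reference <- match.arg(reference)
  tot <- total_counts(stack)
  nz <- tot > 0
  if (!any(nz)) stop("stack is all-zero; nothing to scale", call. = FALSE)
  ref <- switch(reference,
                "mean-nonzero" = mean(tot[nz]),
                "brightest" = max(tot))
  flim_stack(stack$counts * (target / ref), stack$meta)
}

#' Poisson noise specification
#'
#' @param background_mean Poisson mean for pixels whose whole ground-truth
#'   trace is zero (default 0.8 photons per bin, matching the dark-count
#'   level seen in real acquisitions).
#' @param seed RNG seed for reproducible draws.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(background_mean = 0.8, seed = 1L) {
  stopifnot(background_mean >= 0)
  structure(list(background_mean = background_mean, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Corrupt a ground-truth stack with Poisson shot noise
#'
#' Every bin value is replaced by an independent Poisson draw whose mean is
#' the ground-truth count in that bin; pixels whose entire trace is zero use
#' `background_mean` in every bin instead, so no pixel has identically zero
#' noise.  Draws are independent across pixels and bins (shot noise is
#' temporally uncorrelated) and fully reproducible from the seed.
#'
#' @param stack Noise-free [flim_stack()] (non-negative).
#' @param noise A [noise_spec()].
#' @return A [flim_stack()] of integer counts.
#' @export
add_poisson_noise <- function(stack, noise = noise_spec()) {
  stopifnot(inherits(stack, "flim_stack"), inherits(noise, "noise_spec"))
  if (min(stack$counts) < 0)
    stop("ground-truth counts must be non-negative", call. = FALSE)
  d <- dim(stack$counts)
  zero_trace <- total_counts(stack) == 0
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(noise$seed)
  # draw bin by bin (column-major slice order) to keep working memory at one
  # frame; the draw stream is identical to a whole-array rpois call
  draws <- array(0L, dim = d)
  for (j in seq_len(d[3])) {
    lam <- stack$counts[, , j]
    if (any(zero_trace)) lam[zero_trace] <- noise$background_mean
    draws[, , j] <- stats::rpois(length(lam), lam)
  }
  flim_stack(draws, stack$meta)
}
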