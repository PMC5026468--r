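#' Uniform random (binomial) point pattern
#'
#' `n` points i.i.d. uniform on the window — the "randomly generated array"
#' used to normalize the nearest-neighbor regularity index, and the
#' no-exclusion-zone baseline for the packing factor.
#'
#' @param n number of points.
#' @param window numeric `c(x_min, y_min, x_max, y_max)` in micrometres.
#' @param seed integer seed; every generator is deterministic given a seed.
#' @param ... metadata passed to [point_pattern()].
#' @return a `ppattern`.
#' @export
gen_random <- function(n, window, seed = NULL, ...) {
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  x <- stats::runif(n, window[1], window[3])
  y <- stats::runif(n, window[2], window[4])
  point_pattern(x, y, window = window, ...)
}

#' Jittered triangular (hexagonal-packing) lattice
#'
#' Triangular-lattice points clipped to the window, each displaced by
#' isotropic Gaussian jitter. With `jitter_sd = 0` this is the perfectly
#' ordered array whose packing factor defines the value 1.
#'
#' @param spacing lattice constant in micrometres (nearest-neighbor distance
#'   of the unjittered lattice).
#' @param window observation window.
#' @param jitter_sd standard deviation of the per-point Gaussian displacement
#'   in micrometres.
#' @param seed integer seed (only used when `jitter_sd > 0`).
#' @param ... metadata passed to [point_pattern()].
#' @return a `ppattern`.
#' @export
gen_hex_lattice <- function(spacing, window, jitter_sd = 0, seed = NULL, ...) {
  stopifnot(spacing > 0, jitter_sd >= 0)
  dy <- spacing * sqrt(3) / 2
  rows <- seq(window[2], window[4], by = dy)
  xs <- ys <- numeric(0)
  for (i in seq_along(rows)) {
    off <- if (i %% 2 == 0) spacing / 2 else 0
    xr <- seq(window[1] + off, window[3], by = spacing)
    xs <- c(xs, xr)
    ys <- c(ys, rep(rows[i], length(xr)))
  }
  if (jitter_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    xs <- xs + stats::rnorm(length(xs), 0, jitter_sd)
    ys <- ys + stats::rnorm(length(ys), 0, jitter_sd)
  }
  keep <- xs >= window[1] & xs <= window[3] & ys >= window[2] & ys <= window[4]
  if (sum(keep) < 3)
    warning("spacing large relative to window: fewer than 3 lattice points")
  point_pattern(xs[keep], ys[keep], window = window, ...)
}

#' Sequential-inhibition (dmin) mosaic pattern
#'
#' Hard-core simple sequential inhibition: uniform candidate points are
#' accepted only if at least `dmin` from every previously accepted point.
#' This is the simplest process with the exclusion-zone signature that the
#' density recovery profile detects in real mosaics.
#'
#' @param n number of points required.
#' @param window observation window.
#' @param dmin exclusion distance in micrometres.
#' @param seed integer seed.
#' @param max_tries cap on total candidate draws before giving up.
#' @param ... metadata passed to [point_pattern()].
#' @return a `ppattern` with all pairwise distances >= `dmin`.
#' @export
gen_dmin <- function(n, window, dmin, seed = NULL, max_tries = 1e5 * max(n, 1),
                     ...) {
  stopifnot(n >= 0, dmin >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (dmin == 0) return(gen_random(n, window, seed = NULL, ...))
  px <- py <- numeric(n)
  acc <- 0L
  tries <- 0L
  d2 <- dmin^2
  while (acc < n) {
    if (tries >= max_tries)
      stop(sprintf(
        "gen_dmin: max_tries (%g) exhausted with %d of %d points placed",
        max_tries, acc, n))
    cx <- stats::runif(1, window[1], window[3])
    cy <- stats::runif(1, window[2], window[4])
    tries <- tries + 1L
    if (acc == 0L ||
        min((px[seq_len(acc)] - cx)^2 + (py[seq_len(acc)] - cy)^2) >= d2) {
      acc <- acc + 1L
      px[acc] <- cx; py[acc] <- cy
    }
  }
  point_pattern(px, py, window = window, ...)
}

#' Neyman-Scott clustered point pattern
#'
#' Uniform parent points; Poisson(`offspring_mean`) offspring per parent,
#' displaced by isotropic Gaussian(`cluster_sd`) and clipped to the window.
#' Models the clustered (anti-mosaic) regime in which near DRP bins exceed
#' the overall density.
#'
#' @param n_parents number of parent (cluster centre) points.
#' @param offspring_mean mean offspring per parent.
#' @param cluster_sd Gaussian dispersal SD in micrometres.
#' @param window observation window.
#' @param seed integer seed.
#' @param ... metadata passed to [point_pattern()].
#' @return a `ppattern` of the offspring only.
#' @export
gen_clustered <- function(n_parents, offspring_mean, cluster_sd, window,
                          seed = NULL, ...) {
  stopifnot(n_parents > 0, offspring_mean > 0, cluster_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  pxs <- stats::runif(n_parents, window[1], window[3])
  pys <- stats::runif(n_parents, window[2], window[4])
  counts <- stats::rpois(n_parents, offspring_mean)
  cx <- rep(pxs, counts) + stats::rnorm(sum(counts), 0, cluster_sd)
  cy <- rep(pys, counts) + stats::rnorm(sum(counts), 0, cluster_sd)
  keep <- cx >= window[1] & cx <= window[3] & cy >= window[2] & cy <= window[4]
  point_pattern(cx[keep], cy[keep], window = window, ...)
}

#' Simulate forced-choice rater comparisons from latent image quality
#'
#' Draws uniformly random distinct image pairs and picks a winner under the
#' Bradley-Terry model: P(a beats b) = 1 / (1 + exp(-(q_a - q_b) /
#' noise_scale)). As `noise_scale` tends to 0 the higher-latent image always
#' wins; large values make choices random. Records are tagged with rater ids
#' in round-robin order, emulating a panel of observers scoring one shared
#' image set.
#'
#' @param latent_scores named numeric vector, one latent quality per image id.
#' @param n_matchups number of comparisons to generate.
#' @param n_raters number of raters cycled round-robin.
#' @param noise_scale logistic noise scale (same units as the latent scores).
#' @param seed integer seed.
#' @return data.frame with columns `image_a`, `image_b`, `winner`, `rater`.
#' @export
gen_comparisons <- function(latent_scores, n_matchups, n_raters = 6,
                            noise_scale = 1, seed = NULL) {
  ids <- names(latent_scores)
  if (is.null(ids) || length(ids) < 2)
    stop("latent_scores must be a named vector over at least 2 images")
  stopifnot(n_matchups >= 1, n_raters >= 1, noise_scale >= 0)
  if (!is.null(seed)) set.seed(seed)
  a <- character(n_matchups); b <- character(n_matchups)
  for (k in seq_len(n_matchups)) {
    pair <- sample(ids, 2)
    a[k] <- pair[1]; b[k] <- pair[2]
  }
  qa <- latent_scores[a]; qb <- latent_scores[b]
  p_a <- if (noise_scale == 0) as.numeric(qa > qb) + 0.5 * (qa == qb) else
    1 / (1 + exp(-(qa - qb) / noise_scale))
  win_a <- stats::runif(n_matchups) < p_a
  data.frame(image_a = a, image_b = b,
             winner = ifelse(win_a, a, b),
             rater = paste0("rater", ((seq_len(n_matchups) - 1) %% n_raters) + 1),
             stringsAsFactors = FALSE)
}

#' Synthetic thresholdable image with known area and overlap fractions
#'
#' Single-channel: a binary-valued image with exactly
#' `round(target_fraction * n_pixels)` foreground pixels, placed at seeded
#' random positions. Two-channel (when `overlap_fraction` is given): channel
#' 2 gets `round(target_fraction * n_pixels)` foreground pixels and channel 1
#' is built so that the overlap area equals `overlap_fraction` of the
#' channel-2 foreground. Ground truth for the percent-area and
#' overlap-ratio measurements.
#'
#' @param shape integer `c(n_rows, n_cols)`.
#' @param target_fraction foreground fraction in `[0, 1]`.
#' @param overlap_fraction optional overlap fraction in `[0, 1]`; triggers
#'   two-channel output.
#' @param seed integer seed.
#' @param scale micrometres per pixel.
#' @return an `intensity_image`.
#' @export
gen_test_image <- function(shape, target_fraction, overlap_fraction = NULL,
                           seed = NULL, scale = 1) {
  stopifnot(length(shape) == 2, target_fraction >= 0, target_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  npix <- prod(shape)
  n_fg <- round(target_fraction * npix)
  if (is.null(overlap_fraction)) {
    px <- matrix(0, shape[1], shape[2])
    px[sample.int(npix, n_fg)] <- 1
    return(intensity_image(px, scale = scale, channel_names = "ch1"))
  }
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1)
  ch2 <- matrix(0, shape[1], shape[2])
  idx2 <- sample.int(npix, n_fg)
  ch2[idx2] <- 1
  n_ov <- round(overlap_fraction * n_fg)
  ch1 <- matrix(0, shape[1], shape[2])
  if (n_ov > 0) ch1[idx2[seq_len(n_ov)]] <- 1
  # pad channel 1 outside the channel-2 mask up to its own target size
  outside <- setdiff(seq_len(npix), idx2)
  n_pad <- min(max(n_fg - n_ov, 0), length(outside))
  if (n_pad > 0) ch1[sample(outside, n_pad)] <- 1
  intensity_image(array(c(ch1, ch2), dim = c(shape, 2)), scale = scale,
                  channel_names = c("ch1", "ch2"))
}
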