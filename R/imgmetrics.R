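#' Percent area above intensity thresholds
#'
#' For each threshold `t`, the percentage of pixels strictly above `t` —
#' the percent-area-occupied measurement applied to projection images at
#' several threshold levels. "Above" is strict (`>`) throughout.
#'
#' @param image a single-channel `intensity_image`.
#' @param thresholds numeric vector of intensity levels (typically 3).
#' @return An object of class `"threshold_area_result"`: list with
#'   `thresholds`, `pixel_counts`, `percent_area` (each in `[0, 100]`,
#'   non-increasing in the threshold).
#' @export
percent_area_above <- function(image, thresholds) {
  px <- image$pixels
  if (dim(px)[3] != 1) stop("percent_area_above expects a single channel")
  if (length(px) == 0) stop("empty image")
  total <- prod(dim(px)[1:2])
  counts <- vapply(thresholds, function(t) sum(px > t), numeric(1))
  structure(list(thresholds = thresholds,
                 pixel_counts = counts,
                 percent_area = 100 * counts / total),
            class = "threshold_area_result")
}

#' Two-channel overlap ratio (thresholded colocalization)
#'
#' Both channels are thresholded and the ratio of the overlap area to the
#' channel-2 (marker) area is returned:
#' `|mask_a AND mask_b| / |mask_b|` with masks defined by strict
#' thresholds. Channel 1 is the stain under quantification, channel 2 the
#' reference marker whose footprint normalizes the overlap — the
#' mask-intersection equivalent of multiplying thresholded channels.
#'
#' @param image a two-channel `intensity_image`.
#' @param t_a,t_b intensity thresholds for channels 1 and 2.
#' @return overlap fraction in `[0, 1]`.
#' @export
overlap_ratio <- function(image, t_a, t_b) {
  px <- image$pixels
  if (dim(px)[3] != 2) stop("overlap_ratio expects a two-channel image")
  mask_a <- px[, , 1] > t_a
  mask_b <- px[, , 2] > t_b
  nb <- sum(mask_b)
  if (nb == 0) stop("undefined ratio: no pixels above threshold in channel 2")
  sum(mask_a & mask_b) / nb
}

#' Mean intensity along a line segment
#'
#' Samples the image with bilinear interpolation at pixel-pitch steps along
#' a segment defined by a start point, unit direction and length (default
#' 10 um, the standard probe projecting into the IPL perpendicular to the
#' INL), and returns the arithmetic mean of the sampled intensities.
#'
#' @param image a single-channel `intensity_image`.
#' @param start numeric `c(x, y)` in micrometres (image convention).
#' @param direction numeric `c(dx, dy)`; normalized internally.
#' @param length segment length in micrometres.
#' @return mean intensity along the segment.
#' @export
line_profile_mean <- function(image, start, direction, length = 10) {
  px <- image$pixels
  if (dim(px)[3] != 1) stop("line_profile_mean expects a single channel")
  stopifnot(length > 0)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be non-zero")
  dirn <- direction / nrm
  sc <- image$scale
  n_steps <- max(2L, floor(length / sc) + 1L)
  t <- seq(0, length, length.out = n_steps)
  xs <- start[1] + t * dirn[1]
  ys <- start[2] + t * dirn[2]
  vals <- bilinear_sample(px[, , 1], xs / sc, ys / sc)
  if (anyNA(vals)) stop("segment exits the image")
  mean(vals)
}

# Bilinear interpolation on pixel centres: pixel (i, j) centre at
# (j - 0.5, i - 0.5) in pixel units. xp, yp in pixel units. Returns NA
# outside the grid of pixel centres extended by half a pixel (edge pixels
# clamp within the outer half-pixel band).
bilinear_sample <- function(m, xp, yp) {
  nr <- nrow(m); nc <- ncol(m)
  out <- rep(NA_real_, length(xp))
  ok <- xp >= 0 & xp <= nc & yp >= 0 & yp <= nr
  cx <- pmin(pmax(xp[ok] - 0.5, 0), nc - 1)
  cy <- pmin(pmax(yp[ok] - 0.5, 0), nr - 1)
  j0 <- pmin(floor(cx), nc - 2); i0 <- pmin(floor(cy), nr - 2)
  if (nc == 1) j0 <- rep(0, length(cx))
  if (nr == 1) i0 <- rep(0, length(cy))
  fx <- cx - j0; fy <- cy - i0
  idx <- function(i, j) m[cbind(i + 1, j + 1)]
  v <- (1 - fx) * (1 - fy) * idx(i0, j0) +
    fx * (1 - fy) * idx(i0, pmin(j0 + 1, nc - 1)) +
    (1 - fx) * fy * idx(pmin(i0 + 1, nr - 1), j0) +
    fx * fy * idx(pmin(i0 + 1, nr - 1), pmin(j0 + 1, nc - 1))
  out[ok] <- v
  out
}
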