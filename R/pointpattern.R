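#' Planar point pattern in a rectangular observation window
#'
#' Container for the cell-body coordinates of one image: positions in
#' micrometres together with the axis-aligned observation window and the
#' image/retina/genotype labels used downstream for per-retina aggregation.
#' Coordinates follow the image convention (origin top-left, y increasing
#' downward); all geometry here is orientation-agnostic so this only matters
#' for plotting.
#'
#' @param x,y numeric vectors of equal length, positions in micrometres.
#' @param window numeric length-4 vector `c(x_min, y_min, x_max, y_max)` in
#'   micrometres, or `NULL` to use the tight bounding box of the points
#'   (a warning is issued because edge correction depends on the window).
#' @param image_id,retina_id,genotype single character labels.
#' @return An object of class `"ppattern"`: a list with elements `x`, `y`,
#'   `window`, `n`, `image_id`, `retina_id`, `genotype`.
#' @examples
#' p <- point_pattern(c(10, 50, 90), c(10, 50, 90),
#'                    window = c(0, 0, 100, 100))
#' p$n
#' @export
point_pattern <- function(x, y, window = NULL,
                          image_id = NA_character_,
                          retina_id = NA_character_,
                          genotype = NA_character_) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y))
    stop("x and y must have equal length")
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y))))
    stop("coordinates must be finite and non-missing")
  if (is.null(window)) {
    if (length(x) == 0)
      stop("cannot infer a window from an empty pattern; supply one")
    window <- c(min(x), min(y), max(x), max(y))
    warning("window not declared; using the tight bounding box of the points",
            call. = FALSE)
  }
  window <- as.numeric(window)
  if (length(window) != 4)
    stop("window must be c(x_min, y_min, x_max, y_max)")
  if (window[3] <= window[1] || window[4] <= window[2])
    stop("window must have strictly positive width and height")
  eps <- 1e-9 * max(1, abs(window))
  if (length(x) > 0 &&
      (any(x < window[1] - eps) || any(x > window[3] + eps) ||
       any(y < window[2] - eps) || any(y > window[4] + eps)))
    stop("point outside declared window")
  structure(list(x = x, y = y, window = window, n = length(x),
                 image_id = as.character(image_id),
                 retina_id = as.character(retina_id),
                 genotype = as.character(genotype)),
            class = "ppattern")
}

#' @export
print.ppattern <- function(x, ...) {
  w <- x$window
  cat(sprintf("Point pattern: %d points in [%g, %g] x [%g, %g] um\n",
              x$n, w[1], w[3], w[2], w[4]))
  if (!is.na(x$image_id))
    cat(sprintf("  image %s | retina %s | genotype %s\n",
                x$image_id, x$retina_id, x$genotype))
  invisible(x)
}

#' Area of the observation window
#' @param pattern a `ppattern`.
#' @return window area in square micrometres.
#' @export
window_area <- function(pattern) {
  w <- pattern$window
  (w[3] - w[1]) * (w[4] - w[2])
}

#' Overall density of a pattern
#' @param pattern a `ppattern`.
#' @return points per square micrometre.
#' @export
overall_density <- function(pattern) pattern$n / window_area(pattern)

# Pairwise Euclidean distances as a full matrix with Inf on the diagonal.
# Used by nearest-neighbour and duplicate checks; fine up to a few thousand
# points.
pair_dist_matrix <- function(pattern) {
  m <- as.matrix(stats::dist(cbind(pattern$x, pattern$y)))
  diag(m) <- Inf
  m
}

has_duplicates <- function(pattern, tol = 0) {
  if (pattern$n < 2) return(FALSE)
  any(stats::dist(cbind(pattern$x, pattern$y)) <= tol)
}
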