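#' Voronoi tessellation domain analysis
#'
#' Assigns every location in the window to the domain of its nearest cell
#' and measures the domain areas. Each cell's polygon is computed by
#' intersecting the window rectangle with the half-planes closer to that
#' cell than to each other cell (perpendicular-bisector clipping, with a
#' distance cutoff so only near neighbors are visited). Cells whose clipped
#' polygon touches the window boundary are excluded from the area
#' statistics — their domains are truncated by the field of view, not by
#' neighbors — and the exclusion count is reported.
#'
#' @param pattern a `ppattern` with at least 3 non-collinear points and no
#'   duplicates.
#' @return An object of class `"voronoi_result"`: list with `areas`
#'   (retained cells, um^2), `all_areas` (every cell, clipped to the
#'   window), `boundary` (logical, per cell), `n_excluded`, `mean_area`,
#'   `variance_area`, `vmr` (um^2), `cv2` (dimensionless), `polygons`.
#' @seealso [domain_vmr()]
#' @export
compute_domains <- function(pattern) {
  n <- pattern$n
  if (n < 3) stop("Voronoi domain analysis requires at least 3 points")
  x <- pattern$x; y <- pattern$y
  dm <- pair_dist_matrix(pattern)
  dup <- which(dm == 0, arr.ind = TRUE)
  if (nrow(dup) > 0)
    stop(sprintf("duplicate points %d and %d", min(dup[1, ]), max(dup[1, ])))
  # collinearity: all cross products of spanning vectors ~ 0
  cr <- (x - x[1]) * (y[2] - y[1]) - (y - y[1]) * (x[2] - x[1])
  span <- max(dm[is.finite(dm)])
  if (all(abs(cr) <= 1e-9 * span^2))
    stop("all points are collinear; tessellation undefined")

  w <- pattern$window
  btol <- 1e-9 * max(w[3] - w[1], w[4] - w[2])
  polys <- vector("list", n)
  areas <- numeric(n)
  boundary <- logical(n)
  for (i in seq_len(n)) {
    poly <- rect_polygon(w)
    ord <- order(dm[i, ])
    for (j in ord) {
      dj <- dm[i, j]
      # farther sites cannot cut once half their distance exceeds the
      # cell's current reach
      rmax <- sqrt(max((poly$x - x[i])^2 + (poly$y - y[i])^2))
      if (dj / 2 > rmax) break
      # half-plane closer to i than j: (pj - pi) . p <= (|pj|^2 - |pi|^2)/2
      a <- x[j] - x[i]; b <- y[j] - y[i]
      cc <- (x[j]^2 + y[j]^2 - x[i]^2 - y[i]^2) / 2
      poly <- clip_halfplane(poly, a, b, cc)
      if (length(poly$x) == 0) break
    }
    polys[[i]] <- poly
    areas[i] <- polygon_area(poly)
    boundary[i] <- length(poly$x) > 0 &&
      any(poly$x <= w[1] + btol | poly$x >= w[3] - btol |
          poly$y <= w[2] + btol | poly$y >= w[4] - btol)
  }
  retained <- areas[!boundary]
  mean_a <- if (length(retained) >= 1) mean(retained) else NA_real_
  var_a <- if (length(retained) >= 2) stats::var(retained) else NA_real_
  structure(list(
    areas = retained,
    all_areas = areas,
    boundary = boundary,
    n_excluded = sum(boundary),
    mean_area = mean_a,
    variance_area = var_a,
    vmr = var_a / mean_a,
    cv2 = var_a / mean_a^2,
    polygons = polys
  ), class = "voronoi_result")
}

#' @export
print.voronoi_result <- function(x, ...) {
  cat(sprintf(
    "Voronoi domains: %d retained, %d boundary-excluded\n",
    length(x$areas), x$n_excluded))
  if (length(x$areas) >= 2)
    cat(sprintf("  mean area %.4g um^2, VMR %.4g um^2, CV^2 %.4g\n",
                x$mean_area, x$vmr, x$cv2))
  invisible(x)
}

#' Variance-to-mean regularity of Voronoi domain areas
#'
#' Sample variance (n - 1) of the retained domain areas divided by their
#' mean. Lower values indicate a more regular mosaic. The VMR carries units
#' of area; the dimensionless variant `cv2 = variance / mean^2` is reported
#' alongside since only it is invariant under rescaling.
#'
#' @param result a `voronoi_result` with at least 2 retained areas.
#' @return the variance-to-mean ratio, in square micrometres.
#' @export
domain_vmr <- function(result) {
  if (length(result$areas) < 2)
    stop("domain_vmr requires at least 2 retained (interior) domains")
  result$vmr
}
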