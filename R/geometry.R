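# Analytic circle/rectangle intersection, used by the DRP edge correction.
#
# disk_rect_area(cx, cy, r, window) returns, for vectors of centres, the area
# of disk(centre, r) intersected with the rectangular window. Closed form via
# corner decomposition: with the disk translated to the origin,
#   area = G(x2,y2) - G(x1,y2) - G(x2,y1) + G(x1,y1)
# where G(a,b) = sign(a) sign(b) F(|a|,|b|) and F(a,b) is the area of the
# disk inside [0,a] x [0,b] (a,b >= 0).

# F(a, b) for a, b >= 0, vectorised; r scalar.
.disk_quadrant_area <- function(a, b, r) {
  if (r <= 0) return(numeric(length(a)))
  a <- pmin(a, r)
  b <- pmin(b, r)
  # integral of sqrt(r^2 - x^2) from 0 to t
  iseg <- function(t) 0.5 * (t * sqrt(pmax(r^2 - t^2, 0)) + r^2 * asin(pmin(t / r, 1)))
  out <- numeric(length(a))
  inside <- a^2 + b^2 <= r^2
  out[inside] <- (a * b)[inside]
  if (any(!inside)) {
    ai <- a[!inside]; bi <- b[!inside]
    xb <- sqrt(pmax(r^2 - bi^2, 0))   # x where the arc crosses height b
    out[!inside] <- ifelse(ai <= xb,
                           ai * bi,
                           bi * xb + iseg(ai) - iseg(xb))
  }
  out
}

.disk_corner <- function(a, b, r) {
  sign(a) * sign(b) * .disk_quadrant_area(abs(a), abs(b), r)
}

# Area of disk((cx, cy), r) intersected with window = c(x1, y1, x2, y2).
# cx, cy vectors; r scalar.
disk_rect_area <- function(cx, cy, r, window) {
  x1 <- window[1] - cx; x2 <- window[3] - cx
  y1 <- window[2] - cy; y2 <- window[4] - cy
  .disk_corner(x2, y2, r) - .disk_corner(x1, y2, r) -
    .disk_corner(x2, y1, r) + .disk_corner(x1, y1, r)
}

# --- convex polygon clipping (Sutherland-Hodgman against a half-plane) ----
# Polygons are lists with $x, $y (no repeated closing vertex).

# Keep the part of convex polygon `poly` with a*x + b*y <= c.
clip_halfplane <- function(poly, a, b, c) {
  n <- length(poly$x)
  if (n == 0) return(poly)
  px <- poly$x; py <- poly$y
  d <- a * px + b * py - c
  keep_all <- all(d <= 0)
  if (keep_all) return(poly)
  if (all(d > 0)) return(list(x = numeric(0), y = numeric(0)))
  nx <- numeric(0); ny <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    din <- d[i] <= 0
    djn <- d[j] <= 0
    if (din) { nx <- c(nx, px[i]); ny <- c(ny, py[i]) }
    if (xor(din, djn)) {
      t <- d[i] / (d[i] - d[j])
      nx <- c(nx, px[i] + t * (px[j] - px[i]))
      ny <- c(ny, py[i] + t * (py[j] - py[i]))
    }
  }
  list(x = nx, y = ny)
}

polygon_area <- function(poly) {
  n <- length(poly$x)
  if (n < 3) return(0)
  x <- poly$x; y <- poly$y
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

rect_polygon <- function(window) {
  list(x = window[c(1, 3, 3, 1)], y = window[c(2, 2, 4, 4)])
}
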