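# Planar polygon primitives. Polygons are n x 2 matrices (columns x, y, in
# micrometres), open (last vertex not repeated), counter-clockwise.

#' Signed polygon area (shoelace formula)
#'
#' Positive for counter-clockwise vertex order.
#'
#' @param poly n x 2 numeric matrix of vertices (open ring).
#' @return Signed area in the square of the coordinate unit.
#' @export
poly_area_signed <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon area (absolute)
#' @inheritParams poly_area_signed
#' @export
poly_area <- function(poly) abs(poly_area_signed(poly))

#' Polygon centroid
#' @inheritParams poly_area_signed
#' @return Length-2 numeric vector.
#' @export
poly_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(poly))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

ensure_ccw <- function(poly) {
  if (poly_area_signed(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

#' Points-in-polygon test (even-odd ray casting)
#'
#' @param pts m x 2 matrix of query points.
#' @param poly n x 2 polygon.
#' @return Logical vector of length m; boundary points count as inside.
#' @export
points_in_polygon <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  px <- pts[, 1]; py <- pts[, 2]
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Distance from each point to a segment set, vectorised over points.
pts_to_segments_min <- function(pts, segs_a, segs_b) {
  # pts m x 2; segs_a/segs_b k x 2 (segment endpoints)
  m <- nrow(pts); k <- nrow(segs_a)
  dx <- segs_b[, 1] - segs_a[, 1]
  dy <- segs_b[, 2] - segs_a[, 2]
  len2 <- dx^2 + dy^2
  len2[len2 == 0] <- .Machine$double.eps
  best <- rep(Inf, m)
  for (s in seq_len(k)) {
    t <- ((pts[, 1] - segs_a[s, 1]) * dx[s] + (pts[, 2] - segs_a[s, 2]) * dy[s]) / len2[s]
    t <- pmin(1, pmax(0, t))
    qx <- segs_a[s, 1] + t * dx[s]
    qy <- segs_a[s, 2] + t * dy[s]
    d <- sqrt((pts[, 1] - qx)^2 + (pts[, 2] - qy)^2)
    best <- pmin(best, d)
  }
  best
}

poly_edges <- function(poly) {
  n <- nrow(poly)
  list(a = poly, b = poly[c(2:n, 1), , drop = FALSE])
}

#' Minimum boundary-to-boundary distance between two disjoint polygons
#'
#' Brute-force vertex-to-edge search in both directions; exact for disjoint
#' polygons because the closest pair of two disjoint segments always involves
#' an endpoint. Returns 0 when the polygons touch or overlap.
#'
#' @param p1,p2 Polygons (n x 2 matrices).
#' @return Distance in the coordinate unit.
#' @export
poly_min_distance <- function(p1, p2) {
  if (any(points_in_polygon(p1, p2)) || any(points_in_polygon(p2, p1))) {
    return(0)
  }
  e1 <- poly_edges(p1); e2 <- poly_edges(p2)
  min(
    min(pts_to_segments_min(p1, e2$a, e2$b)),
    min(pts_to_segments_min(p2, e1$a, e1$b))
  )
}

#' Minimum distance from a polygon to a circle boundary (from inside)
#'
#' @param poly Polygon assumed inside the circle.
#' @param center Circle center (length-2).
#' @param radius Circle radius.
#' @export
poly_to_circle_gap <- function(poly, center, radius) {
  r <- sqrt((poly[, 1] - center[1])^2 + (poly[, 2] - center[2])^2)
  radius - max(r)
}

#' Regular n-gon approximation of an ellipse
#'
#' @param center Length-2 center.
#' @param a,b Semi-axes.
#' @param angle Rotation of the `a` axis, radians.
#' @param n Number of vertices.
#' @export
ellipse_poly <- function(center, a, b, angle = 0, n = 96) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- a * cos(th); y <- b * sin(th)
  ca <- cos(angle); sa <- sin(angle)
  cbind(center[1] + ca * x - sa * y, center[2] + sa * x + ca * y)
}

#' Circle polygon whose shoelace area is exactly pi r^2
#'
#' The vertex radius is inflated so the inscribed n-gon's area equals the
#' target circle area; area-based measures are then exact.
#' @param center Length-2 center.
#' @param radius Target circle radius (area pi r^2).
#' @param n Number of vertices.
#' @export
circle_poly_area_exact <- function(center, radius, n = 256) {
  r_vertex <- radius * sqrt(2 * pi / (n * sin(2 * pi / n)))
  ellipse_poly(center, r_vertex, r_vertex, 0, n)
}

#' Isoperimetric circularity 4 pi A / P^2
#' @inheritParams poly_area_signed
#' @export
poly_circularity <- function(poly) {
  n <- nrow(poly)
  nxt <- c(2:n, 1)
  per <- sum(sqrt(rowSums((poly[nxt, , drop = FALSE] - poly)^2)))
  4 * pi * poly_area(poly) / per^2
}

scale_poly <- function(poly, factor, center) {
  cbind(center[1] + (poly[, 1] - center[1]) * factor,
        center[2] + (poly[, 2] - center[2]) * factor)
}

translate_poly <- function(poly, v) {
  cbind(poly[, 1] + v[1], poly[, 2] + v[2])
}

polygon_contains <- function(outer, inner) {
  # contract the inner ring infinitesimally so shared boundaries count as
  # contained (ray casting is ill-defined exactly on an edge)
  ctr <- poly_centroid(inner)
  all(points_in_polygon(scale_poly(inner, 1 - 1e-9, ctr), outer))
}

#' Rasterize polygons onto a pixel grid
#'
#' Pixel centers at (i - 0.5) * pixel_size relative to `origin`; a pixel is
#' set when its center lies inside the polygon.
#'
#' @param polys List of polygons, rasterized in order (later ones overwrite).
#' @param values Integer value per polygon.
#' @param origin Physical coordinate of the grid corner (length-2).
#' @param dim_xy Grid size, pixels (nx, ny).
#' @param pixel_size Pixel edge, micrometres.
#' @return Integer matrix (ny rows = y, nx cols = x) with attributes
#'   `pixel_size` and `origin`.
#' @export
rasterize_polygons <- function(polys, values, origin, dim_xy, pixel_size) {
  nx <- dim_xy[1]; ny <- dim_xy[2]
  cx <- origin[1] + (seq_len(nx) - 0.5) * pixel_size
  cy <- origin[2] + (seq_len(ny) - 0.5) * pixel_size
  m <- matrix(0L, nrow = ny, ncol = nx)
  for (k in seq_along(polys)) {
    p <- polys[[k]]
    ix <- which(cx >= min(p[, 1]) - pixel_size & cx <= max(p[, 1]) + pixel_size)
    iy <- which(cy >= min(p[, 2]) - pixel_size & cy <= max(p[, 2]) + pixel_size)
    if (!length(ix) || !length(iy)) next
    pts <- cbind(rep(cx[ix], times = length(iy)), rep(cy[iy], each = length(ix)))
    inside <- points_in_polygon(pts, p)
    sub <- matrix(inside, nrow = length(iy), ncol = length(ix), byrow = TRUE)
    block <- m[iy, ix, drop = FALSE]
    block[sub] <- values[k]
    m[iy, ix] <- block
  }
  attr(m, "pixel_size") <- pixel_size
  attr(m, "origin") <- origin
  m
}
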