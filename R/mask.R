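# 2D binary masks with physical pixel size. Stored as numeric matrices
# (rows = y, cols = x) with attributes pixel_size (um) and origin (um, the
# physical coordinate of the corner of pixel [1,1]).

#' Construct a 2D mask
#'
#' @param m Numeric/integer matrix, rows = y, cols = x.
#' @param pixel_size Pixel edge, micrometres.
#' @param origin Physical coordinate (x, y) of the grid corner; pixel
#'   centers sit at `origin + (index - 0.5) * pixel_size`.
#' @export
mask2d <- function(m, pixel_size, origin = c(0, 0)) {
  m <- as.matrix(m)
  attr(m, "pixel_size") <- pixel_size
  attr(m, "origin") <- origin
  class(m) <- c("mask2d", class(m))
  m
}

mask_pixel_size <- function(m) attr(m, "pixel_size") %||% 1
mask_origin <- function(m) attr(m, "origin") %||% c(0, 0)

# physical coordinates of pixel centers
mask_axes <- function(m) {
  ps <- mask_pixel_size(m); o <- mask_origin(m)
  list(x = o[1] + (seq_len(ncol(m)) - 0.5) * ps,
       y = o[2] + (seq_len(nrow(m)) - 0.5) * ps)
}

#' Bilinear sampling of an image at physical points
#'
#' Points outside the grid return `outside`.
#'
#' @param m A [mask2d()] (or any matrix with pixel metadata).
#' @param pts n x 2 matrix of physical (x, y) coordinates.
#' @param outside Fill value outside the image.
#' @return Numeric vector of length n.
#' @export
bilinear_sample <- function(m, pts, outside = 0) {
  ps <- mask_pixel_size(m); o <- mask_origin(m)
  # continuous pixel coordinates (1-based at pixel centers)
  cx <- (pts[, 1] - o[1]) / ps + 0.5
  cy <- (pts[, 2] - o[2]) / ps + 0.5
  x0 <- floor(cx); y0 <- floor(cy)
  fx <- cx - x0; fy <- cy - y0
  nr <- nrow(m); nc <- ncol(m)
  get <- function(ix, iy) {
    ok <- ix >= 1 & ix <= nc & iy >= 1 & iy <= nr
    v <- rep(outside, length(ix))
    v[ok] <- m[cbind(iy[ok], ix[ok])]
    v
  }
  v00 <- get(x0, y0);     v10 <- get(x0 + 1, y0)
  v01 <- get(x0, y0 + 1); v11 <- get(x0 + 1, y0 + 1)
  v <- (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
  fully_out <- cx < 0.5 | cx > nc + 0.5 | cy < 0.5 | cy > nr + 0.5
  v[fully_out] <- outside
  v
}

#' Center of mass of a mask, physical coordinates
#' @param m A [mask2d()].
#' @export
mask_com <- function(m) {
  ax <- mask_axes(m)
  w <- sum(m)
  if (w == 0) nm_abort("EMPTY_MASK", "mask has no foreground")
  c(sum(colSums(m) * ax$x), sum(rowSums(m) * ax$y)) / w
}

#' Dice overlap coefficient of two binary masks (same grid)
#' @param a,b Binary matrices of identical shape.
#' @export
dice_coefficient <- function(a, b) {
  a <- a > 0.5; b <- b > 0.5
  2 * sum(a & b) / (sum(a) + sum(b))
}

# Resample an image onto a new grid by sampling at mapped physical points.
# map_fun maps output physical coords -> input physical coords.
resample_mask <- function(m, map_fun, out_dim, out_pixel, out_origin,
                          binarize = TRUE) {
  xs <- out_origin[1] + (seq_len(out_dim[1]) - 0.5) * out_pixel
  ys <- out_origin[2] + (seq_len(out_dim[2]) - 0.5) * out_pixel
  pts <- cbind(rep(xs, times = out_dim[2]), rep(ys, each = out_dim[1]))
  src <- map_fun(pts)
  v <- bilinear_sample(m, src)
  if (binarize) v <- as.numeric(v >= 0.5)
  mask2d(matrix(v, nrow = out_dim[2], ncol = out_dim[1], byrow = TRUE),
         out_pixel, out_origin)
}
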