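# Metadata-tier co-registration: stylus trace post-processing, landmark
# rigid fits, anatomical-level fraction mapping, histology slice estimation.

#' Trim a dense trace cloud and fit a cubic B-spline curve
#'
#' Trimming keeps points greedily along the acquisition order, enforcing a
#' minimum inter-point spacing; the curve is a least-squares cubic B-spline
#' per coordinate over normalized chord length.
#'
#' @param cloud n x 3 matrix of trace points (mm), in acquisition order.
#' @param target_spacing Minimum spacing kept by trimming (mm).
#' @param df Degrees of freedom of the B-spline basis (default adapts to
#'   the number of kept points).
#' @return Object of class `fitted_curve`: `curve(t)` for t in [0, 1],
#'   `rms_residual` (mm), `kept` (trimmed points), `n_kept`.
#' @export
trim_and_fit_spline <- function(cloud, target_spacing, df = NULL) {
  cloud <- as.matrix(cloud)
  keep <- 1L
  last <- cloud[1, ]
  for (i in 2:nrow(cloud)) {
    if (sqrt(sum((cloud[i, ] - last)^2)) >= target_spacing) {
      keep <- c(keep, i)
      last <- cloud[i, ]
    }
  }
  kept <- cloud[keep, , drop = FALSE]
  n <- nrow(kept)
  if (n < 4) nm_abort("TOO_FEW_POINTS", "fewer than 4 points after trimming")
  tt <- c(0, cumsum(sqrt(rowSums(diff(kept)^2))))
  tt <- tt / max(tt)
  df <- df %||% max(4, min(floor(n / 4) + 3, 25))
  basis <- splines::bs(tt, df = df, degree = 3, intercept = TRUE,
                       Boundary.knots = c(0, 1))
  coefs <- qr.coef(qr(basis), kept)
  coefs[is.na(coefs)] <- 0
  fitted <- basis %*% coefs
  rms <- sqrt(mean(rowSums((fitted - kept)^2)))
  curve <- function(t) {
    b <- splines::bs(pmin(1, pmax(0, t)), df = df, degree = 3,
                     intercept = TRUE, Boundary.knots = c(0, 1))
    unname(b %*% coefs)
  }
  structure(list(curve = curve, rms_residual = rms, kept = kept, n_kept = n,
                 df = df),
            class = "fitted_curve")
}

#' Centroid of a landmark point cloud
#' @param cloud n x 3 matrix (mm).
#' @return Length-3 arithmetic mean.
#' @export
landmark_centroid <- function(cloud) {
  cloud <- as.matrix(cloud)
  if (nrow(cloud) < 1) nm_abort("EMPTY_CLOUD", "landmark cloud is empty")
  colMeans(cloud)
}

#' Least-squares rigid fit between named landmark sets
#'
#' Kabsch/SVD solution (rotation + translation, no scale) mapping source
#' landmarks onto destination landmarks matched by name.
#'
#' @param src,dst Named matrices (rownames = landmark names, columns xyz).
#' @return Object of class `rigid3d`: `rotation` (3 x 3), `translation`,
#'   `rms_residual`, and `transform_points()` support via
#'   [apply_transform_points()].
#' @export
register_landmarks_rigid <- function(src, dst) {
  shared <- intersect(rownames(src), rownames(dst))
  if (length(shared) < 3) {
    nm_abort("NAME_MISMATCH", "need >= 3 shared landmark names")
  }
  P <- as.matrix(src[shared, , drop = FALSE])
  Q <- as.matrix(dst[shared, , drop = FALSE])
  pbar <- colMeans(P); qbar <- colMeans(Q)
  Pc <- sweep(P, 2, pbar); Qc <- sweep(Q, 2, qbar)
  sv <- svd(t(Pc) %*% Qc)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-12)) {
    nm_abort("DEGENERATE_CONFIGURATION", "landmarks are collinear")
  }
  dsign <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, dsign)) %*% t(sv$u)
  tvec <- qbar - as.vector(R %*% pbar)
  mapped <- t(R %*% t(P)) + matrix(tvec, nrow(P), 3, byrow = TRUE)
  rms <- sqrt(mean(rowSums((mapped - Q)^2)))
  structure(list(rotation = R, translation = tvec, rms_residual = rms,
                 landmarks = shared),
            class = "rigid3d")
}

#' Map a position between spaces by anatomical-level fraction
#'
#' Positions are expressed as superior-inferior arc coordinates; the query's
#' fractional position between its two bracketing matched levels in space A
#' is preserved in space B.
#'
#' @param query Scalar (or vector) arc position in space A.
#' @param levels_a,levels_b Named numeric vectors of level positions; names
#'   must match across spaces.
#' @return Mapped position(s) in space B.
#' @export
map_by_level_fraction <- function(query, levels_a, levels_b) {
  shared <- intersect(names(levels_a), names(levels_b))
  if (length(shared) < 2) nm_abort("UNBRACKETED_QUERY", "need >= 2 matched levels")
  a <- levels_a[shared]; b <- levels_b[shared]
  ord <- order(a)
  a <- a[ord]; b <- b[ord]
  vapply(query, function(q) {
    if (q < a[1] || q > a[length(a)]) {
      nm_abort("UNBRACKETED_QUERY", sprintf(
        "query %.3f not bracketed by matched levels [%.3f, %.3f]",
        q, a[1], a[length(a)]))
    }
    i <- max(which(a <= q))
    if (i == length(a)) return(unname(b[i]))
    f <- (q - a[i]) / (a[i + 1] - a[i])
    unname(b[i] + f * (b[i + 1] - b[i]))
  }, numeric(1))
}

#' Histology slide metadata record
#'
#' @param subject_id Subject identifier.
#' @param sample_id Sample identifier; must match the `SR###-XX#` grammar
#'   (e.g. "SR008-CL1").
#' @param block_id Grid coordinate of the paraffin block.
#' @param slice_depth_um Depth of the slice within the block, micrometres.
#' @param scene_id Scene (nerve cross section within the slide).
#' @param stain Stain or primary antibody name.
#' @export
histology_metadata <- function(subject_id, sample_id, block_id,
                               slice_depth_um, scene_id = 1, stain = "H&E") {
  if (!grepl("^SR[0-9]{3}-[A-Z]+[0-9]$", sample_id)) {
    nm_abort("INVALID_ARGUMENT",
             sprintf("sample id '%s' does not match the SR###-XX# grammar", sample_id))
  }
  stopifnot_scalar_num(slice_depth_um, "slice_depth_um", 0)
  structure(list(subject_id = subject_id, sample_id = sample_id,
                 block_id = block_id, slice_depth_um = slice_depth_um,
                 scene_id = scene_id, stain = stain),
            class = "histology_metadata")
}

#' Estimate the microCT z-slice corresponding to a histology slide
#'
#' The slice index is the annotated gridline of the slide's block plus the
#' slice depth divided by the voxel size, rounded to the nearest slice.
#'
#' @param meta A [histology_metadata()].
#' @param gridlines Data frame with columns `block_id`, `z_index`
#'   (0-based microCT slice of each gridline annotation).
#' @param voxel_size MicroCT voxel size, micrometres (default 11.4).
#' @param block_extent_um Optional physical extent of a block; depths beyond
#'   it raise an error.
#' @return Integer microCT z index (0-based).
#' @export
estimate_histology_slice <- function(meta, gridlines, voxel_size = 11.4,
                                     block_extent_um = NULL) {
  row <- gridlines[gridlines$block_id == meta$block_id, , drop = FALSE]
  if (nrow(row) == 0) {
    nm_abort("GRIDLINE_ABSENT",
             sprintf("no gridline annotation for block '%s'", meta$block_id))
  }
  if (!is.null(block_extent_um) && meta$slice_depth_um > block_extent_um) {
    nm_abort("OUT_OF_BLOCK", "slice depth exceeds the block extent")
  }
  as.integer(round(row$z_index[1] + meta$slice_depth_um / voxel_size))
}
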