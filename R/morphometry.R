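# Fascicular morphometry: effective diameters, perineurium thickness,
# split/merge detection, centerlines, transverse reslicing.

#' Effective circular diameter of a region
#'
#' The diameter of a circle with the same cross-sectional area as the
#' region: `2 sqrt(A / pi)`. Accepts a polygon (n x 2 matrix, micrometres)
#' or a binary mask (area = pixel count x pixel_size^2).
#'
#' @param region Polygon or [mask2d()] (any matrix with >2 columns is
#'   treated as a mask if `pixel_size` is supplied).
#' @param pixel_size Pixel size for plain-matrix masks, micrometres.
#' @return Effective diameter, micrometres.
#' @export
effective_circular_diameter <- function(region, pixel_size = NULL) {
  a <- region_area(region, pixel_size)
  if (a <= 0) nm_abort("EMPTY_REGION", "region has zero area")
  2 * sqrt(a / pi)
}

region_area <- function(region, pixel_size = NULL) {
  if (inherits(region, "mask2d") || (!is.null(pixel_size) && is.matrix(region))) {
    ps <- pixel_size %||% mask_pixel_size(region)
    sum(region > 0) * ps^2
  } else if (is.matrix(region) && ncol(region) == 2) {
    if (nrow(region) < 3) nm_abort("EMPTY_REGION", "polygon needs >= 3 vertices")
    poly_area(region)
  } else {
    nm_abort("INVALID_ARGUMENT",
             "region must be an n x 2 polygon or a mask with a pixel size")
  }
}

#' Perineurium thickness from inner and outer boundary polygons
#'
#' Area-equivalent definition: half the difference of the effective
#' circular diameters of the outer and inner boundaries. Rotation-invariant
#' and consistent with the effective-diameter convention.
#'
#' @param inner,outer Polygons (micrometres); `inner` must lie inside `outer`.
#' @return Thickness, micrometres.
#' @export
perineurium_thickness <- function(inner, outer) {
  if (!polygon_contains(outer, inner)) {
    nm_abort("GEOMETRY_ORDER", "inner boundary must lie inside the outer boundary")
  }
  (effective_circular_diameter(outer) - effective_circular_diameter(inner)) / 2
}

#' Morphometrics of a nerve cross section
#'
#' Nerve effective diameter from the epineurium polygon, per-fascicle
#' effective diameters from the inner-perineurium polygons, and
#' area-equivalent perineurium thicknesses.
#'
#' @param section A [cross_section()].
#' @return Object of class `morphometrics` with a per-fascicle tibble;
#'   see [tidy.morphometrics()] and [glance.morphometrics()].
#' @export
measure_cross_section <- function(section) {
  stopifnot(inherits(section, "cross_section"))
  nerve_d <- effective_circular_diameter(section$epineurium)
  n <- length(section$fascicles)
  fasc <- tibble::tibble(
    fascicle_id = seq_len(n),
    effective_diameter_um = vapply(section$fascicles, function(f)
      effective_circular_diameter(f$inner), numeric(1)),
    perineurium_thickness_um = vapply(section$fascicles, function(f)
      perineurium_thickness(f$inner, f$outer), numeric(1)),
    inner_area_um2 = vapply(section$fascicles, function(f)
      poly_area(f$inner), numeric(1)),
    outer_area_um2 = vapply(section$fascicles, function(f)
      poly_area(f$outer), numeric(1))
  )
  structure(
    list(nerve_effective_diameter_um = nerve_d,
         fascicle_count = n,
         fascicles = fasc,
         modality_tag = section$modality_tag),
    class = "morphometrics"
  )
}

#' @export
print.morphometrics <- function(x, ...) {
  cat(sprintf("<morphometrics> nerve %.1f um, %d fascicle(s)\n",
              x$nerve_effective_diameter_um, x$fascicle_count))
  print(x$fascicles)
  invisible(x)
}

# Connected components of one binary slice (4-neighbourhood), with small
# components (raster artifacts) suppressed.
slice_components <- function(slice, min_voxels) {
  lab <- label_components(slice > 0)
  if (min_voxels > 1 && max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    drop <- which(sizes < min_voxels)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  lab
}

#' Detect fascicle split and merge events along a label volume
#'
#' For each consecutive slice pair the bipartite overlap graph of
#' foreground connected components is built (overlap = >= 1 shared voxel
#' footprint, components below `min_component_voxels` ignored). A component
#' with >= 2 successors is a split; one with >= 2 predecessors is a merge.
#' The event rate is normalized by the analyzed length
#' `(slices - 1) x voxel_size`.
#'
#' @param volume A [label_volume()] with at least 2 slices.
#' @param min_component_voxels Minimum component size considered.
#' @return Object of class `split_merge_report`: tibble of events
#'   (`z_index` 0-based, `type`, `parent_labels`, `child_labels`), plus
#'   `rate_per_mm` and `length_analyzed_mm`.
#' @export
detect_split_merge <- function(volume, min_component_voxels = 5) {
  stopifnot(inherits(volume, "label_volume"))
  L <- volume$labels
  nz <- dim(L)[1]
  if (nz < 2) nm_abort("INVALID_ARGUMENT", "volume needs >= 2 slices")

  events <- list()
  prev <- slice_components(L[1, , ], min_component_voxels)
  for (iz in 2:nz) {
    cur <- slice_components(L[iz, , ], min_component_voxels)
    both <- prev > 0 & cur > 0
    if (any(both)) {
      ov <- table(prev[both], cur[both])
      # majority volume label per component, for reporting
      maj <- function(compmat, slicemat, id) {
        v <- slicemat[compmat == id]
        as.integer(names(which.max(table(v[v > 0]))))
      }
      succ <- rowSums(ov > 0)
      for (a in names(succ)[succ >= 2]) {
        kids <- colnames(ov)[ov[a, ] > 0]
        events[[length(events) + 1]] <- tibble::tibble(
          z_index = iz - 1, type = "split",
          parent_labels = as.character(maj(prev, L[iz - 1, , ], as.integer(a))),
          child_labels = paste(vapply(as.integer(kids), function(k)
            maj(cur, L[iz, , ], k), integer(1)), collapse = ","))
      }
      pred <- colSums(ov > 0)
      for (b in names(pred)[pred >= 2]) {
        pars <- rownames(ov)[ov[, b] > 0]
        events[[length(events) + 1]] <- tibble::tibble(
          z_index = iz - 1, type = "merge",
          parent_labels = paste(vapply(as.integer(pars), function(k)
            maj(prev, L[iz - 1, , ], k), integer(1)), collapse = ","),
          child_labels = as.character(maj(cur, L[iz, , ], as.integer(b))))
      }
    }
    prev <- cur
  }
  ev <- if (length(events)) dplyr::bind_rows(events) else
    tibble::tibble(z_index = numeric(0), type = character(0),
                   parent_labels = character(0), child_labels = character(0))
  ev <- dplyr::arrange(ev, .data$z_index)
  len_mm <- (nz - 1) * volume$voxel_size / 1000
  structure(
    list(events = ev, rate_per_mm = nrow(ev) / len_mm,
         length_analyzed_mm = len_mm),
    class = "split_merge_report"
  )
}

#' @export
print.split_merge_report <- function(x, ...) {
  cat(sprintf("<split_merge_report> %d event(s) over %.2f mm (%.3f events/mm)\n",
              nrow(x$events), x$length_analyzed_mm, x$rate_per_mm))
  if (nrow(x$events)) print(x$events)
  invisible(x)
}

#' Extract the centerline of one label of a volume
#'
#' Per-slice centroid of the labeled voxels, linked along z and smoothed
#' with a moving average; arc length accumulated from point spacing.
#'
#' @param volume A [label_volume()].
#' @param label Integer label to follow (default: whole foreground).
#' @param smooth_window Moving-average window, slices (odd).
#' @return Object of class `centerline`: tibble `x_um, y_um, z_um,
#'   arc_length_um`.
#' @export
extract_centerline <- function(volume, label = NULL, smooth_window = 5) {
  stopifnot(inherits(volume, "label_volume"))
  L <- volume$labels
  vx <- volume$voxel_size
  nz <- dim(L)[1]
  pts <- matrix(NA_real_, nz, 3)
  for (iz in seq_len(nz)) {
    sl <- L[iz, , ]
    sel <- if (is.null(label)) sl > 0 else sl == label
    if (!any(sel)) next
    idx <- which(sel, arr.ind = TRUE)  # rows = y index, cols = x index
    pts[iz, ] <- c(mean(idx[, 2] - 1) * vx, mean(idx[, 1] - 1) * vx,
                   (iz - 1) * vx)
  }
  keep <- !is.na(pts[, 1])
  if (sum(keep) < 2) {
    nm_abort("LABEL_ABSENT", "label present in fewer than 2 slices")
  }
  pts <- pts[keep, , drop = FALSE]
  if (smooth_window > 1 && nrow(pts) > smooth_window) {
    w <- smooth_window
    half <- floor(w / 2)
    sm <- pts
    for (k in seq_len(nrow(pts))) {
      lo <- max(1, k - half); hi <- min(nrow(pts), k + half)
      sm[k, 1:2] <- colMeans(pts[lo:hi, 1:2, drop = FALSE])
    }
    pts <- sm
  }
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  structure(
    list(points = tibble::tibble(x_um = pts[, 1], y_um = pts[, 2],
                                 z_um = pts[, 3], arc_length_um = arc),
         voxel_size = vx),
    class = "centerline"
  )
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, arc length %.1f um\n",
              nrow(x$points), max(x$points$arc_length_um)))
  invisible(x)
}

centerline_frame <- function(centerline, arc_position) {
  p <- as.matrix(centerline$points[, c("x_um", "y_um", "z_um")])
  arc <- centerline$points$arc_length_um
  if (arc_position < 0 || arc_position > max(arc)) {
    nm_abort("OUT_OF_RANGE", "arc position outside the centerline")
  }
  at <- function(s) {
    c(stats::approx(arc, p[, 1], s, rule = 2)$y,
      stats::approx(arc, p[, 2], s, rule = 2)$y,
      stats::approx(arc, p[, 3], s, rule = 2)$y)
  }
  h <- max(max(arc) / 200, centerline$voxel_size)
  p0 <- at(arc_position)
  tg <- at(min(arc_position + h, max(arc))) - at(max(arc_position - h, 0))
  tg <- tg / sqrt(sum(tg^2))
  u <- c(tg[2], -tg[1], 0)
  if (sqrt(sum(u^2)) < 1e-9) u <- c(1, 0, 0) else u <- u / sqrt(sum(u^2))
  v <- c(tg[2] * u[3] - tg[3] * u[2],
         tg[3] * u[1] - tg[1] * u[3],
         tg[1] * u[2] - tg[2] * u[1])
  list(origin = p0, tangent = tg, u = u, v = v)
}

#' Transverse reslice of a label volume
#'
#' Samples the plane orthogonal to the centerline tangent at the given arc
#' position by nearest-neighbor interpolation at the volume's native
#' resolution, so oblique tubes can be measured with true cross sections.
#'
#' @param volume A [label_volume()].
#' @param centerline A [extract_centerline()] result.
#' @param arc_position Arc position along the centerline, micrometres.
#' @param plane_size Side length of the sampled plane, micrometres.
#' @return A [mask2d()] of labels at `voxel_size` spacing.
#' @export
reslice_transverse <- function(volume, centerline, arc_position, plane_size) {
  fr <- centerline_frame(centerline, arc_position)
  vx <- volume$voxel_size
  nhalf <- ceiling(plane_size / 2 / vx)
  s <- (-nhalf:nhalf) * vx
  uu <- rep(s, times = length(s)); vv <- rep(s, each = length(s))
  pts <- cbind(fr$origin[1] + uu * fr$u[1] + vv * fr$v[1],
               fr$origin[2] + uu * fr$u[2] + vv * fr$v[2],
               fr$origin[3] + uu * fr$u[3] + vv * fr$v[3])
  L <- volume$labels
  d <- dim(L)
  ix <- round(pts[, 1] / vx) + 1
  iy <- round(pts[, 2] / vx) + 1
  iz <- round(pts[, 3] / vx) + 1
  ok <- ix >= 1 & ix <= d[3] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[1]
  val <- integer(nrow(pts))
  val[ok] <- L[cbind(iz[ok], iy[ok], ix[ok])]
  m <- matrix(val, nrow = length(s), ncol = length(s), byrow = TRUE)
  mask2d(m, vx, origin = c(s[1] - vx / 2, s[1] - vx / 2))
}
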