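# Core geometric containers shared across modules.

#' Cross-section geometry of a nerve
#'
#' Polygons for the epineurium boundary and, per fascicle, the inner and
#' outer perineurium boundaries, all in physical micrometre coordinates.
#'
#' @param epineurium n x 2 polygon (micrometres, counter-clockwise).
#' @param fascicles List of `list(inner =, outer =)` polygon pairs.
#' @param pixel_size Pixel size of the originating raster, micrometres.
#' @param modality_tag Free-text label of the originating modality.
#' @return An object of class `cross_section`.
#' @export
cross_section <- function(epineurium, fascicles = list(), pixel_size = NA_real_,
                          modality_tag = "synthetic") {
  epineurium <- ensure_ccw(as.matrix(epineurium))
  fascicles <- lapply(fascicles, function(f) {
    inner <- ensure_ccw(as.matrix(f$inner))
    outer <- ensure_ccw(as.matrix(f$outer))
    if (!polygon_contains(outer, inner)) {
      nm_abort("GEOMETRY_ORDER", "fascicle inner boundary must lie inside the outer boundary")
    }
    list(inner = inner, outer = outer)
  })
  for (f in fascicles) {
    if (!polygon_contains(epineurium, f$outer)) {
      nm_abort("GEOMETRY_ORDER", "every fascicle must lie inside the epineurium boundary")
    }
  }
  structure(
    list(epineurium = epineurium, fascicles = fascicles,
         pixel_size = pixel_size, modality_tag = modality_tag),
    class = "cross_section"
  )
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf(
    "<cross_section> %d fascicle(s), nerve effective diameter %.1f um [%s]\n",
    length(x$fascicles), 2 * sqrt(poly_area(x$epineurium) / pi), x$modality_tag
  ))
  invisible(x)
}

#' 3D labeled fascicle volume
#'
#' Integer labels in a (z, y, x) array, 0 = background, isotropic voxels.
#' z increases superior to inferior; physical coordinates are
#' `(index - 1) * voxel_size` at voxel centers (0-based physical convention).
#'
#' @param labels 3D integer array, dimension order (z, y, x).
#' @param voxel_size Isotropic voxel edge, micrometres.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, voxel_size) {
  stopifnot_scalar_num(voxel_size, "voxel_size", 0, strict = TRUE)
  if (length(dim(labels)) != 3) {
    nm_abort("INVALID_ARGUMENT", "`labels` must be a 3D array ordered (z, y, x)")
  }
  if (any(labels < 0)) nm_abort("INVALID_ARGUMENT", "labels must be >= 0")
  structure(list(labels = labels, voxel_size = voxel_size), class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d x %d x %d (z,y,x) at %.2f um/voxel, %d label(s)\n",
              d[1], d[2], d[3], x$voxel_size,
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}
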