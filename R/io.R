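# Interchange I/O: multi-page TIFF label volumes with JSON sidecars,
# co-registration metadata JSON, morphometrics/threshold CSV, run config.

#' Write a label volume as multi-page TIFF plus JSON sidecar
#'
#' Pixel data is stored as 16-bit; the voxel size travels in
#' `<path>.json`. Round-trips are byte-exact on the label array.
#'
#' @param volume A [label_volume()] (labels must fit 16 bits).
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(volume, path) {
  stopifnot(inherits(volume, "label_volume"))
  L <- volume$labels
  if (max(L) > 65535) nm_abort("FORMAT_ERROR", "labels exceed 16-bit range")
  pages <- lapply(seq_len(dim(L)[1]), function(iz) L[iz, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(voxel_size_um = volume$voxel_size, axis_order = "ZYX",
         n_slices = dim(L)[1], schema_version = "1.0"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a label volume written by [write_label_volume()]
#'
#' @param path TIFF path; `<path>.json` must hold the voxel size.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    nm_abort("MISSING_SIDECAR", sprintf("no sidecar JSON next to %s", path))
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) any(p != round(p) | p < 0), logical(1)))) {
    nm_abort("FORMAT_ERROR", "label TIFF must hold non-negative integer pixels")
  }
  d <- dim(pages[[1]])
  L <- array(0L, dim = c(length(pages), d[1], d[2]))
  for (iz in seq_along(pages)) L[iz, , ] <- as.integer(pages[[iz]])
  label_volume(L, meta$voxel_size_um)
}

# Required co-registration JSON fields: common plus per-modality payloads.
coreg_required_fields <- function(modality) {
  common <- c("modality", "subject_id", "n_dimensions",
              "anatomical_axes_order", "image_axes_order",
              "pixel_count", "pixel_size_um", "coregistration")
  extra <- switch(modality,
    ct = character(0),
    mri = character(0),
    tracing = character(0),
    microct = "sample_id",
    histology = c("sample_id", "block_id", "scene_id", "slice_depth_um",
                  "stain"),
    nm_abort("SCHEMA_VIOLATION", sprintf("unknown modality '%s'", modality))
  )
  payload <- switch(modality,
    ct = "anatomical_landmarks",
    mri = "anatomical_landmarks",
    tracing = c("anatomical_landmarks_mri", "anatomical_landmarks_ct",
                "anatomical_levels", "branch_points"),
    microct = c("gridlines", "level_centerline_coordinates",
                "sample_translations"),
    histology = c("anatomical_label", "approximate_microct_image")
  )
  list(top = c(common, extra), payload = payload)
}

#' Write a co-registration metadata record to JSON
#'
#' @param record Named list with the per-modality fields (see
#'   [validate_coreg_json()] for the required set).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coreg_json <- function(record, path) {
  record$schema_version <- record$schema_version %||% "1.0"
  rep_ <- validate_coreg_record(record)
  if (!rep_$valid) {
    nm_abort("SCHEMA_VIOLATION", paste(
      "record incomplete:", paste(rep_$missing, collapse = ", ")))
  }
  jsonlite::write_json(record, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

validate_coreg_record <- function(record) {
  missing <- character(0)
  mod <- record$modality
  if (is.null(mod)) {
    return(list(valid = FALSE, missing = "modality", modality = NA))
  }
  req <- coreg_required_fields(mod)
  for (f in req$top) if (is.null(record[[f]])) missing <- c(missing, f)
  if (!is.null(record$coregistration)) {
    for (f in req$payload) {
      if (is.null(record$coregistration[[f]])) {
        missing <- c(missing, paste0("coregistration.", f))
      }
    }
  }
  sid <- record$sample_id
  if (!is.null(sid) && !grepl("^SR[0-9]{3}-[A-Z]+[0-9]$", sid)) {
    missing <- c(missing, "sample_id (grammar SR###-XX#)")
  }
  list(valid = length(missing) == 0, missing = missing, modality = mod)
}

#' Validate a co-registration JSON file
#'
#' Checks the per-modality required fields (identifiers, axes orders, pixel
#' geometry, and the modality's co-registration payload) and the sample-id
#' grammar, reporting every missing field.
#'
#' @param path JSON path.
#' @return List `valid`, `missing` (character), `modality`.
#' @export
validate_coreg_json <- function(path) {
  record <- jsonlite::read_json(path, simplifyVector = FALSE)
  validate_coreg_record(record)
}

#' Run configuration
#'
#' Schema-validated configuration for the pipeline; unknown keys are
#' rejected.
#'
#' @param seed Master seed.
#' @param phantom Named list of [phantom_spec()] overrides.
#' @param reshape Named list of [reshape_settings()] overrides.
#' @param registration Named list of [registration_settings()] overrides.
#' @param sim Named list of [sim_settings()] overrides.
#' @param field Named list: `voxel_um`, `domain_xy_mm`, `domain_z_mm`,
#'   `tol`, `max_iter`.
#' @param fiber_diameters_um Diameters simulated per fascicle.
#' @param out_dir Output directory.
#' @param verbosity 0-2.
#' @export
run_config <- function(seed = 1, phantom = list(), reshape = list(),
                       registration = list(), sim = list(), field = list(),
                       fiber_diameters_um = seq(2, 16, by = 2), out_dir = ".",
                       verbosity = 1) {
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) nm_abort("INVALID_ARGUMENT", sprintf(
      "unknown %s key(s): %s", where, paste(bad, collapse = ", ")))
  }
  check_keys(phantom, names(formals(phantom_spec)), "phantom")
  check_keys(reshape, names(formals(reshape_settings)), "reshape")
  check_keys(registration, names(formals(registration_settings)), "registration")
  check_keys(sim, names(formals(sim_settings)), "sim")
  check_keys(field, c("voxel_um", "domain_xy_mm", "domain_z_mm", "tol",
                      "max_iter"), "field")
  structure(list(seed = seed, phantom = phantom, reshape = reshape,
                 registration = registration, sim = sim, field = field,
                 fiber_diameters_um = fiber_diameters_um,
                 out_dir = out_dir, verbosity = verbosity),
            class = "run_config")
}

#' Read a run configuration from JSON
#' @param path JSON file with [run_config()] fields.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

#' Write a cross section to JSON (polygons in micrometres)
#' @param section A [cross_section()].
#' @param path Output path.
#' @export
write_cross_section_json <- function(section, path) {
  jsonlite::write_json(
    list(schema_version = "1.0",
         modality_tag = section$modality_tag,
         pixel_size_um = section$pixel_size,
         epineurium = section$epineurium,
         fascicles = lapply(section$fascicles, function(f)
           list(inner = f$inner, outer = f$outer))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cross section written by [write_cross_section_json()]
#' @param path JSON path.
#' @export
read_cross_section_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$epineurium)) nm_abort("FORMAT_ERROR", "not a cross-section JSON")
  fas <- x$fascicles
  if (is.data.frame(fas)) {
    fas <- lapply(seq_len(nrow(fas)), function(i)
      list(inner = fas$inner[[i]], outer = fas$outer[[i]]))
  }
  cross_section(x$epineurium, fas %||% list(),
                pixel_size = x$pixel_size_um %||% NA_real_,
                modality_tag = x$modality_tag %||% "unknown")
}

#' Serialize a transform (or chain) to JSON
#' @param chain A transform or list of transforms.
#' @param path Output path.
#' @export
write_transform_json <- function(chain, path) {
  if (!is.list(chain) || inherits(chain, c("rigid_transform",
                                           "bspline_transform", "rigid3d"))) {
    chain <- list(chain)
  }
  ser <- lapply(chain, function(t) {
    if (inherits(t, "rigid_transform")) {
      list(type = "rigid2d", mode = t$mode, scale = t$scale, angle = t$angle,
           translation = t$translation, center = t$center,
           converged = t$converged)
    } else if (inherits(t, "bspline_transform")) {
      list(type = "bspline", init = list(
        mode = t$init$mode, scale = t$init$scale, angle = t$init$angle,
        translation = t$init$translation, center = t$init$center),
        coef_x = t$coef_x, coef_y = t$coef_y, domain = as.list(t$domain),
        dice_rigid = t$dice_rigid, dice_bspline = t$dice_bspline)
    } else if (inherits(t, "rigid3d")) {
      list(type = "rigid3d", rotation = t$rotation, translation = t$translation,
           rms_residual = t$rms_residual)
    } else nm_abort("INVALID_ARGUMENT", "unknown transform type")
  })
  jsonlite::write_json(list(schema_version = "1.0", transforms = ser), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
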