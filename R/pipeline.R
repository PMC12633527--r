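# End-to-end chain: phantom -> morphometry -> reshape -> field -> thresholds
# -> dose-response. Deterministic for a fixed configuration.

#' Run the full stimulation-model pipeline on a synthetic nerve
#'
#' Generates a seeded phantom cross section and fiber population, inflates
#' it for shrinkage, circularizes it, builds the cuff model, solves the
#' potential field for both contacts, finds per-fascicle thresholds for the
#' configured fiber diameters at the fascicle centroids, interpolates them
#' quadratically across diameter, maps them to the population, and computes
#' the dose-response curve.
#'
#' @param config A [run_config()].
#' @return List with every intermediate stage and the final `dose_response`.
#' @export
run_pipeline <- function(config = run_config()) {
  spec <- do.call(phantom_spec, c(list(seed = config$seed), config$phantom))
  rs <- do.call(reshape_settings, config$reshape)
  sim <- do.call(sim_settings, c(list(duration_ms = 10), config$sim))
  fopt <- config$field

  cs <- gen_cross_section(spec)
  pop <- gen_fiber_population(spec, cs$geometry)
  morpho <- measure_cross_section(cs$geometry)

  inflated <- inflate_for_shrinkage(cs$geometry, rs$shrinkage)
  circ <- circularize_nerve(inflated, rs)
  geom <- build_cuff_geometry(circ)

  grid <- voxelize_geometry(
    geom,
    voxel_um = fopt$voxel_um %||% 100,
    domain_xy_mm = fopt$domain_xy_mm %||% 4,
    domain_z_mm = fopt$domain_z_mm %||% 10
  )
  fields <- lapply(seq_along(grid$contact_z_um), function(k) {
    solve_laplace_fd(grid, contact_source_voxel(grid, k),
                     tol = fopt$tol %||% 1e-8,
                     max_iter = fopt$max_iter %||% 20000)
  })

  # fibers run along z through each fascicle centroid; sample both contact
  # fields along that line at 1 um
  zmax <- dim(grid$region)[1] * grid$voxel_um
  scale_f <- 1 / (1 - rs$shrinkage)
  fits <- list()
  thresholds <- list()
  for (i in seq_along(circ$fascicles)) {
    ctr <- poly_centroid(circ$fascicles[[i]]$inner)
    zs <- grid$origin_um[3] + c(0.5, dim(grid$region)[1] - 1.5) * grid$voxel_um
    line <- rbind(c(ctr, zs[1]), c(ctr, zs[2]))
    s1 <- sample_potentials_along_line(fields[[1]], line, 1)
    s2 <- sample_potentials_along_line(fields[[2]], line, 1)
    th <- vapply(config$fiber_diameters_um, function(d) {
      fiber <- build_mrg_fiber(d, path_length_mm = diff(zs) / 1000,
                               center_um = mean(zs))
      sf <- superpose_contacts(s1$v_volts, s2$v_volts)
      ve1 <- compartment_potentials(
        tibble::tibble(arc_um = s1$arc_um, v_volts = sf$shape_volts),
        fiber, arc_offset_um = min(fiber$compartments$z_um) - zs[1],
        extend = TRUE)
      find_threshold(fiber, ve1, settings = sim)$threshold_mA
    }, numeric(1))
    thresholds[[i]] <- tibble::tibble(
      fascicle_id = i, diameter_um = config$fiber_diameters_um,
      threshold_mA = th)
    fits[[as.character(i)]] <-
      fit_quadratic_thresholds(config$fiber_diameters_um, th)
  }
  thresholds <- dplyr::bind_rows(thresholds)

  # population coordinates live in the original section frame; rescale and
  # recentre them into the circularized frame fascicle by fascicle
  pop_mapped <- pop
  for (i in seq_along(circ$fascicles)) {
    sel <- pop$fascicle_id == i
    src_c <- poly_centroid(cs$geometry$fascicles[[i]]$inner)
    dst_c <- poly_centroid(circ$fascicles[[i]]$inner)
    pop_mapped$x_um[sel] <- (pop$x_um[sel] - src_c[1]) * scale_f + dst_c[1]
    pop_mapped$y_um[sel] <- (pop$y_um[sel] - src_c[2]) * scale_f + dst_c[2]
  }

  tmap <- assign_population_thresholds(pop_mapped, fits)
  amax <- max(tmap$fibers$threshold_mA)
  dr <- dose_response_curve(tmap,
                            seq(0, 1.05 * amax, length.out = 101))

  list(spec = spec, section = cs, population = pop, morphometrics = morpho,
       circularized = circ, geometry = geom, grid = grid, fields = fields,
       fascicle_thresholds = thresholds, fits = fits,
       threshold_map = tmap, dose_response = dr)
}

#' Source voxel for a contact (point source at the contact center)
#'
#' @param grid A [voxelize_geometry()] result.
#' @param contact Contact index (1 or 2).
#' @return Voxel index `c(z, y, x)`.
#' @export
contact_source_voxel <- function(grid, contact) {
  if (contact > length(grid$contact_z_um)) {
    nm_abort("INVALID_ARGUMENT", "no such contact")
  }
  h <- grid$voxel_um; o <- grid$origin_um
  d <- dim(grid$region)
  iz <- round((grid$contact_z_um[[contact]] - o[3]) / h) + 1
  ix <- round((grid$contact_r_um - o[1]) / h) + 1
  iy <- round((0 - o[2]) / h) + 1
  iz <- min(max(iz, 2), d[1] - 1)
  ix <- min(max(ix, 2), d[3] - 1)
  iy <- min(max(iy, 2), d[2] - 1)
  plat <- which(grid$region == grid$regions$id[grid$regions$material == "platinum"],
                arr.ind = TRUE)
  if (nrow(plat)) {
    # snap to the nearest platinum voxel
    dd <- (plat[, 1] - iz)^2 + (plat[, 2] - iy)^2 + (plat[, 3] - ix)^2
    k <- which.min(dd)
    c(plat[k, 1], plat[k, 2], plat[k, 3])
  } else {
    c(iz, iy, ix)
  }
}
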