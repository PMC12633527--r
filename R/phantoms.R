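# Seeded synthetic nerve phantoms. Every generator returns its ground truth
# so downstream modules can be tested against known answers.

#' Specification for a synthetic nerve phantom
#'
#' Defaults emulate a mid-cervical nerve cross section: a ~2 mm nerve with a
#' handful of fascicles, microCT-like 11.4 um voxels for 3D volumes and
#' few-micron rasters for 2D sections.
#'
#' @param seed Master seed; all randomness derives from it through
#'   per-purpose streams (placement, diameters, warp, fibers, trace), so e.g.
#'   adding fibers does not perturb geometry.
#' @param nerve_diameter Effective nerve diameter, micrometres.
#' @param n_fascicles Number of fascicles.
#' @param fascicle_diameter_range Min/max effective fascicle diameter, um.
#' @param perineurium_fraction Perineurium ring thickness as a fraction of
#'   the fascicle (outer) effective radius.
#' @param min_gap Minimum boundary-to-boundary spacing enforced at
#'   generation, micrometres.
#' @param pixel_size Raster pixel size for 2D masks, micrometres.
#' @param voxel_size Isotropic voxel size for 3D volumes, micrometres
#'   (default 11.4, microCT-like).
#' @param z_extent Longitudinal extent of 3D volumes, micrometres.
#' @param event_schedule List of `list(z =, type = "split"|"merge",
#'   labels =)` entries with z strictly inside (0, z_extent).
#' @param fiber_density Myelinated fiber density, fibers per mm^2 of
#'   endoneurium.
#' @param diameter_mixture Gaussian mixture for fiber diameters: list of
#'   `c(weight, mean_um, sd_um)`; weights must sum to 1.
#' @param nerve_axis_ratio Major/minor axis ratio of the epineurium ellipse
#'   (1 = circular nerve).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed,
                         nerve_diameter = 2000,
                         n_fascicles = 6,
                         fascicle_diameter_range = c(150, 350),
                         perineurium_fraction = 0.08,
                         min_gap = 20,
                         pixel_size = 4,
                         voxel_size = 11.4,
                         z_extent = 5000,
                         event_schedule = list(),
                         fiber_density = 5000,
                         diameter_mixture = list(c(0.7, 4, 1), c(0.3, 9, 2)),
                         nerve_axis_ratio = 1) {
  stopifnot_scalar_num(seed, "seed")
  stopifnot_scalar_num(nerve_diameter, "nerve_diameter", 0, strict = TRUE)
  stopifnot_scalar_num(min_gap, "min_gap", 0)
  stopifnot_scalar_num(pixel_size, "pixel_size", 0, strict = TRUE)
  stopifnot_scalar_num(voxel_size, "voxel_size", 0, strict = TRUE)
  if (any(fascicle_diameter_range <= 0) || diff(fascicle_diameter_range) < 0) {
    nm_abort("INVALID_ARGUMENT", "fascicle_diameter_range must be positive and ordered")
  }
  if (perineurium_fraction <= 0 || perineurium_fraction >= 1) {
    nm_abort("INVALID_ARGUMENT", "perineurium_fraction must be in (0, 1)")
  }
  w <- vapply(diameter_mixture, `[`, numeric(1), 1)
  if (abs(sum(w) - 1) > 1e-8) {
    nm_abort("INVALID_ARGUMENT", "diameter mixture weights must sum to 1")
  }
  for (ev in event_schedule) {
    if (!is.list(ev) || is.null(ev$z) || !ev$type %in% c("split", "merge")) {
      nm_abort("INVALID_ARGUMENT", "schedule entries need z and type split|merge")
    }
    if (ev$z <= 0 || ev$z >= z_extent) {
      nm_abort("INVALID_ARGUMENT", "schedule z values must lie strictly inside (0, z_extent)")
    }
  }
  structure(
    list(seed = seed, nerve_diameter = nerve_diameter,
         n_fascicles = as.integer(n_fascicles),
         fascicle_diameter_range = fascicle_diameter_range,
         perineurium_fraction = perineurium_fraction, min_gap = min_gap,
         pixel_size = pixel_size, voxel_size = voxel_size,
         z_extent = z_extent, event_schedule = event_schedule,
         fiber_density = fiber_density, diameter_mixture = diameter_mixture,
         nerve_axis_ratio = nerve_axis_ratio),
    class = "phantom_spec"
  )
}

# Draw a point uniformly inside an axis-aligned ellipse.
runif_in_ellipse <- function(n, a, b) {
  r <- sqrt(stats::runif(n)); th <- stats::runif(n, 0, 2 * pi)
  cbind(a * r * cos(th), b * r * sin(th))
}

#' Generate a synthetic nerve cross section
#'
#' Fascicles are ellipses with axis ratio bounded by 2:1, placed by rejection
#' sampling under the spacing constraint. The drawn effective diameter of
#' each fascicle is exact by construction (semi-axes `a b = (d/2)^2`).
#'
#' @param spec A [phantom_spec()].
#' @param n_vertices Vertices per polygon.
#' @param attempt_cap Total rejection-sampling attempts before giving up
#'   with a `PACKING_INFEASIBLE` error.
#' @param tight_pair_gap Optional; after placement, translate fascicle 2
#'   toward fascicle 1 so their boundary gap equals this value (used to build
#'   sections that deliberately violate a downstream spacing constraint).
#' @return List with `geometry` (a [cross_section()]), `masks` (epineurium
#'   binary mask plus inner/outer fascicle label rasters), and
#'   `ground_truth` (per-fascicle tibble).
#' @export
gen_cross_section <- function(spec, n_vertices = 96, attempt_cap = 10000,
                              tight_pair_gap = NULL) {
  R <- spec$nerve_diameter / 2
  ar <- spec$nerve_axis_ratio
  epi_a <- R * sqrt(ar); epi_b <- R / sqrt(ar)
  epi <- ellipse_poly(c(0, 0), epi_a, epi_b, 0, max(n_vertices, 128))
  epi_edges <- poly_edges(epi)

  n <- spec$n_fascicles
  diams <- with_stream(spec$seed, "diameters",
                       stats::runif(n, spec$fascicle_diameter_range[1],
                                    spec$fascicle_diameter_range[2]))
  shape <- with_stream(spec$seed, "orientation", {
    list(ratio = stats::runif(n, 1, 2), angle = stats::runif(n, 0, pi))
  })

  placed <- vector("list", n)
  centers <- matrix(NA_real_, n, 2)
  circum <- numeric(n)
  order_by_size <- order(diams, decreasing = TRUE)  # big fascicles first
  with_stream(spec$seed, "placement", {
    attempts <- 0L
    for (i in order_by_size) {
      a <- diams[i] / 2 * sqrt(shape$ratio[i])
      b <- diams[i] / 2 / sqrt(shape$ratio[i])
      done <- which(!vapply(placed, is.null, logical(1)))
      ok <- FALSE
      while (!ok) {
        attempts <- attempts + 1L
        if (attempts > attempt_cap) {
          nm_abort("PACKING_INFEASIBLE", sprintf(
            "could not place %d fascicles at min_gap %.1f um within %d attempts",
            n, spec$min_gap, attempt_cap))
        }
        ctr <- if (n == 1) c(0, 0) else as.vector(runif_in_ellipse(1, epi_a, epi_b))
        # conservative quick accept for the boundary clearance: the ellipse
        # eroded by (circumradius + gap) is contained in the shrunken ellipse
        clear <- a + spec$min_gap + 1
        boundary_ok <- (epi_a > clear) && (epi_b > clear) &&
          (ctr[1] / (epi_a - clear))^2 + (ctr[2] / (epi_b - clear))^2 <= 1
        # bounding-circle prescreen against placed fascicles
        clash <- FALSE
        for (j in done) {
          dc <- sqrt(sum((ctr - centers[j, ])^2))
          if (dc - a - circum[j] < spec$min_gap) { clash <- TRUE; break }
        }
        if (clash) next
        cand <- ellipse_poly(ctr, a, b, shape$angle[i], n_vertices)
        if (!boundary_ok) {
          if (!all(points_in_polygon(cand, epi))) next
          if (min(pts_to_segments_min(cand, epi_edges$a, epi_edges$b)) <
              spec$min_gap) next
        }
        placed[[i]] <- cand
        centers[i, ] <- ctr
        circum[i] <- a
        ok <- TRUE
      }
    }
  })

  if (!is.null(tight_pair_gap) && n >= 2) {
    # slide fascicle 2 along the centroid-centroid line until the boundary
    # gap equals tight_pair_gap (monotone in the slide parameter)
    dir <- centers[1, ] - centers[2, ]
    len <- sqrt(sum(dir^2)); dir <- dir / len
    gap_at <- function(t) poly_min_distance(placed[[1]],
                                            translate_poly(placed[[2]], t * len * dir))
    if (gap_at(0) > tight_pair_gap) {
      t_star <- stats::uniroot(function(t) gap_at(t) - tight_pair_gap,
                               lower = 0, upper = 1, tol = 1e-10)$root
      placed[[2]] <- translate_poly(placed[[2]], t_star * len * dir)
      centers[2, ] <- centers[2, ] + t_star * len * dir
    }
  }

  fascicles <- lapply(seq_len(n), function(i) {
    list(inner = scale_poly(placed[[i]], 1 - spec$perineurium_fraction,
                            poly_centroid(placed[[i]])),
         outer = placed[[i]])
  })
  geom <- cross_section(epi, fascicles, pixel_size = spec$pixel_size)

  # raster masks over the nerve bounding box plus a 2-pixel margin
  px <- spec$pixel_size
  origin <- c(min(epi[, 1]), min(epi[, 2])) - 2 * px
  span <- c(max(epi[, 1]), max(epi[, 2])) - origin + 2 * px
  dim_xy <- ceiling(span / px)
  masks <- list(
    epineurium = rasterize_polygons(list(epi), 1L, origin, dim_xy, px),
    fascicles_outer = rasterize_polygons(lapply(fascicles, `[[`, "outer"),
                                         seq_len(n), origin, dim_xy, px),
    fascicles_inner = rasterize_polygons(lapply(fascicles, `[[`, "inner"),
                                         seq_len(n), origin, dim_xy, px)
  )

  gt <- tibble::tibble(
    fascicle_id = seq_len(n),
    x_um = vapply(fascicles, function(f) poly_centroid(f$outer)[1], numeric(1)),
    y_um = vapply(fascicles, function(f) poly_centroid(f$outer)[2], numeric(1)),
    effective_diameter_um = diams,
    inner_effective_diameter_um = diams * (1 - spec$perineurium_fraction),
    axis_ratio = shape$ratio,
    angle = shape$angle
  )
  list(geometry = geom, masks = masks, ground_truth = gt)
}

#' Generate a 3D fascicle label volume with scheduled splits and merges
#'
#' Fascicle tracks are circles extruded along z (superior to inferior). A
#' scheduled split bifurcates a track into two children that separate
#' linearly over a 10-voxel transition zone; a merge joins two tracks the
#' same way in reverse, so the slice-overlap definition of an event fires
#' exactly once per scheduled event.
#'
#' @param spec A [phantom_spec()]; `event_schedule` entries use `labels` to
#'   name the track(s) involved (`split` takes one label, `merge` two).
#' @param transition_voxels Length of the split/merge transition zone.
#' @return List with `volume` (a [label_volume()]) and `ground_truth`
#'   (`true_events` tibble and per-track layout).
#' @export
gen_label_volume <- function(spec, transition_voxels = 10) {
  vx <- spec$voxel_size
  nz <- max(2L, round(spec$z_extent / vx))
  R <- spec$nerve_diameter / 2
  n <- spec$n_fascicles

  sched <- spec$event_schedule
  if (length(sched) > 1) {
    zi <- vapply(sched, function(e) round(e$z / vx), numeric(1))
    lb <- vapply(sched, function(e) paste(sort(unlist(e$labels)), collapse = ","),
                 character(1))
    for (i in seq_along(sched)) for (j in seq_len(i - 1)) {
      if (zi[i] == zi[j] &&
          length(intersect(unlist(sched[[i]]$labels), unlist(sched[[j]]$labels))) > 0) {
        nm_abort("SCHEDULE_CONFLICT",
                 "two events share the same z slice and label")
      }
    }
  }

  # deterministic ring layout keeps tracks well separated
  radii <- with_stream(spec$seed, "diameters",
                       stats::runif(n, spec$fascicle_diameter_range[1],
                                    spec$fascicle_diameter_range[2]) / 2)
  phase <- with_stream(spec$seed, "placement", stats::runif(1, 0, 2 * pi))
  ring_r <- if (n == 1) 0 else 0.55 * R
  ang <- phase + 2 * pi * (seq_len(n) - 1) / max(n, 1)
  tracks <- lapply(seq_len(n), function(i) {
    list(label = i, center = c(ring_r * cos(ang[i]), ring_r * sin(ang[i])),
         r = radii[i])
  })
  next_label <- n + 1L

  sched_idx <- if (length(sched)) order(vapply(sched, `[[`, numeric(1), "z")) else integer(0)
  sched <- sched[sched_idx]
  events_z <- vapply(sched, function(e) round(e$z / vx), numeric(1))

  # grid
  half <- R + 2 * vx
  nxy <- ceiling(2 * half / vx)
  cx <- (seq_len(nxy) - 1) * vx - half
  Xg <- matrix(cx, nrow = nxy, ncol = nxy, byrow = TRUE)   # [y, x]: x along columns
  Yg <- matrix(cx, nrow = nxy, ncol = nxy, byrow = FALSE)  # y along rows

  labels <- array(0L, dim = c(nz, nxy, nxy))
  ev_log <- list()
  active <- tracks       # list of tracks currently alive
  transitions <- list()  # in-progress transitions

  tangent_dir <- function(center) {
    # direction perpendicular to the radial direction (stays inside nerve)
    if (sqrt(sum(center^2)) < 1e-9) c(1, 0) else {
      v <- c(-center[2], center[1]); v / sqrt(sum(v^2))
    }
  }

  for (iz in seq_len(nz)) {
    z0 <- iz - 1  # 0-based slice index
    # start any events scheduled at this slice
    hit <- which(events_z == z0)
    for (h in hit) {
      ev <- sched[[h]]
      labs <- unlist(ev$labels)
      if (ev$type == "split") {
        k <- which(vapply(active, `[[`, numeric(1), "label") == labs[1])
        if (length(k) != 1) nm_abort("SCHEDULE_CONFLICT", sprintf(
          "split references label %s not alive at z=%g", labs[1], ev$z))
        par <- active[[k]]
        rc <- par$r / sqrt(2)
        dirv <- tangent_dir(par$center)
        child2 <- next_label; next_label <- next_label + 1L
        transitions[[length(transitions) + 1]] <- list(
          type = "split", z_start = z0, parent = par, r_child = rc,
          dir = dirv, off_end = rc + spec$min_gap, labels = c(par$label, child2))
        active[[k]] <- NULL
        ev_log[[length(ev_log) + 1]] <- tibble::tibble(
          z_index = z0, z_um = z0 * vx, type = "split",
          parent_labels = as.character(par$label),
          child_labels = paste(c(par$label, child2), collapse = ","))
      } else {
        ks <- vapply(labs, function(L)
          which(vapply(active, `[[`, numeric(1), "label") == L)[1], numeric(1))
        if (any(is.na(ks))) nm_abort("SCHEDULE_CONFLICT", sprintf(
          "merge references labels %s not alive at z=%g",
          paste(labs, collapse = ","), ev$z))
        ta <- active[[ks[1]]]; tb <- active[[ks[2]]]
        transitions[[length(transitions) + 1]] <- list(
          type = "merge", z_start = z0, a = ta, b = tb,
          mid = (ta$center + tb$center) / 2,
          r_merged = sqrt(ta$r^2 + tb$r^2), labels = labs)
        for (k in sort(ks, decreasing = TRUE)) active[[k]] <- NULL
        ev_log[[length(ev_log) + 1]] <- tibble::tibble(
          z_index = z0, z_um = z0 * vx, type = "merge",
          parent_labels = paste(labs, collapse = ","),
          child_labels = as.character(ta$label))
      }
    }

    # draw active static tracks
    slice <- matrix(0L, nxy, nxy)
    draw_circle <- function(slice, center, r, lab) {
      sel <- (Xg - center[1])^2 + (Yg - center[2])^2 <= r^2
      slice[sel] <- lab
      slice
    }
    for (tr in active) slice <- draw_circle(slice, tr$center, tr$r, tr$label)

    # draw transitions; finish those whose zone has elapsed
    done <- logical(length(transitions))
    for (ti in seq_along(transitions)) {
      trn <- transitions[[ti]]
      f <- min(1, (z0 - trn$z_start) / transition_voxels)
      if (trn$type == "split") {
        off <- f * trn$off_end
        c1 <- trn$parent$center + off * trn$dir
        c2 <- trn$parent$center - off * trn$dir
        slice <- draw_circle(slice, c1, trn$r_child, trn$labels[1])
        slice <- draw_circle(slice, c2, trn$r_child, trn$labels[2])
        if (f >= 1) {
          active[[length(active) + 1]] <- list(label = trn$labels[1], center = c1,
                                               r = trn$r_child)
          active[[length(active) + 1]] <- list(label = trn$labels[2], center = c2,
                                               r = trn$r_child)
          done[ti] <- TRUE
        }
      } else {
        ca <- trn$a$center + f * (trn$mid - trn$a$center)
        cb <- trn$b$center + f * (trn$mid - trn$b$center)
        if (f < 1) {
          slice <- draw_circle(slice, ca, trn$a$r, trn$a$label)
          slice <- draw_circle(slice, cb, trn$b$r, trn$b$label)
        } else {
          slice <- draw_circle(slice, trn$mid, trn$r_merged, trn$a$label)
          active[[length(active) + 1]] <- list(label = trn$a$label,
                                               center = trn$mid, r = trn$r_merged)
          done[ti] <- TRUE
        }
      }
    }
    transitions <- transitions[!done]
    labels[iz, , ] <- slice
  }

  true_events <- if (length(ev_log)) dplyr::bind_rows(ev_log) else
    tibble::tibble(z_index = numeric(0), z_um = numeric(0), type = character(0),
                   parent_labels = character(0), child_labels = character(0))
  list(
    volume = label_volume(labels, vx),
    ground_truth = list(
      true_events = true_events,
      tracks = tibble::tibble(
        label = vapply(tracks, `[[`, numeric(1), "label"),
        x_um = vapply(tracks, function(t) t$center[1], numeric(1)),
        y_um = vapply(tracks, function(t) t$center[2], numeric(1)),
        r_um = vapply(tracks, `[[`, numeric(1), "r"))
    )
  )
}
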