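# Nerve reshaping for cuff-electrode models: shrinkage compensation,
# area-preserving circularization with minimum-gap fascicle repacking, and
# cuff/saline/medium geometry construction.

#' Reshaping settings
#'
#' @param shrinkage Linear (diameter) shrinkage fraction to compensate
#'   (default 0.20: fixation and histological processing).
#' @param min_gap Minimum fascicle-fascicle and fascicle-boundary spacing
#'   after circularization, micrometres (default 10).
#' @param max_relax_iters Cap on constraint-relaxation sweeps.
#' @param relax_slack Extra clearance added when resolving a violated pair,
#'   micrometres.
#' @export
reshape_settings <- function(shrinkage = 0.20, min_gap = 10,
                             max_relax_iters = 200, relax_slack = 0.5) {
  if (shrinkage < 0 || shrinkage >= 1) {
    nm_abort("INVALID_FRACTION", "shrinkage must be in [0, 1)")
  }
  stopifnot_scalar_num(min_gap, "min_gap", 0)
  structure(list(shrinkage = shrinkage, min_gap = min_gap,
                 max_relax_iters = max_relax_iters,
                 relax_slack = relax_slack),
            class = "reshape_settings")
}

#' Inflate a cross section to compensate tissue shrinkage
#'
#' All coordinates scale about the section centroid by `1 / (1 - s)` under
#' the linear (diameter) shrinkage convention, so
#' `(1 - d_before/d_after) x 100` equals the shrinkage percentage.
#'
#' @param section A [cross_section()].
#' @param shrinkage Linear shrinkage fraction in [0, 1).
#' @return The inflated [cross_section()].
#' @export
inflate_for_shrinkage <- function(section, shrinkage = 0.20) {
  if (shrinkage < 0 || shrinkage >= 1) {
    nm_abort("INVALID_FRACTION", "shrinkage must be in [0, 1)")
  }
  f <- 1 / (1 - shrinkage)
  ctr <- poly_centroid(section$epineurium)
  cross_section(
    scale_poly(section$epineurium, f, ctr),
    lapply(section$fascicles, function(fa)
      list(inner = scale_poly(fa$inner, f, ctr),
           outer = scale_poly(fa$outer, f, ctr))),
    pixel_size = section$pixel_size,
    modality_tag = section$modality_tag
  )
}

# Gap diagnostics used by circularize_nerve and by the acceptance checks:
# brute-force pairwise polygon distances plus fascicle-to-boundary gaps.
#' Minimum spacing of a circularized section
#'
#' Brute-force minimum over all fascicle-fascicle boundary distances and
#' each fascicle's distance to the (circular) nerve boundary.
#'
#' @param section A [cross_section()] whose epineurium is a circle.
#' @return List `min_pair_gap`, `min_boundary_gap`, `min_gap`.
#' @export
section_min_gaps <- function(section) {
  ctr <- poly_centroid(section$epineurium)
  # vertex-based circle radius (boundary produced by circularize_nerve)
  R <- mean(sqrt((section$epineurium[, 1] - ctr[1])^2 +
                   (section$epineurium[, 2] - ctr[2])^2))
  outers <- lapply(section$fascicles, `[[`, "outer")
  n <- length(outers)
  pair <- Inf
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      pair <- min(pair, poly_min_distance(outers[[i]], outers[[j]]))
    }
  }
  bound <- if (n) min(vapply(outers, poly_to_circle_gap, numeric(1),
                             center = ctr, radius = R)) else Inf
  list(min_pair_gap = pair, min_boundary_gap = bound,
       min_gap = min(pair, bound))
}

#' Deform a nerve cross section to a circle with fascicle repacking
#'
#' The epineurium becomes a circle of equal area (mimicking chronic cuff
#' reshaping); fascicles keep their shape and area and are only translated:
#' first a boundary-radial projection pulls fascicles that the original
#' elongated outline placed outside the target circle inward, then
#' iterative pairwise constraint relaxation displaces violated pairs
#' symmetrically along their centroid-centroid line (or radially for
#' boundary violations) by half the violation plus a small slack, sweeping
#' deterministically in fascicle order, until all gaps are at least
#' `min_gap`.
#'
#' @param section A [cross_section()].
#' @param settings A [reshape_settings()].
#' @return The circularized [cross_section()].
#' @export
circularize_nerve <- function(section, settings = reshape_settings()) {
  A <- poly_area(section$epineurium)
  R <- sqrt(A / pi)
  ctr <- poly_centroid(section$epineurium)
  gap <- settings$min_gap
  outers <- lapply(section$fascicles, `[[`, "outer")
  inners <- lapply(section$fascicles, `[[`, "inner")
  n <- length(outers)

  # feasibility bound: effective discs (circumradius + half gap) must fit a
  # hexagonal packing of the target disc
  if (n) {
    circum <- vapply(seq_len(n), function(i) {
      c0 <- poly_centroid(outers[[i]])
      max(sqrt((outers[[i]][, 1] - c0[1])^2 + (outers[[i]][, 2] - c0[2])^2))
    }, numeric(1))
    need <- sum(pi * (circum + gap / 2)^2)
    avail <- 0.9069 * pi * max(R - gap / 2, 0)^2
    if (need > avail) {
      nm_abort("PACKING_INFEASIBLE", sprintf(
        "fascicles cannot satisfy a %.1f um gap inside the %.0f um circle",
        gap, 2 * R))
    }
  }

  centers <- lapply(outers, poly_centroid)
  # circumradius of each fascicle about its centroid
  crad <- if (n) vapply(seq_len(n), function(i) {
    max(sqrt((outers[[i]][, 1] - centers[[i]][1])^2 +
               (outers[[i]][, 2] - centers[[i]][2])^2))
  }, numeric(1)) else numeric(0)

  # boundary-radial projection: scale each centroid's radial position so
  # the fascicle fits inside the circle with the required clearance
  shift <- vector("list", n)
  for (i in seq_len(n)) {
    v <- centers[[i]] - ctr
    d <- sqrt(sum(v^2))
    dmax <- R - gap - crad[i]
    new_c <- if (d > dmax && d > 0) ctr + v / d * max(dmax, 0) else centers[[i]]
    shift[[i]] <- new_c - centers[[i]]
  }
  outers <- lapply(seq_len(n), function(i) translate_poly(outers[[i]], shift[[i]]))
  inners <- lapply(seq_len(n), function(i) translate_poly(inners[[i]], shift[[i]]))

  # iterative pairwise relaxation
  slack <- settings$relax_slack
  iter <- 0L
  repeat {
    iter <- iter + 1L
    moved <- FALSE
    for (i in seq_len(n)) {
      ci <- poly_centroid(outers[[i]])
      # fascicle-boundary constraint (radial)
      rmax <- max(sqrt((outers[[i]][, 1] - ctr[1])^2 +
                         (outers[[i]][, 2] - ctr[2])^2))
      viol <- rmax - (R - gap)
      if (viol > 1e-9) {
        v <- ci - ctr; d <- sqrt(sum(v^2))
        dir <- if (d > 1e-9) v / d else c(1, 0)
        mv <- -dir * (viol + slack)
        outers[[i]] <- translate_poly(outers[[i]], mv)
        inners[[i]] <- translate_poly(inners[[i]], mv)
        moved <- TRUE
      }
      if (i < n) for (j in (i + 1):n) {
        # bounding-circle prescreen: pair cannot violate the gap
        dc <- sqrt(sum((poly_centroid(outers[[i]]) - poly_centroid(outers[[j]]))^2))
        if (dc - crad[i] - crad[j] >= gap) next
        dgap <- poly_min_distance(outers[[i]], outers[[j]])
        if (dgap < gap - 1e-9) {
          ci <- poly_centroid(outers[[i]]); cj <- poly_centroid(outers[[j]])
          v <- cj - ci; d <- sqrt(sum(v^2))
          dir <- if (d > 1e-9) v / d else c(1, 0)
          mv <- (gap - dgap + slack) / 2
          outers[[i]] <- translate_poly(outers[[i]], -dir * mv)
          inners[[i]] <- translate_poly(inners[[i]], -dir * mv)
          outers[[j]] <- translate_poly(outers[[j]], dir * mv)
          inners[[j]] <- translate_poly(inners[[j]], dir * mv)
          moved <- TRUE
        }
      }
    }
    if (!moved) break
    if (iter >= settings$max_relax_iters) {
      nm_abort("PACKING_INFEASIBLE", sprintf(
        "constraint relaxation did not settle within %d sweeps", iter))
    }
  }

  boundary <- circle_poly_area_exact(ctr, R, 256)
  cross_section(
    boundary,
    lapply(seq_len(n), function(i) list(inner = inners[[i]], outer = outers[[i]])),
    pixel_size = section$pixel_size,
    modality_tag = section$modality_tag
  )
}

#' Build the cuff-electrode model geometry around a circularized nerve
#'
#' Extrudes the nerve, wraps it in a saline layer and a bipolar cuff, and
#' embeds everything in a cylindrical surrounding medium (muscle). The
#' saline layer thickness is the binding constraint, so the cuff inner
#' diameter always equals the nerve diameter plus twice the saline layer
#' (3 mm for a 2.8 mm nerve); the two ring contacts sit symmetrically about
#' the longitudinal midpoint.
#'
#' @param section A circularized [cross_section()].
#' @param extrusion_mm Nerve/model length (default 50).
#' @param saline_um Saline layer thickness (default 100).
#' @param cuff_wall_um Silicone cuff wall thickness.
#' @param contact_width_mm,contact_spacing_mm Ring contact width and
#'   edge-to-edge spacing.
#' @param contact_thickness_um Radial thickness of the platinum rings.
#' @param cuff_length_mm Longitudinal extent of the cuff.
#' @param medium_diameter_mm,medium_length_mm Surrounding-medium cylinder.
#' @return Object of class `cuff_geometry`.
#' @export
build_cuff_geometry <- function(section, extrusion_mm = 50, saline_um = 100,
                                cuff_wall_um = 600,
                                contact_width_mm = 1, contact_spacing_mm = 1,
                                contact_thickness_um = 50,
                                cuff_length_mm = 10,
                                medium_diameter_mm = 10, medium_length_mm = 50) {
  circ <- poly_circularity(section$epineurium)
  if (circ < 0.99) {
    nm_abort("INVALID_ARGUMENT", "section must be circularized first")
  }
  nerve_d_um <- effective_circular_diameter(section$epineurium)
  cuff_inner_um <- nerve_d_um + 2 * saline_um
  cuff_outer_um <- cuff_inner_um + 2 * cuff_wall_um
  if (cuff_outer_um >= medium_diameter_mm * 1000) {
    nm_abort("NERVE_TOO_LARGE", "cuff exceeds the surrounding medium")
  }
  mid <- extrusion_mm / 2
  half_sep <- contact_spacing_mm / 2 + contact_width_mm / 2
  ctr <- poly_centroid(section$epineurium)
  fascicles <- lapply(section$fascicles, function(f)
    list(inner = translate_poly(f$inner, -ctr),
         outer = translate_poly(f$outer, -ctr)))
  structure(list(
    nerve_diameter_um = nerve_d_um,
    fascicles = fascicles,
    extrusion_mm = extrusion_mm,
    saline_thickness_um = saline_um,
    cuff_inner_diameter_mm = cuff_inner_um / 1000,
    cuff_outer_diameter_mm = cuff_outer_um / 1000,
    cuff_nominal_inner_mm = 3,
    cuff_expanded = cuff_inner_um > 3000,
    cuff_length_mm = cuff_length_mm,
    contact_centers_mm = c(mid - half_sep, mid + half_sep),
    contact_width_mm = contact_width_mm,
    contact_thickness_um = contact_thickness_um,
    medium_diameter_mm = medium_diameter_mm,
    medium_length_mm = medium_length_mm,
    materials = c(endoneurium = "endoneurium", perineurium = "perineurium",
                  epineurium = "epineurium", saline = "saline",
                  contact = "platinum", cuff = "silicone", medium = "muscle")
  ), class = "cuff_geometry")
}

#' @export
print.cuff_geometry <- function(x, ...) {
  cat(sprintf(
    paste0("<cuff_geometry> nerve %.2f mm, cuff inner %.2f mm, saline %g um,\n",
           "  contacts at %.1f / %.1f mm of %g mm, medium %g x %g mm\n"),
    x$nerve_diameter_um / 1000, x$cuff_inner_diameter_mm,
    x$saline_thickness_um, x$contact_centers_mm[1], x$contact_centers_mm[2],
    x$extrusion_mm, x$medium_diameter_mm, x$medium_length_mm))
  invisible(x)
}
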