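# Quasi-static extracellular potentials: anisotropic point-source closed
# form, finite-difference Laplace solver on the voxelized cuff geometry,
# line sampling, and biphasic two-contact superposition.

#' Material conductivity table
#'
#' Established conductivities for the cuff model regions, S/m; anisotropic
#' tissues carry {transverse, transverse, longitudinal} diagonal tensors.
#'
#' @return Tibble with `material`, `sigma_x`, `sigma_y`, `sigma_z`.
#' @export
material_table <- function() {
  tibble::tribble(
    ~material,     ~sigma_x,  ~sigma_y,  ~sigma_z,
    "endoneurium", 0.167,     0.167,     0.571,
    "perineurium", 0.0008703, 0.0008703, 0.0008703,
    "epineurium",  0.159,     0.159,     0.159,
    "saline",      1.76,      1.76,      1.76,
    "platinum",    9.43e6,    9.43e6,    9.43e6,
    "silicone",    1e-12,     1e-12,     1e-12,
    "muscle",      0.086,     0.086,     0.35
  )
}

#' Closed-form potential of a point source in an anisotropic medium
#'
#' `V = I / (4 pi sqrt(sy sz x^2 + sx sz y^2 + sx sy z^2))` for a diagonal
#' conductivity tensor; reduces to `I / (4 pi sigma r)` when isotropic.
#'
#' @param current_mA Source current, mA.
#' @param sigma Scalar (isotropic) or length-3 diagonal conductivity, S/m.
#' @param offset_um n x 3 matrix (or length-3 vector) of offsets from the
#'   source, micrometres.
#' @return Potential(s), volts.
#' @export
analytic_point_source <- function(current_mA, sigma, offset_um) {
  if (is.null(dim(offset_um))) offset_um <- matrix(offset_um, ncol = 3)
  dimnames(offset_um) <- NULL
  if (length(sigma) == 1) sigma <- rep(sigma, 3)
  if (any(sigma <= 0)) nm_abort("INVALID_ARGUMENT", "conductivities must be > 0")
  r_m <- offset_um * 1e-6
  denom2 <- sigma[2] * sigma[3] * r_m[, 1]^2 +
    sigma[1] * sigma[3] * r_m[, 2]^2 +
    sigma[1] * sigma[2] * r_m[, 3]^2
  if (any(denom2 <= 0)) nm_abort("SINGULAR_POINT", "potential undefined at the source")
  (current_mA * 1e-3) / (4 * pi * sqrt(denom2))
}

#' Voxelize a cuff model geometry into a conductivity grid
#'
#' Each voxel takes the material of the region containing its center. The
#' solve domain is a reduced, contact-centered box with grounded (Dirichlet
#' 0) outer boundary. Perineurium thinner than one voxel is handled by a
#' thin-sheet correction: the ring's radial conductivity is scaled by
#' `voxel / thickness` so the sheet resistance is preserved.
#'
#' @param geom A [build_cuff_geometry()] result.
#' @param materials Conductivity table as from [material_table()].
#' @param voxel_um Isotropic voxel size (default 25).
#' @param domain_xy_mm,domain_z_mm Reduced-domain extents; the box is
#'   centered transversely on the nerve axis and longitudinally on the cuff.
#' @param thin_layer_correction Enable the perineurium sheet correction.
#' @return Object of class `conductivity_grid`.
#' @export
voxelize_geometry <- function(geom, materials = material_table(),
                              voxel_um = 25, domain_xy_mm = 6,
                              domain_z_mm = 10,
                              thin_layer_correction = TRUE) {
  stopifnot(inherits(geom, "cuff_geometry"))
  if (voxel_um > 50 && !thin_layer_correction) {
    nm_abort("RESOLUTION_TOO_COARSE",
             "voxel must be <= 50 um unless the thin-layer correction is enabled")
  }
  domain_xy_mm <- min(domain_xy_mm, geom$medium_diameter_mm)
  domain_z_mm <- min(domain_z_mm, geom$medium_length_mm)
  h <- voxel_um
  nxy <- max(8L, floor(domain_xy_mm * 1000 / h))
  nz <- max(8L, floor(domain_z_mm * 1000 / h))
  zmid <- geom$extrusion_mm * 1000 / 2
  # voxel-center coordinates (um); x/y centered on the nerve axis
  xc <- (seq_len(nxy) - (nxy + 1) / 2) * h
  zc <- zmid + (seq_len(nz) - (nz + 1) / 2) * h
  origin <- c(xc[1], xc[1], zc[1])

  r_nerve <- geom$nerve_diameter_um / 2
  r_saline <- r_nerve + geom$saline_thickness_um
  r_cuff <- geom$cuff_outer_diameter_mm * 1000 / 2
  r_contact <- r_saline + geom$contact_thickness_um
  cuff_z <- zmid + c(-1, 1) * geom$cuff_length_mm * 1000 / 2
  contact_z <- lapply(geom$contact_centers_mm, function(c0)
    c0 * 1000 + c(-1, 1) * geom$contact_width_mm * 1000 / 2)

  # region table: shared regions first, then per-fascicle endo/perineurium
  regions <- tibble::tibble(
    id = 1:4,
    name = c("epineurium", "saline", "silicone", "muscle"),
    material = c("epineurium", "saline", "silicone", "muscle")
  )
  nf <- length(geom$fascicles)
  if (nf) {
    regions <- dplyr::bind_rows(
      regions,
      tibble::tibble(id = 4 + seq_len(nf), name = paste0("endoneurium_f", seq_len(nf)),
                     material = "endoneurium"),
      tibble::tibble(id = 4 + nf + seq_len(nf),
                     name = paste0("perineurium_f", seq_len(nf)),
                     material = "perineurium")
    )
  }
  regions <- dplyr::bind_rows(
    regions,
    tibble::tibble(id = 5 + 2 * nf, name = "platinum", material = "platinum")
  )
  regions <- dplyr::left_join(regions, materials, by = "material")

  # 2D cross-section region map (inside-cuff band and outside-cuff band)
  X <- matrix(xc, nxy, nxy, byrow = TRUE)
  Y <- matrix(xc, nxy, nxy, byrow = FALSE)
  rr <- sqrt(X^2 + Y^2)
  in_cuff_2d <- matrix(4L, nxy, nxy)          # z within cuff extent; muscle
  in_cuff_2d[rr <= r_cuff] <- 3L              # silicone
  in_cuff_2d[rr <= r_saline] <- 2L            # saline
  in_cuff_2d[rr <= r_nerve] <- 1L             # epineurium
  out_cuff_2d <- matrix(4L, nxy, nxy)         # muscle
  out_cuff_2d[rr <= r_nerve] <- 1L
  contact_band_2d <- rr > r_saline & rr <= r_contact & rr <= r_cuff

  pts <- cbind(as.vector(X), as.vector(Y))
  for (i in seq_len(nf)) {
    f <- geom$fascicles[[i]]
    io <- points_in_polygon(pts, f$outer)
    ii <- points_in_polygon(pts, f$inner)
    ring <- io & !ii
    if (!any(ring)) ring <- io  # sub-voxel ring: carry the sheet on the disc edge
    peri_id <- as.integer(4 + nf + i)
    endo_id <- as.integer(4 + i)
    sel_ring <- matrix(ring, nxy, nxy)
    sel_in <- matrix(io & ii, nxy, nxy)
    in_cuff_2d[sel_ring] <- peri_id
    out_cuff_2d[sel_ring] <- peri_id
    in_cuff_2d[sel_in] <- endo_id
    out_cuff_2d[sel_in] <- endo_id
  }

  region <- array(0L, dim = c(nz, nxy, nxy))
  plat_id <- as.integer(5 + 2 * nf)
  for (iz in seq_len(nz)) {
    z <- zc[iz]
    if (z >= cuff_z[1] && z <= cuff_z[2]) {
      sl <- in_cuff_2d
      in_contact <- any(vapply(contact_z, function(w) z >= w[1] && z <= w[2],
                               logical(1)))
      if (in_contact) sl[contact_band_2d] <- plat_id
      region[iz, , ] <- sl
    } else {
      region[iz, , ] <- out_cuff_2d
    }
  }

  # thin-sheet correction per fascicle
  if (thin_layer_correction && nf) {
    for (i in seq_len(nf)) {
      t_um <- perineurium_thickness(geom$fascicles[[i]]$inner,
                                    geom$fascicles[[i]]$outer)
      if (t_um < voxel_um && t_um > 0) {
        k <- which(regions$name == paste0("perineurium_f", i))
        regions$sigma_x[k] <- regions$sigma_x[k] * voxel_um / t_um
        regions$sigma_y[k] <- regions$sigma_y[k] * voxel_um / t_um
      }
    }
  }

  structure(list(region = region, regions = regions, voxel_um = voxel_um,
                 origin_um = origin,
                 contact_z_um = lapply(contact_z, mean),
                 contact_r_um = (r_saline + r_contact) / 2,
                 geom = geom),
            class = "conductivity_grid")
}

#' @export
print.conductivity_grid <- function(x, ...) {
  d <- dim(x$region)
  cat(sprintf("<conductivity_grid> %d x %d x %d voxels at %g um, %d region(s)\n",
              d[1], d[2], d[3], x$voxel_um, nrow(x$regions)))
  invisible(x)
}

#' Build a uniform conductivity grid (solver benchmark)
#'
#' @param n Voxels per edge.
#' @param voxel_um Voxel size, micrometres.
#' @param sigma Conductivity, S/m (scalar or length-3).
#' @export
homogeneous_grid <- function(n, voxel_um, sigma = 1) {
  if (length(sigma) == 1) sigma <- rep(sigma, 3)
  regions <- tibble::tibble(id = 1L, name = "medium", material = "uniform",
                            sigma_x = sigma[1], sigma_y = sigma[2],
                            sigma_z = sigma[3])
  structure(list(region = array(1L, dim = c(n, n, n)), regions = regions,
                 voxel_um = voxel_um, origin_um = c(0, 0, 0) + voxel_um / 2,
                 contact_z_um = list(), contact_r_um = NA_real_, geom = NULL),
            class = "conductivity_grid")
}

shift_z <- function(a, k) {
  # returns array shifted so that result[i] = a[i+k] (zero padded)
  d <- dim(a); out <- array(0, d)
  if (k == 1) out[1:(d[1] - 1), , ] <- a[2:d[1], , ]
  else out[2:d[1], , ] <- a[1:(d[1] - 1), , ]
  out
}
shift_y <- function(a, k) {
  d <- dim(a); out <- array(0, d)
  if (k == 1) out[, 1:(d[2] - 1), ] <- a[, 2:d[2], ]
  else out[, 2:d[2], ] <- a[, 1:(d[2] - 1), ]
  out
}
shift_x <- function(a, k) {
  d <- dim(a); out <- array(0, d)
  if (k == 1) out[, , 1:(d[3] - 1)] <- a[, , 2:d[3]]
  else out[, , 2:d[3]] <- a[, , 1:(d[3] - 1)]
  out
}

#' Finite-difference Laplace solve for a point current source
#'
#' 7-point stencil with harmonic averaging of face conductivities, grounded
#' (V = 0) outer boundary, Jacobi-preconditioned conjugate gradients to a
#' relative residual of `tol`. Near-insulators (below `sigma_floor`) are
#' excluded from the domain; very high conductivities are capped at
#' `sigma_cap` to keep the system well conditioned (both configurable).
#'
#' @param grid A [voxelize_geometry()] / [homogeneous_grid()] result.
#' @param source Voxel index `c(z, y, x)` (1-based) of the current source,
#'   or a matrix of such rows (current split equally).
#' @param current_mA Injected current (default 1 mA).
#' @param tol Relative residual tolerance.
#' @param max_iter Conjugate-gradient iteration cap.
#' @param sigma_floor,sigma_cap Conductivity clamp, S/m.
#' @param boundary_values Optional array (grid-shaped) of fixed potentials
#'   on the outer boundary, volts; default 0 everywhere (grounded). Used
#'   e.g. to emulate an open medium when validating against the closed
#'   form.
#' @return Object of class `potential_field` with `v` (volts, dimension of
#'   the grid), iteration diagnostics, and grid metadata.
#' @export
solve_laplace_fd <- function(grid, source, current_mA = 1, tol = 1e-8,
                             max_iter = 20000, sigma_floor = 1e-8,
                             sigma_cap = 1e3, boundary_values = NULL) {
  d <- dim(grid$region)
  lut <- grid$regions
  clamp <- function(s) ifelse(s < sigma_floor, 0, pmin(s, sigma_cap))
  sig_of <- function(col) {
    v <- clamp(lut[[col]])[match(as.vector(grid$region), lut$id)]
    array(v, d)
  }
  Sx <- sig_of("sigma_x"); Sy <- sig_of("sigma_y"); Sz <- sig_of("sigma_z")
  h <- grid$voxel_um * 1e-6
  harm <- function(a, b) ifelse(a + b > 0, 2 * a * b / (a + b), 0)
  # face conductances (S): g = harmonic(sigma) * h
  gzp <- harm(Sz, shift_z(Sz, 1)) * h
  gyp <- harm(Sy, shift_y(Sy, 1)) * h
  gxp <- harm(Sx, shift_x(Sx, 1)) * h
  gzm <- shift_z(gzp, -1); gym <- shift_y(gyp, -1); gxm <- shift_x(gxp, -1)

  # Dirichlet boundary + excluded voxels
  interior <- array(TRUE, d)
  interior[c(1, d[1]), , ] <- FALSE
  interior[, c(1, d[2]), ] <- FALSE
  interior[, , c(1, d[3])] <- FALSE
  interior[Sx + Sy + Sz == 0] <- FALSE

  diagA <- gzp + gzm + gyp + gym + gxp + gxm
  solvable <- interior & diagA > 0

  b <- array(0, d)
  src <- if (is.null(dim(source))) matrix(source, ncol = 3) else source
  for (k in seq_len(nrow(src))) {
    if (!solvable[src[k, 1], src[k, 2], src[k, 3]]) {
      nm_abort("INVALID_ARGUMENT", "source voxel outside the solvable domain")
    }
    b[src[k, 1], src[k, 2], src[k, 3]] <-
      b[src[k, 1], src[k, 2], src[k, 3]] + current_mA * 1e-3 / nrow(src)
  }

  amul <- function(v) {
    out <- diagA * v -
      gzp * shift_z(v, 1) - gzm * shift_z(v, -1) -
      gyp * shift_y(v, 1) - gym * shift_y(v, -1) -
      gxp * shift_x(v, 1) - gxm * shift_x(v, -1)
    out[!solvable] <- 0
    out
  }

  vfix <- array(0, d)
  if (!is.null(boundary_values)) {
    vfix[!interior] <- boundary_values[!interior]
  }

  minv <- array(0, d)
  minv[solvable] <- 1 / diagA[solvable]
  if (!is.null(boundary_values)) {
    # move the known boundary potentials to the right-hand side
    contrib <- gzp * shift_z(vfix, 1) + gzm * shift_z(vfix, -1) +
      gyp * shift_y(vfix, 1) + gym * shift_y(vfix, -1) +
      gxp * shift_x(vfix, 1) + gxm * shift_x(vfix, -1)
    b <- b + contrib
  }
  b[!solvable] <- 0

  v <- array(0, d)
  r <- b
  z <- minv * r
  p <- z
  rz <- sum(r * z)
  b_norm <- sqrt(sum(b^2))
  iters <- 0L
  repeat {
    iters <- iters + 1L
    Ap <- amul(p)
    alpha <- rz / sum(p * Ap)
    v <- v + alpha * p
    r <- r - alpha * Ap
    res <- sqrt(sum(r^2)) / b_norm
    if (res <= tol) break
    if (iters >= max_iter) {
      nm_abort("SOLVER_DIVERGENCE", sprintf(
        "conjugate gradients did not reach %.1e within %d iterations (residual %.2e)",
        tol, max_iter, res))
    }
    z <- minv * r
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p
  }
  v <- v + vfix

  structure(list(v = v, iterations = iters, residual = res,
                 voxel_um = grid$voxel_um, origin_um = grid$origin_um,
                 grounded = is.null(boundary_values), source = src,
                 current_mA = current_mA),
            class = "potential_field")
}

#' @export
print.potential_field <- function(x, ...) {
  cat(sprintf("<potential_field> %s voxels, CG %d iters (residual %.1e)\n",
              paste(dim(x$v), collapse = " x "), x$iterations, x$residual))
  invisible(x)
}

# Trilinear interpolation inside a potential field. pts in physical um
# (x, y, z model coordinates).
trilinear_sample_field <- function(field, pts) {
  h <- field$voxel_um; o <- field$origin_um
  d <- dim(field$v)
  fx <- (pts[, 1] - o[1]) / h + 1
  fy <- (pts[, 2] - o[2]) / h + 1
  fz <- (pts[, 3] - o[3]) / h + 1
  if (any(fx < 1 | fx > d[3] | fy < 1 | fy > d[2] | fz < 1 | fz > d[1])) {
    nm_abort("OUT_OF_DOMAIN", "sample point outside the potential grid")
  }
  x0 <- pmin(floor(fx), d[3] - 1); y0 <- pmin(floor(fy), d[2] - 1)
  z0 <- pmin(floor(fz), d[1] - 1)
  wx <- fx - x0; wy <- fy - y0; wz <- fz - z0
  g <- function(dz, dy, dx) field$v[cbind(z0 + dz, y0 + dy, x0 + dx)]
  (1 - wz) * ((1 - wy) * ((1 - wx) * g(0, 0, 0) + wx * g(0, 0, 1)) +
                wy * ((1 - wx) * g(0, 1, 0) + wx * g(0, 1, 1))) +
    wz * ((1 - wy) * ((1 - wx) * g(1, 0, 0) + wx * g(1, 0, 1)) +
            wy * ((1 - wx) * g(1, 1, 0) + wx * g(1, 1, 1)))
}

#' Sample a potential field along a polyline
#'
#' Trilinear interpolation at fixed arc-length spacing (default 1 um, the
#' fascicle-centroid sampling used for threshold computation); the sample
#' count is `floor(L / step) + 1`.
#'
#' @param field A [solve_laplace_fd()] result.
#' @param polyline n x 3 matrix of points (um).
#' @param step_um Arc-length step.
#' @return Tibble `arc_um`, `v_volts`.
#' @export
sample_potentials_along_line <- function(field, polyline, step_um = 1) {
  polyline <- as.matrix(polyline)
  seg <- sqrt(rowSums(diff(polyline)^2))
  arc <- c(0, cumsum(seg))
  L <- max(arc)
  s <- seq(0, floor(L / step_um) * step_um, by = step_um)
  pts <- cbind(stats::approx(arc, polyline[, 1], s)$y,
               stats::approx(arc, polyline[, 2], s)$y,
               stats::approx(arc, polyline[, 3], s)$y)
  tibble::tibble(arc_um = s, v_volts = trilinear_sample_field(field, pts))
}

#' Symmetric biphasic stimulus description
#'
#' @param amplitude_mA Phase amplitude, mA.
#' @param phase_us Phase width (default 250 us).
#' @param start_ms Stimulus onset (default 1 ms).
#' @param polarity First-phase sign per contact (default `c(1, -1)`:
#'   contacts driven in anti-phase).
#' @export
stimulus <- function(amplitude_mA = 1, phase_us = 250, start_ms = 1,
                     polarity = c(1, -1)) {
  structure(list(amplitude_mA = amplitude_mA, phase_us = phase_us,
                 start_ms = start_ms, polarity = polarity),
            class = "stimulus")
}

#' Biphasic weight of a stimulus at given times
#'
#' +1 during the first phase, -1 during the second, 0 elsewhere; the
#' time-integral over a pulse is zero (charge balance).
#'
#' @param stim A [stimulus()].
#' @param t_ms Times, ms.
#' @export
stimulus_weight <- function(stim, t_ms) {
  pw <- stim$phase_us / 1000
  ifelse(t_ms >= stim$start_ms & t_ms < stim$start_ms + pw, 1,
         ifelse(t_ms >= stim$start_ms + pw & t_ms < stim$start_ms + 2 * pw,
                -1, 0))
}

#' Superpose per-contact unit potentials under a biphasic bipolar stimulus
#'
#' With per-contact unit (1 mA) potential samples `v1`, `v2` along a fiber
#' path, the extracellular potential is
#' `Ve(x, t) = A w(t) (p1 v1(x) + p2 v2(x))` with `w` the biphasic weight
#' and `p` the contact polarities (anti-phase by default, i.e. V1 - V2).
#'
#' @param v1,v2 Aligned numeric vectors, volts per mA.
#' @param stim A [stimulus()].
#' @return Object of class `stim_field`: `shape_volts` (per mA of drive)
#'   and `ve_at(t_ms)` returning volts at each position.
#' @export
superpose_contacts <- function(v1, v2, stim = stimulus()) {
  if (length(v1) != length(v2)) {
    nm_abort("LENGTH_MISMATCH", "contact sample arrays differ in length")
  }
  shape <- stim$polarity[1] * v1 + stim$polarity[2] * v2
  structure(list(
    shape_volts = shape, stim = stim,
    ve_at = function(t_ms) {
      outer(shape, stimulus_weight(stim, t_ms)) * stim$amplitude_mA
    }
  ), class = "stim_field")
}
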