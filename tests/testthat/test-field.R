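test_that("analytic point source: closed form, symmetry, anisotropy", {
  # 1 mA, 1 S/m, 1 mm -> 1/(4 pi) V
  expect_equal(analytic_point_source(1, 1, c(1000, 0, 0)), 1 / (4 * pi),
               tolerance = 1e-12)
  # symmetry V(r) = V(-r)
  r <- c(300, -200, 800)
  expect_equal(analytic_point_source(1, 2, rbind(r)),
               analytic_point_source(1, 2, rbind(-r)))
  # anisotropic value equals the coordinate-scaled isotropic oracle:
  # V(sigma, r) = V_iso(1, r / sqrt(sigma)) / sqrt(prod(sigma))
  sig <- c(0.167, 0.167, 0.571)
  pts <- rbind(c(500, 200, -100), c(-50, 900, 300))
  oracle <- analytic_point_source(1, 1, sweep(pts, 2, sqrt(sig), "/")) /
    sqrt(prod(sig))
  expect_equal(analytic_point_source(1, sig, pts), oracle, tolerance = 1e-12)
  expect_error(analytic_point_source(1, 1, c(0, 0, 0)), class = "SINGULAR_POINT")
})

# shared small cuff grid fixture
cuff_grid <- function() fixture("cuff_grid", {
  sec <- cross_section(
    circle_poly_area_exact(c(0, 0), 1000),
    list(list(inner = circle_poly_area_exact(c(300, 0), 180),
              outer = circle_poly_area_exact(c(300, 0), 200)),
         list(inner = circle_poly_area_exact(c(-350, 100), 140),
              outer = circle_poly_area_exact(c(-350, 100), 155))))
  geom <- build_cuff_geometry(sec)
  list(geom = geom,
       grid = voxelize_geometry(geom, voxel_um = 100, domain_xy_mm = 4,
                                domain_z_mm = 8))
})

test_that("voxelization assigns regions consistently with the geometry", {
  cg <- cuff_grid()
  grid <- cg$grid; geom <- cg$geom
  h <- grid$voxel_um
  vol <- function(name) sum(grid$region == grid$regions$id[
    grid$regions$name == name]) * h^3

  d <- dim(grid$region)
  Lz_um <- d[1] * h
  # nerve cylinder volume (epineurium + fascicle interiors) within 2%
  r_nerve <- geom$nerve_diameter_um / 2
  v_nerve <- sum(vapply(c("epineurium", paste0("endoneurium_f", 1:2),
                          paste0("perineurium_f", 1:2)), vol, numeric(1)))
  expect_equal(v_nerve, pi * r_nerve^2 * Lz_um, tolerance = 0.02)
  # saline annulus volume (cuff z-extent clipped to the reduced domain)
  r_sal <- r_nerve + geom$saline_thickness_um
  sal_len_um <- min(geom$cuff_length_mm * 1000, Lz_um)
  v_sal_true <- pi * (r_sal^2 - r_nerve^2) * sal_len_um
  expect_equal(vol("saline"), v_sal_true, tolerance = 0.05)

  # endoneurium voxels lie inside fascicle inner polygons (point-in-polygon
  # oracle on voxel centers)
  for (i in 1:2) {
    id <- grid$regions$id[grid$regions$name == paste0("endoneurium_f", i)]
    w <- which(grid$region == id, arr.ind = TRUE)
    ctrs <- cbind(grid$origin_um[1] + (w[, 3] - 1) * h,
                  grid$origin_um[2] + (w[, 2] - 1) * h)
    expect_true(all(points_in_polygon(ctrs, geom$fascicles[[i]]$inner)))
  }

  # platinum only within the contact radial band; silicone beyond it
  plat <- which(grid$region == grid$regions$id[grid$regions$name == "platinum"],
                arr.ind = TRUE)
  expect_gt(nrow(plat), 0)
  rr <- sqrt((grid$origin_um[1] + (plat[, 3] - 1) * h)^2 +
               (grid$origin_um[2] + (plat[, 2] - 1) * h)^2)
  expect_true(all(rr > r_nerve))
  expect_true(all(rr <= geom$cuff_outer_diameter_mm * 1000 / 2 + h))

  # thin-sheet correction raised the radial perineurium conductivity
  k <- grid$regions$name == "perineurium_f1"
  expect_gt(grid$regions$sigma_x[k], 0.0008703)
  expect_equal(grid$regions$sigma_z[k], 0.0008703)

  expect_error(voxelize_geometry(geom, voxel_um = 80,
                                 thin_layer_correction = FALSE),
               class = "RESOLUTION_TOO_COARSE")
})

test_that("FD Laplace solve matches the closed form in a homogeneous medium", {
  n <- 41; h <- 50; sig <- 0.5
  g <- homogeneous_grid(n, h, sigma = sig)
  src <- c(21, 21, 21)
  idx <- which(array(TRUE, c(n, n, n)), arr.ind = TRUE)
  off <- cbind((idx[, 3] - src[3]) * h, (idx[, 2] - src[2]) * h,
               (idx[, 1] - src[1]) * h)
  r <- sqrt(rowSums(off^2))
  bnd <- idx[, 1] %in% c(1, n) | idx[, 2] %in% c(1, n) | idx[, 3] %in% c(1, n)
  vb <- array(0, c(n, n, n))
  vb[idx[bnd, ]] <- analytic_point_source(1, sig, off[bnd, ])
  f <- solve_laplace_fd(g, src, boundary_values = vb)
  sel <- r >= 5 * h & r <= (n - 1) / 2 * h
  va <- analytic_point_source(1, sig, off[sel, ])
  expect_lt(max(abs(f$v[idx[sel, ]] - va) / va), 0.05)

  # grounded solve: boundary exactly zero
  f0 <- solve_laplace_fd(g, src)
  expect_identical(max(abs(f0$v[idx[bnd, ]])), 0)

  # discrete flux through a closed surface equals the injected current
  flux_through_cube <- function(V, k) {
    hm <- h * 1e-6
    tot <- 0
    inside <- array(FALSE, c(n, n, n))
    inside[(src[1] - k):(src[1] + k), (src[2] - k):(src[2] + k),
           (src[3] - k):(src[3] + k)] <- TRUE
    ii <- which(inside, arr.ind = TRUE)
    for (s3 in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                    c(0, 0, 1), c(0, 0, -1))) {
      nb <- sweep(ii, 2, s3, "+")
      w <- which(!inside[nb])
      tot <- tot + sum(sig * hm * (V[ii[w, , drop = FALSE]] -
                                     V[nb[w, , drop = FALSE]]))
    }
    tot
  }
  for (k in c(5, 10)) {
    expect_equal(flux_through_cube(f0$v, k), 1e-3, tolerance = 0.01)
  }

  # linearity: scaling I scales V identically
  f2 <- solve_laplace_fd(g, src, current_mA = 2)
  expect_lt(max(abs(f2$v - 2 * f0$v)), 1e-12 + 2 * max(abs(f0$v)) * 1e-10)
})

test_that("solver error decreases when the voxel size halves", {
  sig <- 1
  err_at <- function(n, h) {
    g <- homogeneous_grid(n, h, sigma = sig)
    src <- rep((n + 1) / 2, 3)
    idx <- which(array(TRUE, c(n, n, n)), arr.ind = TRUE)
    off <- cbind((idx[, 3] - src[3]) * h, (idx[, 2] - src[2]) * h,
                 (idx[, 1] - src[1]) * h)
    r <- sqrt(rowSums(off^2))
    bnd <- idx[, 1] %in% c(1, n) | idx[, 2] %in% c(1, n) | idx[, 3] %in% c(1, n)
    vb <- array(0, c(n, n, n))
    vb[idx[bnd, ]] <- analytic_point_source(1, sig, off[bnd, ])
    f <- solve_laplace_fd(g, src, boundary_values = vb)
    sel <- r >= 400 & r <= 900   # same physical band for both grids
    mean(abs(f$v[idx[sel, ]] -
               analytic_point_source(1, sig, off[sel, ])) /
           analytic_point_source(1, sig, off[sel, ]))
  }
  e_coarse <- err_at(21, 100)
  e_fine <- err_at(41, 50)
  expect_gt(e_coarse / e_fine, 1.8)   # observed order >= ~1
})

test_that("line sampling: counts and trilinear exactness on linear fields", {
  n <- 21; h <- 100
  g <- homogeneous_grid(n, h)
  # build a potential field object directly with V = alpha z + c
  alpha <- 2e-4; c0 <- 0.05
  zc <- (seq_len(n) - 1) * h + h / 2
  V <- array(rep(alpha * zc + c0, times = n * n), dim = c(n, n, n))
  f <- structure(list(v = V, iterations = 0, residual = 0, voxel_um = h,
                      origin_um = c(h / 2, h / 2, h / 2), grounded = FALSE,
                      source = NULL, current_mA = 1),
                 class = "potential_field")
  line <- rbind(c(500, 500, 100), c(500, 500, 1900))
  s <- sample_potentials_along_line(f, line, step_um = 1)
  expect_equal(nrow(s), floor(1800 / 1) + 1)
  expect_lt(max(abs(s$v_volts - (alpha * (100 + s$arc_um) + c0))), 1e-9)

  # uniform field: all samples equal
  fU <- f; fU$v <- array(0.123, dim = c(n, n, n))
  sU <- sample_potentials_along_line(fU, line, step_um = 10)
  expect_true(all(sU$v_volts == 0.123))

  # compartment interpolation agrees with direct sampling on linear fields
  fib <- build_mrg_fiber(6, path_length_mm = 1, center_um = 1000)
  ve <- compartment_potentials(s, fib, arc_offset_um = 200, extend = TRUE)
  z <- fib$compartments$z_um - min(fib$compartments$z_um) + 200
  direct <- (alpha * (100 + z) + c0) * 1000
  inside <- z <= max(s$arc_um)
  expect_lt(max(abs(ve[inside] - direct[inside])), 1e-3)  # 1 uV in mV

  expect_error(sample_potentials_along_line(f, rbind(c(0, 0, -500),
                                                     c(0, 0, 500))),
               class = "OUT_OF_DOMAIN")
})

test_that("biphasic superposition: phases, charge balance, anti-phase drive", {
  stim <- stimulus(amplitude_mA = 2, phase_us = 250, start_ms = 1)
  v1 <- c(0.1, 0.2, 0.3); v2 <- c(0.05, 0.1, 0.15)
  sf <- superpose_contacts(v1, v2, stim)
  # before onset
  expect_true(all(sf$ve_at(0.5) == 0))
  # first phase: A (V1 - V2)
  expect_equal(as.vector(sf$ve_at(1.1)), 2 * (v1 - v2))
  # second phase: sign flips
  expect_equal(as.vector(sf$ve_at(1.3)), -2 * (v1 - v2))
  # after the pulse
  expect_true(all(sf$ve_at(2) == 0))
  # charge balance: integral of the weight over the pulse is zero
  tt <- seq(0, 3, by = 1e-4)
  expect_equal(sum(stimulus_weight(stim, tt)) * 1e-4, 0, tolerance = 1e-6)
  expect_error(superpose_contacts(v1, v2[1:2]), class = "LENGTH_MISMATCH")
})
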