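# Shared, lazily computed fixtures (built once per test run).

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

small_spec <- function(seed = 3, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_fascicles = 3, nerve_diameter = 600,
         fascicle_diameter_range = c(100, 180), pixel_size = 8),
    list(...))
  do.call(phantom_spec, args)
}

# mid-size phantom for mask registration (content ~1.5 mm across)
reg_spec <- function() phantom_spec(seed = 5, n_fascicles = 5,
                                    nerve_diameter = 1500, pixel_size = 8)

# 12-fascicle section (packing + morphometry recovery)
section12 <- function() fixture("section12", {
  gen_cross_section(phantom_spec(seed = 7, n_fascicles = 12,
                                 nerve_diameter = 2000, pixel_size = 8))
})

# registration phantom pair with known similarity scale and smooth warp
reg_pair <- function() fixture("reg_pair", {
  gen_modality_pair(reg_spec(), scale = 0.915, warp_amplitude = 20)
})

reg_std <- function() fixture("reg_std", {
  p <- reg_pair()
  preprocess_mask_pair(p$fixed, p$moving)
})

reg_rigid <- function() fixture("reg_rigid", {
  s <- reg_std()
  register_masks_rigid(s$fixed, s$moving, "similarity")
})

reg_bspline <- function() fixture("reg_bspline", {
  s <- reg_std()
  register_masks_bspline(s$fixed, s$moving, reg_rigid())
})

# analytic cathodic point-source field 1 mm from a fiber, per-compartment mV
analytic_ve <- function(fiber, sigma = 0.3, dist_um = 1000, center_um = 10000) {
  z <- fiber$compartments$z_um
  analytic_point_source(-1, sigma, cbind(z - center_um, dist_um, 0)) * 1000
}

# straight-tube label volume (single circular fascicle along z)
straight_tube <- function(nz = 60, nxy = 41, r_vox = 8, voxel = 11.4) {
  L <- array(0L, dim = c(nz, nxy, nxy))
  ctr <- (nxy + 1) / 2
  xs <- matrix(seq_len(nxy), nxy, nxy, byrow = TRUE)
  ys <- matrix(seq_len(nxy), nxy, nxy, byrow = FALSE)
  disc <- (xs - ctr)^2 + (ys - ctr)^2 <= r_vox^2
  for (iz in seq_len(nz)) { sl <- matrix(0L, nxy, nxy); sl[disc] <- 1L; L[iz, , ] <- sl }
  label_volume(L, voxel)
}
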