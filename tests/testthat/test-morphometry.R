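test_that("effective circular diameter: closed forms and pixel oracle", {
  # circle of radius 50 -> 100 (area-exact circle polygon)
  circ <- circle_poly_area_exact(c(10, -5), 50)
  expect_equal(effective_circular_diameter(circ), 100, tolerance = 1e-9)
  # 100 x 100 square -> 2 sqrt(1e4 / pi) = 112.8379
  sq <- cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))
  expect_equal(effective_circular_diameter(sq), 2 * sqrt(1e4 / pi),
               tolerance = 1e-12)
  expect_equal(effective_circular_diameter(sq), 112.8379, tolerance = 1e-4)
  # arbitrary blob mask equals the brute-force pixel-count oracle
  set.seed(42)
  blob <- matrix(0, 40, 40)
  blob[10:30, 8:25] <- 1
  blob[cbind(sample(40, 60, TRUE), sample(40, 60, TRUE))] <- 1
  ps <- 2.5
  oracle <- 2 * sqrt(sum(blob > 0) * ps^2 / pi)
  expect_equal(effective_circular_diameter(mask2d(blob, ps)), oracle,
               tolerance = 1e-9)
  # invariance to rotation/translation, monotone in area
  rot <- function(p, th) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    t(R %*% t(p)) + 7
  }
  expect_equal(effective_circular_diameter(rot(sq, 0.7)),
               effective_circular_diameter(sq), tolerance = 1e-9)
  expect_gt(effective_circular_diameter(scale_poly(sq, 1.1, c(0, 0))),
            effective_circular_diameter(sq))
  expect_error(effective_circular_diameter(mask2d(matrix(0, 4, 4), 1)),
               class = "EMPTY_REGION")
})

test_that("perineurium thickness from effective diameters", {
  inner <- circle_poly_area_exact(c(0, 0), 45)
  outer <- circle_poly_area_exact(c(0, 0), 50)
  expect_equal(perineurium_thickness(inner, outer), 5, tolerance = 1e-9)
  expect_equal(perineurium_thickness(inner, inner), 0, tolerance = 1e-12)
  # concentric ellipses: equals the polygon-area oracle
  ei <- ellipse_poly(c(0, 0), 60, 30, 0.4, 256)
  eo <- ellipse_poly(c(0, 0), 75, 40, 0.4, 256)
  oracle <- (2 * sqrt(poly_area(eo) / pi) - 2 * sqrt(poly_area(ei) / pi)) / 2
  expect_equal(perineurium_thickness(ei, eo), oracle, tolerance = 1e-12)
  expect_error(perineurium_thickness(eo, ei), class = "GEOMETRY_ORDER")
})

test_that("measure_cross_section recovers phantom ground truth", {
  # simple constructed case: one circular fascicle d=400 in a d=1000 nerve
  sec <- cross_section(
    circle_poly_area_exact(c(0, 0), 500),
    list(list(inner = circle_poly_area_exact(c(0, 0), 200),
              outer = circle_poly_area_exact(c(0, 0), 210))))
  m <- measure_cross_section(sec)
  expect_equal(m$fascicle_count, 1)
  expect_equal(m$nerve_effective_diameter_um, 1000, tolerance = 1e-9)
  expect_equal(m$fascicles$effective_diameter_um, 400, tolerance = 1e-9)
  expect_equal(m$fascicles$perineurium_thickness_um, 10, tolerance = 1e-9)

  # phantom: count and diameters match generator ground truth
  cs <- section12()
  m12 <- measure_cross_section(cs$geometry)
  expect_equal(m12$fascicle_count, 12)
  expect_equal(m12$fascicles$effective_diameter_um,
               cs$ground_truth$inner_effective_diameter_um,
               tolerance = 2 * 8 / 200)  # within 2 pixels on ~200 um fascicles

  # empty fascicle list
  m0 <- measure_cross_section(cross_section(circle_poly_area_exact(c(0, 0), 500)))
  expect_equal(m0$fascicle_count, 0)
  expect_equal(nrow(m0$fascicles), 0)
  expect_equal(m0$nerve_effective_diameter_um, 1000, tolerance = 1e-9)

  # tidy/glance surfaces
  expect_s3_class(tidy(m12), "tbl_df")
  expect_equal(nrow(tidy(m12)), 12)
  expect_equal(glance(m12)$fascicle_count, 12)
})

test_that("split/merge detection matches scheduled events exactly", {
  expect_equal(detect_split_merge(straight_tube())$rate_per_mm, 0)

  v1 <- gen_label_volume(phantom_spec(seed = 4, n_fascicles = 1,
    nerve_diameter = 1500, fascicle_diameter_range = c(300, 400),
    z_extent = 1500,
    event_schedule = list(list(z = 500, type = "split", labels = 1))))
  r1 <- detect_split_merge(v1$volume)
  expect_equal(nrow(r1$events), 1)
  expect_equal(r1$events$type, "split")
  z0 <- round(500 / v1$volume$voxel_size)
  expect_gte(r1$events$z_index, z0)
  expect_lte(r1$events$z_index, z0 + 11)

  v5 <- gen_label_volume(phantom_spec(seed = 11, n_fascicles = 3,
    nerve_diameter = 2000, fascicle_diameter_range = c(250, 400),
    z_extent = 5000,
    event_schedule = list(
      list(z = 800, type = "split", labels = 1),
      list(z = 1700, type = "split", labels = 2),
      list(z = 2600, type = "split", labels = 3),
      list(z = 3500, type = "merge", labels = c(1, 4)),
      list(z = 4300, type = "merge", labels = c(2, 5)))))
  r5 <- detect_split_merge(v5$volume)
  expect_equal(r5$events$type, c("split", "split", "split", "merge", "merge"))
  expect_equal(r5$rate_per_mm, 5 / r5$length_analyzed_mm)
  expect_equal(r5$rate_per_mm, 1.0, tolerance = 0.02)
})

test_that("centerline extraction: straight and helical tubes", {
  tube <- straight_tube(nz = 60)
  cl <- extract_centerline(tube, label = 1)
  # axis-aligned: transverse deviation < 1 voxel
  expect_lt(max(abs(cl$points$x_um - cl$points$x_um[1])), 11.4)
  expect_lt(max(abs(cl$points$y_um - cl$points$y_um[1])), 11.4)
  # arc length of straight tube = (slices - 1) * voxel within 0.1%
  expect_equal(max(cl$points$arc_length_um), 59 * 11.4,
               tolerance = 1e-3)

  # helix: arc length must exceed the z extent
  nz <- 80; nxy <- 61; vx <- 11.4
  L <- array(0L, dim = c(nz, nxy, nxy))
  xs <- matrix(seq_len(nxy), nxy, nxy, byrow = TRUE)
  ys <- matrix(seq_len(nxy), nxy, nxy, byrow = FALSE)
  for (iz in seq_len(nz)) {
    cx <- 31 + 15 * cos(2 * pi * iz / 40)
    cy <- 31 + 15 * sin(2 * pi * iz / 40)
    sl <- matrix(0L, nxy, nxy)
    sl[(xs - cx)^2 + (ys - cy)^2 <= 36] <- 1L
    L[iz, , ] <- sl
  }
  hel <- extract_centerline(label_volume(L, vx), label = 1)
  expect_gt(max(hel$points$arc_length_um), (nz - 1) * vx)

  expect_error(extract_centerline(tube, label = 99), class = "LABEL_ABSENT")
})

test_that("transverse reslice recovers true tube diameter on oblique tubes", {
  vx <- 11.4
  # axis-aligned: reslice equals the native slice (same disc)
  tube <- straight_tube(nz = 60, r_vox = 8)
  cl <- extract_centerline(tube, 1)
  rs <- reslice_transverse(tube, cl, arc_position = 300, plane_size = 450)
  native <- tube$labels[round(300 / vx) + 1, , ]
  expect_equal(sum(rs > 0), sum(native > 0), tolerance = 0.05)

  # 45-degree tilted tube (axis in y-z plane)
  nz <- 90; nxy <- 91
  r_um <- 6 * vx
  L <- array(0L, dim = c(nz, nxy, nxy))
  xs <- matrix(seq_len(nxy), nxy, nxy, byrow = TRUE)
  ys <- matrix(seq_len(nxy), nxy, nxy, byrow = FALSE)
  for (iz in seq_len(nz)) {
    cy <- 10 + (iz - 1)           # dy/dz = 1 -> 45 degrees
    # distance from voxel center to the tube axis in 3D:
    # axis point p(t) = (cx, 10 + t, t); direction (0, 1, 1)/sqrt(2)
    dx <- (xs - 46) * vx
    dyz <- (ys - cy) * vx / sqrt(2)   # perpendicular component of y-z offset
    sl <- matrix(0L, nxy, nxy)
    sl[dx^2 + dyz^2 <= r_um^2] <- 1L
    L[iz, , ] <- sl
  }
  vol <- label_volume(L, vx)
  cl2 <- extract_centerline(vol, 1, smooth_window = 5)
  mid_arc <- max(cl2$points$arc_length_um) / 2
  rs2 <- reslice_transverse(vol, cl2, mid_arc, plane_size = 2 * r_um + 20 * vx)
  d_true <- 2 * r_um
  d_reslice <- effective_circular_diameter(rs2)
  expect_equal(d_reslice, d_true, tolerance = 0.05)
  # native oblique slice is foreshortened-elongated: larger effective diameter
  native_mid <- mask2d(vol$labels[45, , ], vx)
  expect_gt(effective_circular_diameter(native_mid), d_reslice)

  expect_error(reslice_transverse(vol, cl2, 1e9, 100), class = "OUT_OF_RANGE")
})
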