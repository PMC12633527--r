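test_that("single-fascicle phantom is centered with exact drawn diameter", {
  spec <- phantom_spec(seed = 1, n_fascicles = 1, nerve_diameter = 1000,
                       fascicle_diameter_range = c(400, 400))
  cs <- gen_cross_section(spec)
  expect_length(cs$geometry$fascicles, 1)
  ctr <- poly_centroid(cs$geometry$fascicles[[1]]$outer)
  expect_lt(sqrt(sum(ctr^2)), 1e-6)
  expect_equal(cs$ground_truth$effective_diameter_um, 400)
  # polygon area realizes the drawn effective diameter (n-gon deficit only)
  expect_equal(effective_circular_diameter(cs$geometry$fascicles[[1]]$outer),
               400, tolerance = 1e-3)
})

test_that("generators are deterministic under a fixed seed", {
  spec <- small_spec(seed = 9)
  a <- gen_cross_section(spec)
  b <- gen_cross_section(spec)
  expect_identical(a$geometry, b$geometry)
  expect_identical(a$masks, b$masks)
  va <- gen_label_volume(small_spec(seed = 9, z_extent = 1000))
  vb <- gen_label_volume(small_spec(seed = 9, z_extent = 1000))
  expect_identical(va$volume$labels, vb$volume$labels)
  pa <- gen_fiber_population(spec, a$geometry)
  pb <- gen_fiber_population(spec, b$geometry)
  expect_identical(pa, pb)
})

test_that("12-fascicle packing respects the spacing constraint (brute-force oracle)", {
  cs <- section12()
  outers <- lapply(cs$geometry$fascicles, `[[`, "outer")
  expect_length(outers, 12)
  min_gap <- Inf
  for (i in 1:11) for (j in (i + 1):12) {
    min_gap <- min(min_gap, poly_min_distance(outers[[i]], outers[[j]]))
  }
  expect_gte(min_gap, 20)
  # all fascicles inside the epineurium
  for (o in outers) {
    expect_true(all(points_in_polygon(o, cs$geometry$epineurium)))
  }
  # raster masks agree with polygons within one pixel: fascicle pixel areas
  # match polygon areas to one-pixel-boundary precision
  ps <- attr(cs$masks$fascicles_outer, "pixel_size")
  for (i in seq_len(12)) {
    a_pix <- sum(cs$masks$fascicles_outer == i) * ps^2
    a_poly <- poly_area(outers[[i]])
    perim <- 2 * pi * sqrt(a_poly / pi)
    expect_lt(abs(a_pix - a_poly), 1.5 * perim * ps)
  }
})

test_that("fascicle geometry is valid: ccw, inner inside outer, bounded eccentricity", {
  cs <- section12()
  expect_gt(poly_area_signed(cs$geometry$epineurium), 0)
  for (f in cs$geometry$fascicles) {
    expect_gt(poly_area_signed(f$outer), 0)
    expect_gt(poly_area_signed(f$inner), 0)
    expect_true(all(points_in_polygon(f$inner, f$outer)))
  }
  expect_true(all(cs$ground_truth$axis_ratio <= 2))
})

test_that("label volume realizes scheduled split/merge structure", {
  # straight tube: no events
  v0 <- gen_label_volume(small_spec(seed = 2, n_fascicles = 1, z_extent = 1000))
  expect_equal(nrow(v0$ground_truth$true_events), 0)
  counts0 <- apply(v0$volume$labels, 1, function(sl)
    max(EBImage::bwlabel(sl > 0)))
  expect_true(all(counts0 == 1))

  # one split: exactly one 1 -> 2 component transition (independent
  # component-count oracle via EBImage)
  v1 <- gen_label_volume(phantom_spec(seed = 4, n_fascicles = 1,
    nerve_diameter = 1500, fascicle_diameter_range = c(300, 400),
    z_extent = 1500,
    event_schedule = list(list(z = 500, type = "split", labels = 1))))
  counts <- apply(v1$volume$labels, 1, function(sl)
    max(EBImage::bwlabel(sl > 0)))
  expect_equal(sum(diff(counts) != 0), 1)
  expect_equal(counts[1], 1)
  expect_equal(counts[length(counts)], 2)
  tz <- which(diff(counts) == 1)
  z0 <- round(500 / v1$volume$voxel_size)
  expect_gte(tz, z0)
  expect_lte(tz, z0 + 11)

  # 3 splits + 2 merges: 5 ground-truth events in schedule order
  v5 <- gen_label_volume(phantom_spec(seed = 11, n_fascicles = 3,
    nerve_diameter = 2000, fascicle_diameter_range = c(250, 400),
    z_extent = 5000,
    event_schedule = list(
      list(z = 800, type = "split", labels = 1),
      list(z = 1700, type = "split", labels = 2),
      list(z = 2600, type = "split", labels = 3),
      list(z = 3500, type = "merge", labels = c(1, 4)),
      list(z = 4300, type = "merge", labels = c(2, 5)))))
  ev <- v5$ground_truth$true_events
  expect_equal(nrow(ev), 5)
  expect_equal(ev$type, c("split", "split", "split", "merge", "merge"))
})

test_that("schedule validation catches conflicts and out-of-range events", {
  expect_error(
    phantom_spec(seed = 1, event_schedule = list(
      list(z = 6000, type = "split", labels = 1)), z_extent = 5000),
    class = "INVALID_ARGUMENT")
  expect_error(
    gen_label_volume(phantom_spec(seed = 1, n_fascicles = 2, z_extent = 2000,
      event_schedule = list(
        list(z = 500, type = "split", labels = 1),
        list(z = 500, type = "merge", labels = c(1, 2))))),
    class = "SCHEDULE_CONFLICT")
})

test_that("modality pair: similarity scale and warp behave as specified", {
  spec <- small_spec(seed = 5)
  # identity: masks equal
  p0 <- gen_modality_pair(spec, scale = 1, warp_amplitude = 0)
  expect_equal(sum(abs(p0$fixed - p0$moving)), 0)
  # pure scale: pixel-count area ratio ~ scale^2
  ps <- gen_modality_pair(spec, scale = 0.915, warp_amplitude = 0)
  ratio <- sum(ps$moving) / sum(ps$fixed)
  expect_equal(ratio, 0.915^2, tolerance = 0.03)
  # warp: Dice < 1, but applying the known backward map restores the fixed mask
  pw <- reg_pair()
  expect_lt(dice_coefficient(pw$fixed, pw$moving), 1)
  undone <- nervemap:::resample_mask(
    pw$fixed, pw$ground_truth$map_moving_to_fixed,
    out_dim = c(ncol(pw$fixed), nrow(pw$fixed)),
    out_pixel = attr(pw$fixed, "pixel_size"),
    out_origin = attr(pw$fixed, "origin"))
  expect_gt(dice_coefficient(undone, pw$moving), 0.99)
  # forward/backward maps are mutual inverses
  pts <- cbind(runif(20, 100, 500), runif(20, 100, 500))
  back <- pw$ground_truth$map_moving_to_fixed(
    pw$ground_truth$map_fixed_to_moving(pts))
  expect_lt(max(abs(back - pts)), 1e-6)
})

test_that("modality pair rejects folding warps", {
  expect_error(gen_modality_pair(small_spec(seed = 5), scale = 1,
                                 warp_amplitude = 500),
               class = "WARP_FOLDS")
})

test_that("fiber population: counts, containment, diameters", {
  spec <- small_spec(seed = 6)
  cs <- gen_cross_section(spec)
  # Poisson count check: expected density x area, 99% interval
  pop <- gen_fiber_population(spec, cs$geometry)
  lambda <- spec$fiber_density *
    sum(vapply(cs$geometry$fascicles, function(f) poly_area(f$inner),
               numeric(1))) / 1e6
  expect_gte(nrow(pop), qpois(0.005, lambda))
  expect_lte(nrow(pop), qpois(0.995, lambda))
  # brute-force containment of every centroid in its inner polygon
  for (i in seq_along(cs$geometry$fascicles)) {
    sel <- pop$fascicle_id == i
    expect_true(all(points_in_polygon(
      cbind(pop$x_um[sel], pop$y_um[sel]),
      cs$geometry$fascicles[[i]]$inner)))
  }
  # degenerate mixture: all mass at 6 um
  spec6 <- small_spec(seed = 6, diameter_mixture = list(c(1, 6, 0)))
  pop6 <- gen_fiber_population(spec6, cs$geometry)
  expect_true(all(pop6$diameter_um == 6))
})

test_that("trace phantom: jitter statistics and landmark centroids", {
  cp <- cbind(seq(0, 100, length.out = 8), sin(seq(0, 3, length.out = 8)) * 10,
              seq(0, 40, length.out = 8))
  # zero jitter: points on the curve
  t0 <- gen_trace_set(cp, jitter = 0, n_points = 200, seed = 2)
  dense <- t0$ground_truth$curve(seq(0, 1, length.out = 4000))
  d0 <- vapply(seq_len(nrow(t0$cloud)), function(i)
    min(sqrt(colSums((t(dense) - t0$cloud[i, ])^2))), numeric(1))
  expect_lt(max(d0), 0.1)
  # jitter 0.5: RMS point-to-curve distance within 10% at n = 1000
  t1 <- gen_trace_set(cp, jitter = 0.5, n_points = 1000, seed = 2)
  d1 <- vapply(seq_len(nrow(t1$cloud)), function(i)
    min(sqrt(colSums((t(dense) - t1$cloud[i, ])^2))), numeric(1))
  expect_equal(sqrt(mean(d1^2)), 0.5, tolerance = 0.1)
  # landmark ground truth equals realized arithmetic means
  tl <- gen_trace_set(cp, jitter = 0, n_points = 50, seed = 3,
                      landmarks = list(a = c(0, 0, 0), b = c(10, 5, 2),
                                       c = c(-4, 8, 1)),
                      landmark_n = 50)
  for (nm in names(tl$landmark_clouds)) {
    expect_identical(tl$ground_truth$landmark_centroids[[nm]],
                     colMeans(tl$landmark_clouds[[nm]]))
  }
})
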