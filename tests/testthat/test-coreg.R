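test_that("trace trimming and B-spline curve fitting", {
  # noiseless line: residual 0, curve on the line
  t <- seq(0, 1, length.out = 200)
  line <- cbind(10 * t, -3 * t, 5 * t)
  fit <- trim_and_fit_spline(line, target_spacing = 0.01)
  expect_lt(fit$rms_residual, 1e-9)
  on_curve <- fit$curve(seq(0, 1, length.out = 50))
  u <- c(10, -3, 5) / sqrt(sum(c(10, -3, 5)^2))
  perp <- on_curve - (on_curve %*% u) %*% t(u)   # component off the line
  expect_lt(max(abs(perp)), 1e-6)

  # duplicated points: trimmed count matches the greedy-spacing oracle
  dup <- line[rep(1:200, each = 3), ]
  fit2 <- trim_and_fit_spline(dup, target_spacing = 0.1)
  greedy <- function(pts, sp) {
    keep <- 1; last <- pts[1, ]
    for (i in 2:nrow(pts)) {
      if (sqrt(sum((pts[i, ] - last)^2)) >= sp) { keep <- keep + 1; last <- pts[i, ] }
    }
    keep
  }
  expect_equal(fit2$n_kept, greedy(dup, 0.1))

  # known smooth curve, zero jitter: max deviation < spacing / 10
  cp <- cbind(seq(0, 100, length.out = 8), 10 * sin(seq(0, 2, length.out = 8)),
              seq(0, 30, length.out = 8))
  tr <- gen_trace_set(cp, jitter = 0, n_points = 800, seed = 4)
  fit3 <- trim_and_fit_spline(tr$cloud, target_spacing = 1)
  truth <- tr$ground_truth$curve(seq(0.02, 0.98, length.out = 300))
  fitted <- fit3$curve(seq(0, 1, length.out = 3000))
  dev <- vapply(seq_len(nrow(truth)), function(i)
    min(sqrt(colSums((t(fitted) - truth[i, ])^2))), numeric(1))
  expect_lt(max(dev), 0.1)

  expect_error(trim_and_fit_spline(line[1:3, ], 0.01), class = "TOO_FEW_POINTS")
})

test_that("landmark centroid is the arithmetic mean", {
  expect_equal(landmark_centroid(matrix(c(1, 2, 3), 1)), c(1, 2, 3))
  sym <- rbind(c(1, 2, 3), -c(1, 2, 3), c(-4, 5, 0), c(4, -5, 0))
  expect_equal(landmark_centroid(sym), c(0, 0, 0))
  set.seed(1)
  cl <- matrix(rnorm(150), ncol = 3)
  oracle <- c(sum(cl[, 1]), sum(cl[, 2]), sum(cl[, 3])) / 50
  expect_equal(landmark_centroid(cl), oracle, tolerance = 1e-12)
  expect_error(landmark_centroid(cl[0, , drop = FALSE]), class = "EMPTY_CLOUD")
})

test_that("rigid landmark registration recovers known transforms", {
  src <- rbind(a = c(0, 0, 0), b = c(10, 0, 0), c = c(0, 8, 0),
               d = c(3, 2, 7), e = c(-4, 5, 1))
  th <- 30 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tv <- c(5, -2, 3)
  dst <- t(R %*% t(src)) + matrix(tv, 5, 3, byrow = TRUE)
  rownames(dst) <- rownames(src)

  fit <- register_landmarks_rigid(src, dst)
  expect_lt(max(abs(fit$rotation - R)), 1e-9)
  expect_lt(max(abs(fit$translation - tv)), 1e-9)
  expect_lt(fit$rms_residual, 1e-9)

  # identity
  fid <- register_landmarks_rigid(src, src)
  expect_lt(max(abs(fid$rotation - diag(3))), 1e-9)
  expect_lt(fid$rms_residual, 1e-12)

  # least-squares optimality under noise: fitted residual never exceeds the
  # residual of the true transform (independent check)
  set.seed(7)
  noisy <- dst + matrix(rnorm(15, 0, 0.3), 5, 3)
  rownames(noisy) <- rownames(src)
  fn <- register_landmarks_rigid(src, noisy)
  res_true <- sqrt(mean(rowSums((t(R %*% t(src)) +
    matrix(tv, 5, 3, byrow = TRUE) - noisy)^2)))
  expect_lte(fn$rms_residual, res_true + 1e-12)

  expect_error(register_landmarks_rigid(src[1:2, ], dst[1:2, ]),
               class = "NAME_MISMATCH")
  col_src <- rbind(a = c(0, 0, 0), b = c(1, 0, 0), c = c(2, 0, 0))
  expect_error(register_landmarks_rigid(col_src, col_src + 1),
               class = "DEGENERATE_CONFIGURATION")
})

test_that("level-fraction mapping preserves fractional position", {
  la <- c(jugular = 0, clavicle = 40, sternal = 90)
  lb <- c(jugular = 5, clavicle = 65, sternal = 140)
  expect_equal(map_by_level_fraction(40, la, lb), 65)
  expect_equal(map_by_level_fraction(20, la, lb), 35)           # midpoint
  expect_equal(map_by_level_fraction(0 + 0.3 * 40, la, lb),
               5 + 0.3 * (65 - 5))                              # 30% oracle
  expect_error(map_by_level_fraction(95, la, lb), class = "UNBRACKETED_QUERY")
})

test_that("histology slice estimation from block gridlines", {
  gl <- data.frame(block_id = c("A1", "B2"), z_index = c(100, 400))
  m0 <- histology_metadata("sub1", "SR008-CL1", "A1", slice_depth_um = 0)
  expect_equal(estimate_histology_slice(m0, gl), 100L)
  m5 <- histology_metadata("sub1", "SR008-CL1", "A1", slice_depth_um = 57)
  expect_equal(estimate_histology_slice(m5, gl, voxel_size = 11.4), 105L)
  expect_error(estimate_histology_slice(
    histology_metadata("s", "SR008-CL1", "Z9", 10), gl),
    class = "GRIDLINE_ABSENT")
  expect_error(estimate_histology_slice(
    histology_metadata("s", "SR008-CL1", "A1", 5000), gl,
    block_extent_um = 3000), class = "OUT_OF_BLOCK")
  expect_error(histology_metadata("s", "bad-id", "A1", 0),
               class = "INVALID_ARGUMENT")
})

test_that("mask pair preprocessing: COM alignment, margin, resolution", {
  # identical masks in -> identical standardized masks out
  m <- mask2d(matrix(0, 120, 120), 9)
  m[40:80, 30:70] <- 1
  std <- preprocess_mask_pair(m, m)
  expect_identical(unclass(std$fixed)[, ], unclass(std$moving)[, ])
  expect_equal(attr(std$fixed, "pixel_size"), 3)

  # translated moving: centers of mass coincide within one output pixel
  m2 <- mask2d(matrix(0, 120, 120), 9)
  m2[44:84, 34:74] <- 1   # ~36 um shift
  std2 <- preprocess_mask_pair(m, m2)
  expect_lt(max(abs(mask_com(std2$fixed) - mask_com(std2$moving))), 3)

  # 900 um tissue bbox -> 1170 um field of view per axis (15% per side)
  mb <- mask2d(matrix(0, 200, 200), 9)
  mb[51:150, 51:150] <- 1   # 100 px x 9 um = 900 um bbox
  stdb <- preprocess_mask_pair(mb, mb)
  expect_equal(ncol(stdb$fixed) * 3, 1170, tolerance = 3 / 1170)
  expect_equal(nrow(stdb$fixed) * 3, 1170, tolerance = 3 / 1170)

  expect_error(preprocess_mask_pair(mask2d(matrix(0, 5, 5), 1), m),
               class = "EMPTY_MASK")
})

test_that("rigid mask registration: identity, scale, and rotation recovery", {
  std <- reg_std()
  # moving = fixed: identity, scale 1 within 1e-3
  id <- register_masks_rigid(std$fixed, std$fixed, "similarity")
  expect_equal(id$scale, 1, tolerance = 1e-3)
  expect_lt(abs(id$angle), 1e-3)
  expect_true(id$converged)

  # known similarity scale 0.915 with smooth warp: recovered in [0.905, 0.925]
  rig <- reg_rigid()
  expect_gte(rig$scale, 0.905)
  expect_lte(rig$scale, 0.925)
  expect_equal(percent_size_difference(rig), 8.5, tolerance = 1.2)

  # pure 10-degree rotation, euler mode: angle within 0.5 degrees
  pr <- gen_modality_pair(small_spec(seed = 8), scale = 1,
                          warp_amplitude = 0, angle = 10 * pi / 180)
  stdr <- preprocess_mask_pair(pr$fixed, pr$moving)
  rr <- register_masks_rigid(stdr$fixed, stdr$moving, "euler")
  expect_equal(rr$scale, 1)  # scale frozen in euler mode
  expect_equal(rr$angle * 180 / pi, 10, tolerance = 0.5 / 10)
})

test_that("B-spline refinement improves overlap without folding", {
  std <- reg_std()
  # moving = fixed: displacement stays essentially zero
  id_rig <- register_masks_rigid(std$fixed, std$fixed, "similarity")
  id_bsp <- register_masks_bspline(std$fixed, std$fixed, id_rig)
  expect_lt(max(sqrt(id_bsp$coef_x^2 + id_bsp$coef_y^2)), 3)

  bsp <- reg_bspline()
  expect_gte(bsp$dice_bspline, bsp$dice_rigid)
  expect_gte(bsp$dice_bspline, 0.98)

  # numerical Jacobian of the recovered total map positive on >= 99% of
  # tissue pixels
  ax <- nervemap:::mask_axes(std$fixed)
  tissue <- which(std$fixed > 0, arr.ind = TRUE)
  pts <- cbind(ax$x[tissue[, 2]], ax$y[tissue[, 1]])
  h <- 1.5
  jxx <- (apply_transform_points(bsp, cbind(pts[, 1] + h, pts[, 2])) -
            apply_transform_points(bsp, cbind(pts[, 1] - h, pts[, 2]))) / (2 * h)
  jyy <- (apply_transform_points(bsp, cbind(pts[, 1], pts[, 2] + h)) -
            apply_transform_points(bsp, cbind(pts[, 1], pts[, 2] - h))) / (2 * h)
  detj <- jxx[, 1] * jyy[, 2] - jxx[, 2] * jyy[, 1]
  expect_gte(mean(detj > 0), 0.99)
})

test_that("transform application composes correctly and maps ground truth", {
  rt <- structure(list(mode = "similarity", scale = 0.9, angle = 0.2,
                       translation = c(5, -3), center = c(50, 50),
                       metric = 0, iterations = 0, converged = TRUE),
                  class = "rigid_transform")
  pts <- cbind(runif(30, 0, 100), runif(30, 0, 100))
  # identity chain
  idt <- structure(list(mode = "euler", scale = 1, angle = 0,
                        translation = c(0, 0), center = c(0, 0),
                        metric = 0, iterations = 0, converged = TRUE),
                   class = "rigid_transform")
  expect_equal(unname(apply_transform_points(idt, pts)[, ]), unname(pts),
               ignore_attr = TRUE)
  # pure translation
  tt <- idt; tt$translation <- c(11, -4)
  mapped <- apply_transform_points(tt, pts)
  expect_equal(mapped[, 1], pts[, 1] + 11)
  expect_equal(mapped[, 2], pts[, 2] - 4)
  # chain = sequential application, pointwise to 1e-9
  chain <- list(rt, tt)
  seq_applied <- apply_transform_points(tt, apply_transform_points(rt, pts))
  expect_equal(apply_transform_points(chain, pts)[, ], seq_applied[, ],
               tolerance = 1e-9, ignore_attr = TRUE)

  # ground-truth similarity chain maps phantom fiber centroids exactly
  spec <- small_spec(seed = 5)
  pair <- gen_modality_pair(spec, scale = 0.915, warp_amplitude = 0,
                            angle = 0.05, translation = c(12, -8))
  gt <- pair$ground_truth
  gt_t <- structure(list(mode = "similarity", scale = gt$scale,
                         angle = gt$angle, translation = gt$translation,
                         center = gt$center, metric = 0, iterations = 0,
                         converged = TRUE), class = "rigid_transform")
  cs <- gen_cross_section(spec)
  pop <- gen_fiber_population(spec, cs$geometry)
  fib <- cbind(pop$x_um, pop$y_um)
  mapped_pkg <- apply_transform_points(gt_t, fib)
  mapped_truth <- gt$map_fixed_to_moving(fib)
  expect_lt(max(sqrt(rowSums((mapped_pkg - mapped_truth)^2))), 6)
})

test_that("percent size difference follows the stated sign convention", {
  mk <- function(s, mode = "similarity") structure(
    list(mode = mode, scale = s, angle = 0, translation = c(0, 0),
         center = c(0, 0), metric = 0, iterations = 0, converged = TRUE),
    class = "rigid_transform")
  expect_equal(percent_size_difference(mk(1)), 0)
  expect_equal(percent_size_difference(mk(0.915)), 8.5, tolerance = 1e-12)
  expect_equal(percent_size_difference(mk(1.10)), -10, tolerance = 1e-12)
  expect_error(percent_size_difference(mk(1, "euler")), class = "MODE_MISMATCH")
})
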