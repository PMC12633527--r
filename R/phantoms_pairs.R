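# Modality pairs, fiber populations, and stylus-trace phantoms.

#' Generate a co-registration phantom pair (fixed and moving masks)
#'
#' The fixed mask is the binary fascicle raster of the phantom cross
#' section. The moving mask carries the same content through a similarity
#' transform (content size ratio `scale`, i.e. scale < 1 makes the moving
#' fascicles smaller) plus a smooth band-limited displacement field of peak
#' magnitude `warp_amplitude`. The ground-truth backward map
#' (moving to fixed coordinates) is closed-form; the forward map is obtained
#' by fixed-point inversion to 1e-9 um.
#'
#' @param spec A [phantom_spec()].
#' @param scale Similarity content scale (moving/fixed size ratio).
#' @param warp_amplitude Peak displacement of the smooth warp, micrometres.
#' @param angle Similarity rotation, radians.
#' @param translation Similarity translation in micrometres (length 2).
#' @return List with `fixed`, `moving` ([mask2d()]), and `ground_truth`
#'   containing the transform parameters and mapping functions.
#' @export
gen_modality_pair <- function(spec, scale = 0.915, warp_amplitude = 0,
                              angle = 0, translation = c(0, 0)) {
  if (scale <= 0) nm_abort("INVALID_ARGUMENT", "scale must be > 0")
  cs <- gen_cross_section(spec)
  fixed <- mask2d((cs$masks$fascicles_outer > 0) * 1,
                  spec$pixel_size, attr(cs$masks$fascicles_outer, "origin"))

  ax <- mask_axes(fixed)
  ctr <- c(mean(range(ax$x)), mean(range(ax$y)))
  Lx <- diff(range(ax$x)); Ly <- diff(range(ax$y))

  ph <- with_stream(spec$seed, "warp", stats::runif(4, 0, 2 * pi))
  u_fun <- function(p) {
    if (warp_amplitude == 0) return(matrix(0, nrow(p), 2))
    sx <- 2 * pi * (p[, 1] - ctr[1]) / Lx
    sy <- 2 * pi * (p[, 2] - ctr[2]) / Ly
    ux <- sin(sx + ph[1]) * cos(sy + ph[2])
    uy <- cos(sx + ph[3]) * sin(sy + ph[4])
    mx <- max(sqrt(ux^2 + uy^2), 1e-12)
    cbind(ux, uy) * (warp_amplitude / mx)
  }

  ca <- cos(angle); sa <- sin(angle)
  # forward similarity (fixed -> moving content position):
  #   A(x) = scale * R(angle) (x - ctr) + ctr + t
  A_inv <- function(y) {
    dx <- y[, 1] - ctr[1] - translation[1]
    dy <- y[, 2] - ctr[2] - translation[2]
    cbind(( ca * dx + sa * dy) / scale + ctr[1],
          (-sa * dx + ca * dy) / scale + ctr[2])
  }
  A_fwd <- function(x) {
    dx <- x[, 1] - ctr[1]; dy <- x[, 2] - ctr[2]
    cbind(scale * (ca * dx - sa * dy) + ctr[1] + translation[1],
          scale * (sa * dx + ca * dy) + ctr[2] + translation[2])
  }
  # backward map G: moving -> fixed, closed form (warp expressed in fixed space)
  map_moving_to_fixed <- function(y) {
    x <- A_inv(y)
    x + u_fun(x)
  }
  map_fixed_to_moving <- function(x, tol = 1e-9, max_iter = 100) {
    # solve G(y) = x by fixed-point iteration: y = A(x - u(xk)) style update
    y <- A_fwd(x)
    for (i in seq_len(max_iter)) {
      xk <- A_inv(y)
      r <- (xk + u_fun(xk)) - x
      if (max(abs(r)) < tol) break
      y <- y - r * scale  # contraction step back through the similarity
    }
    y
  }

  # fold check: Jacobian determinant of the backward map on a coarse grid
  if (warp_amplitude > 0) {
    h <- spec$pixel_size
    gx <- seq(min(ax$x), max(ax$x), length.out = 25)
    gy <- seq(min(ax$y), max(ax$y), length.out = 25)
    g <- cbind(rep(gx, times = 25), rep(gy, each = 25))
    jp <- (map_moving_to_fixed(cbind(g[, 1] + h, g[, 2])) -
             map_moving_to_fixed(cbind(g[, 1] - h, g[, 2]))) / (2 * h)
    jq <- (map_moving_to_fixed(cbind(g[, 1], g[, 2] + h)) -
             map_moving_to_fixed(cbind(g[, 1], g[, 2] - h))) / (2 * h)
    detj <- jp[, 1] * jq[, 2] - jp[, 2] * jq[, 1]
    if (any(detj <= 0)) {
      nm_abort("WARP_FOLDS", "displacement field folds (non-positive Jacobian)")
    }
  }

  moving <- resample_mask(fixed, map_moving_to_fixed,
                          out_dim = c(ncol(fixed), nrow(fixed)),
                          out_pixel = spec$pixel_size,
                          out_origin = mask_origin(fixed))
  list(
    fixed = fixed, moving = moving,
    ground_truth = list(
      scale = scale, angle = angle, translation = translation, center = ctr,
      warp_amplitude = warp_amplitude,
      map_moving_to_fixed = map_moving_to_fixed,
      map_fixed_to_moving = map_fixed_to_moving
    )
  )
}

# Truncated-at-zero Gaussian mixture draw.
draw_mixture <- function(n, mixture) {
  w <- vapply(mixture, `[`, numeric(1), 1)
  comp <- sample.int(length(mixture), n, replace = TRUE, prob = w)
  out <- numeric(n)
  for (k in seq_along(mixture)) {
    idx <- comp == k
    if (!any(idx)) next
    mu <- mixture[[k]][2]; sd <- mixture[[k]][3]
    v <- stats::rnorm(sum(idx), mu, sd)
    while (any(v <= 0.2)) v[v <= 0.2] <- stats::rnorm(sum(v <= 0.2), mu, sd)
    out[idx] <- v
  }
  out
}

# Uniform points inside a polygon by bounding-box rejection.
runif_in_polygon <- function(n, poly) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  bb <- apply(poly, 2, range)
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- max(2 * (n - nrow(out)), 16)
    cand <- cbind(stats::runif(m, bb[1, 1], bb[2, 1]),
                  stats::runif(m, bb[1, 2], bb[2, 2]))
    out <- rbind(out, cand[points_in_polygon(cand, poly), , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Generate a myelinated fiber population inside a cross section
#'
#' Fiber counts per fascicle are Poisson with mean
#' `fiber_density x inner area`; centroids are uniform inside the
#' inner-perineurium polygon; diameters follow the spec's Gaussian mixture.
#'
#' @param spec A [phantom_spec()].
#' @param section A [cross_section()] (typically from [gen_cross_section()]).
#' @return Tibble `fiber_id, x_um, y_um, diameter_um, fascicle_id`.
#' @export
gen_fiber_population <- function(spec, section) {
  if (spec$fiber_density <= 0) {
    nm_abort("INVALID_ARGUMENT", "fiber_density must be > 0")
  }
  with_stream(spec$seed, "fibers", {
    rows <- lapply(seq_along(section$fascicles), function(i) {
      inner <- section$fascicles[[i]]$inner
      area_mm2 <- poly_area(inner) / 1e6
      n <- stats::rpois(1, spec$fiber_density * area_mm2)
      pts <- runif_in_polygon(n, inner)
      tibble::tibble(
        x_um = pts[, 1], y_um = pts[, 2],
        diameter_um = draw_mixture(n, spec$diameter_mixture),
        fascicle_id = i
      )
    })
    out <- dplyr::bind_rows(rows)
    dplyr::mutate(out, fiber_id = dplyr::row_number(), .before = 1)
  })
}

#' Generate a stylus-trace phantom (point cloud plus landmark clouds)
#'
#' Emulates optical-stylus digitization of a nerve path: points scattered
#' around a smooth true curve (interpolating spline through the control
#' points, chord-length parameterized) with `jitter` the RMS point-to-curve
#' distance, plus Gaussian landmark clouds whose ground-truth centroids are
#' the realized arithmetic means.
#'
#' @param control_points k x 3 matrix (mm) defining the true curve.
#' @param jitter RMS point-to-curve distance, mm.
#' @param n_points Number of trace points.
#' @param landmarks Optional named list of true landmark positions (length-3).
#' @param landmark_n Points per landmark cloud.
#' @param landmark_sd Isotropic landmark scatter sd, mm.
#' @param seed Seed for the trace stream.
#' @return List with `cloud`, `landmark_clouds`, and `ground_truth`
#'   (`curve` function of arc-fraction t in [0,1], `landmark_centroids`).
#' @export
gen_trace_set <- function(control_points, jitter = 0, n_points = 500,
                          landmarks = NULL, landmark_n = 50, landmark_sd = 1,
                          seed = 1) {
  if (jitter < 0) nm_abort("INVALID_ARGUMENT", "jitter must be >= 0")
  cp <- as.matrix(control_points)
  d <- c(0, cumsum(sqrt(rowSums(diff(cp)^2))))
  t_cp <- d / max(d)
  fx <- stats::splinefun(t_cp, cp[, 1], method = "natural")
  fy <- stats::splinefun(t_cp, cp[, 2], method = "natural")
  fz <- stats::splinefun(t_cp, cp[, 3], method = "natural")
  curve <- function(t) cbind(fx(t), fy(t), fz(t))

  with_stream(seed, "trace", {
    tt <- sort(stats::runif(n_points))
    pts <- curve(tt)
    if (jitter > 0) {
      # isotropic 3D noise with per-axis sd jitter/sqrt(2) gives an RMS
      # perpendicular (point-to-curve) distance of `jitter`
      pts <- pts + matrix(stats::rnorm(3 * n_points, 0, jitter / sqrt(2)),
                          ncol = 3)
    }
    lm_clouds <- NULL
    lm_centroids <- NULL
    if (!is.null(landmarks)) {
      lm_clouds <- lapply(landmarks, function(p) {
        sweep(matrix(stats::rnorm(3 * landmark_n, 0, landmark_sd), ncol = 3),
              2, p, `+`)
      })
      lm_centroids <- lapply(lm_clouds, colMeans)
    }
    list(
      cloud = pts,
      landmark_clouds = lm_clouds,
      ground_truth = list(curve = curve, t = tt,
                          landmark_centroids = lm_centroids)
    )
  })
}
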