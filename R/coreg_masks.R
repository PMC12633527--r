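# Mask-based co-registration: preprocessing, rigid/similarity alignment by
# regular-step gradient descent, cubic B-spline refinement by L-BFGS-B.
#
# Transform convention (resampling form): a fitted transform maps
# coordinates of the FIXED standardized frame to the MOVING frame, so the
# reported similarity scale is the moving/fixed content size ratio (a scale
# of 0.915 means the moving structures are 8.5% smaller).

#' Registration settings
#'
#' Defaults: mean-squares metric on binary masks; rigid stage by regular
#' step gradient descent (learning rate 1.0, minimum step 0.01, at most 100
#' iterations, relaxation 0.5, parameter scales 10.0, 1.0, 0.001, 0.001 for
#' scale, rotation and translations); B-spline stage by L-BFGS-B (gradient
#' tolerance 1e-5, at most 100 iterations, 5 corrections, at most 1024
#' evaluations, cost convergence factor 1e7); 15% bounding-box margin per
#' side; 3 um resampling.
#'
#' @param learning_rate,min_step,max_iter,relaxation Rigid optimizer budget.
#' @param scales Parameter scales (scale, rotation, tx, ty).
#' @param bspline_gradient_tol,bspline_max_iter,bspline_corrections,
#'   bspline_max_evals,bspline_cost_factor B-spline optimizer budget.
#' @param margin Bounding-box margin per side (fraction).
#' @param resample_um Common resolution of the standardized pair.
#' @export
registration_settings <- function(learning_rate = 1.0, min_step = 0.01,
                                  max_iter = 100, relaxation = 0.5,
                                  scales = c(10.0, 1.0, 0.001, 0.001),
                                  bspline_gradient_tol = 1e-5,
                                  bspline_max_iter = 100,
                                  bspline_corrections = 5,
                                  bspline_max_evals = 1024,
                                  bspline_cost_factor = 1e7,
                                  margin = 0.15, resample_um = 3) {
  structure(list(learning_rate = learning_rate, min_step = min_step,
                 max_iter = max_iter, relaxation = relaxation,
                 scales = scales,
                 bspline_gradient_tol = bspline_gradient_tol,
                 bspline_max_iter = bspline_max_iter,
                 bspline_corrections = bspline_corrections,
                 bspline_max_evals = bspline_max_evals,
                 bspline_cost_factor = bspline_cost_factor,
                 margin = margin, resample_um = resample_um),
            class = "registration_settings")
}

#' Standardize a fixed/moving mask pair
#'
#' Aligns centers of mass, crops/pads to a common field of view equal to
#' the larger tissue bounding box plus a margin per side, and resamples both
#' masks to a common isotropic resolution.
#'
#' @param fixed,moving [mask2d()] binary masks.
#' @param settings A [registration_settings()].
#' @return List `fixed`, `moving` ([mask2d()] on the same grid with origin
#'   (0,0)) and `center` (field-of-view center, micrometres).
#' @export
preprocess_mask_pair <- function(fixed, moving, settings = registration_settings()) {
  for (m in list(fixed, moving)) if (sum(m > 0) == 0) {
    nm_abort("EMPTY_MASK", "mask has no foreground")
  }
  bbox_size <- function(m) {
    ax <- mask_axes(m); ps <- mask_pixel_size(m)
    nz <- which(m > 0, arr.ind = TRUE)
    c(diff(range(ax$x[nz[, 2]])) + ps, diff(range(ax$y[nz[, 1]])) + ps)
  }
  fov <- pmax(bbox_size(fixed), bbox_size(moving)) * (1 + 2 * settings$margin)
  sp <- settings$resample_um
  out_dim <- pmax(2L, as.integer(round(fov / sp)))
  std_one <- function(m) {
    com <- mask_com(m)
    shift <- com - out_dim * sp / 2  # output origin (0,0); COM at FOV center
    resample_mask(m, function(p) cbind(p[, 1] + shift[1], p[, 2] + shift[2]),
                  out_dim = out_dim, out_pixel = sp, out_origin = c(0, 0))
  }
  list(fixed = std_one(fixed), moving = std_one(moving),
       center = out_dim * sp / 2)
}

# Forward map of a 2D rigid/similarity transform: fixed -> moving coords.
rigid2d_map <- function(t, pts) {
  ca <- cos(t$angle); sa <- sin(t$angle)
  dx <- pts[, 1] - t$center[1]; dy <- pts[, 2] - t$center[2]
  cbind(t$scale * (ca * dx - sa * dy) + t$center[1] + t$translation[1],
        t$scale * (sa * dx + ca * dy) + t$center[2] + t$translation[2])
}

mean_squares_metric <- function(fixed, moving, map_fun) {
  ax <- mask_axes(fixed)
  pts <- cbind(rep(ax$x, times = length(ax$y)), rep(ax$y, each = length(ax$x)))
  w <- bilinear_sample(moving, map_fun(pts))
  mean((w - as.vector(t(fixed)))^2)
}

#' Rigid or similarity registration of a standardized mask pair
#'
#' Mean-squares metric on the binary masks (linearly interpolated) with
#' regular-step gradient descent: normalized steps in the scaled parameter
#' space, step length halved whenever the gradient direction reverses,
#' terminating at the minimum step size or the iteration cap. Exhausting
#' the cap is reported as `converged = FALSE`, not an error.
#'
#' @param fixed,moving Standardized masks from [preprocess_mask_pair()].
#' @param mode `"euler"` (rotation + translation) or `"similarity"`
#'   (adds isotropic scale).
#' @param settings A [registration_settings()].
#' @return Object of class `rigid_transform` mapping fixed to moving
#'   coordinates: `scale`, `angle` (radians), `translation` (um), `center`,
#'   `metric`, `iterations`, `converged`.
#' @export
register_masks_rigid <- function(fixed, moving, mode = c("similarity", "euler"),
                                 settings = registration_settings()) {
  mode <- match.arg(mode)
  ctr <- c(ncol(fixed), nrow(fixed)) * mask_pixel_size(fixed) / 2
  free <- if (mode == "similarity") c(TRUE, TRUE, TRUE, TRUE) else
    c(FALSE, TRUE, TRUE, TRUE)
  scales <- settings$scales
  if (mode == "euler") scales[1] <- 1  # scale entry unused in euler mode
  p <- c(1, 0, 0, 0)  # (scale, angle, tx, ty)
  ax <- mask_axes(fixed)
  pts <- cbind(rep(ax$x, times = nrow(fixed)), rep(ax$y, each = ncol(fixed)))
  Fv <- as.vector(t(fixed))
  dx <- pts[, 1] - ctr[1]; dy <- pts[, 2] - ctr[2]
  delta <- mask_pixel_size(fixed) / 2

  obj <- function(p) {
    t <- list(scale = p[1], angle = p[2], translation = p[3:4], center = ctr)
    w <- bilinear_sample(moving, rigid2d_map(t, pts))
    mean((w - Fv)^2)
  }
  # analytic mean-squares gradient via the warped image gradient
  grad <- function(p) {
    t <- list(scale = p[1], angle = p[2], translation = p[3:4], center = ctr)
    q <- rigid2d_map(t, pts)
    r <- bilinear_sample(moving, q) - Fv
    mx <- (bilinear_sample(moving, cbind(q[, 1] + delta, q[, 2])) -
             bilinear_sample(moving, cbind(q[, 1] - delta, q[, 2]))) / (2 * delta)
    my <- (bilinear_sample(moving, cbind(q[, 1], q[, 2] + delta)) -
             bilinear_sample(moving, cbind(q[, 1], q[, 2] - delta))) / (2 * delta)
    ca <- cos(p[2]); sa <- sin(p[2])
    rx <- ca * dx - sa * dy; ry <- sa * dx + ca * dy   # R (x - c)
    g <- c(
      if (free[1]) mean(2 * r * (mx * rx + my * ry)) else 0,
      mean(2 * r * (mx * p[1] * (-ry) + my * p[1] * rx)),
      mean(2 * r * mx),
      mean(2 * r * my)
    )
    g
  }

  step <- settings$learning_rate
  gs_prev <- NULL
  iters <- 0L
  converged <- FALSE
  while (iters < settings$max_iter) {
    iters <- iters + 1L
    g <- grad(p)
    gs <- g / scales
    nrm <- sqrt(sum(gs^2))
    if (nrm < 1e-14) { converged <- TRUE; break }
    if (!is.null(gs_prev) && sum(gs * gs_prev) < 0) {
      step <- step * settings$relaxation
    }
    if (step < settings$min_step) { converged <- TRUE; break }
    p <- p - step * gs / nrm
    gs_prev <- gs
  }

  structure(list(mode = mode, scale = p[1], angle = p[2],
                 translation = p[3:4], center = ctr,
                 metric = obj(p), iterations = iters, converged = converged),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform %s> scale %.4f, angle %.3f deg, t = (%.1f, %.1f) um%s\n",
    x$mode, x$scale, x$angle * 180 / pi, x$translation[1], x$translation[2],
    if (!x$converged) " [NON_CONVERGENCE]" else ""))
  invisible(x)
}

# Cubic B-spline tensor basis over [0, L]: 8 coefficients per axis.
bspline_basis <- function(x, L, n_coef = 8) {
  h <- L / (n_coef - 3)
  knots <- h * ((-3):(n_coef))
  splines::splineDesign(knots, pmin(pmax(x, 0), L), ord = 4, outer.ok = TRUE)
}

#' Cubic B-spline refinement of a rigid/similarity registration
#'
#' An 8 x 8 control grid of displacements (added in the moving frame to the
#' rigid map) over the fixed field of view, optimized with L-BFGS-B under
#' the configured budget and an analytic gradient. Initialized at the
#' identity field, as the rigid stage already aligns the pair.
#'
#' @param fixed,moving Standardized masks.
#' @param init A `rigid_transform` from [register_masks_rigid()].
#' @param settings A [registration_settings()].
#' @return Object of class `bspline_transform`: the rigid init, `coef_x`,
#'   `coef_y` (8 x 8, micrometres), `domain`, metric/Dice diagnostics.
#' @export
register_masks_bspline <- function(fixed, moving, init,
                                   settings = registration_settings()) {
  stopifnot(inherits(init, "rigid_transform"))
  ps <- mask_pixel_size(fixed)
  Lx <- ncol(fixed) * ps; Ly <- nrow(fixed) * ps
  ax <- mask_axes(fixed)
  Bx <- bspline_basis(ax$x, Lx)   # nx x 8
  By <- bspline_basis(ax$y, Ly)   # ny x 8
  nx <- ncol(fixed); ny <- nrow(fixed)
  pts0 <- rigid2d_map(init, cbind(rep(ax$x, times = ny), rep(ax$y, each = nx)))
  Fv <- as.vector(t(fixed))
  delta <- ps / 2
  n_eval <- 0L

  warp_vals <- function(cx, cy) {
    ux <- as.vector(t(By %*% t(cx) %*% t(Bx)))  # [iy, ix] flattened x-fastest
    uy <- as.vector(t(By %*% t(cy) %*% t(Bx)))
    cbind(pts0[, 1] + ux, pts0[, 2] + uy)
  }
  obj <- function(par) {
    n_eval <<- n_eval + 1L
    cx <- matrix(par[1:64], 8, 8); cy <- matrix(par[65:128], 8, 8)
    w <- bilinear_sample(moving, warp_vals(cx, cy))
    mean((w - Fv)^2)
  }
  grd <- function(par) {
    cx <- matrix(par[1:64], 8, 8); cy <- matrix(par[65:128], 8, 8)
    p <- warp_vals(cx, cy)
    w <- bilinear_sample(moving, p)
    r <- w - Fv
    mx <- (bilinear_sample(moving, cbind(p[, 1] + delta, p[, 2])) -
             bilinear_sample(moving, cbind(p[, 1] - delta, p[, 2]))) / (2 * delta)
    my <- (bilinear_sample(moving, cbind(p[, 1], p[, 2] + delta)) -
             bilinear_sample(moving, cbind(p[, 1], p[, 2] - delta))) / (2 * delta)
    Wx <- matrix(2 * r * mx / length(r), nrow = ny, byrow = TRUE)
    Wy <- matrix(2 * r * my / length(r), nrow = ny, byrow = TRUE)
    gx <- t(t(By) %*% Wx %*% Bx)  # -> [k (x-basis), l (y-basis)]
    gy <- t(t(By) %*% Wy %*% Bx)
    c(as.vector(gx), as.vector(gy))
  }

  fit <- stats::optim(rep(0, 128), obj, grd, method = "L-BFGS-B",
                      control = list(maxit = settings$bspline_max_iter,
                                     factr = settings$bspline_cost_factor,
                                     pgtol = settings$bspline_gradient_tol,
                                     lmm = settings$bspline_corrections))
  cx <- matrix(fit$par[1:64], 8, 8); cy <- matrix(fit$par[65:128], 8, 8)

  warped_rigid <- bilinear_sample(moving, pts0)
  warped_bspl <- bilinear_sample(moving, warp_vals(cx, cy))
  dice_rigid <- dice_coefficient(matrix(warped_rigid, ny, byrow = TRUE), fixed)
  dice_bspline <- dice_coefficient(matrix(warped_bspl, ny, byrow = TRUE), fixed)

  structure(list(init = init, coef_x = cx, coef_y = cy,
                 domain = c(Lx = Lx, Ly = Ly), metric = fit$value,
                 dice_rigid = dice_rigid, dice_bspline = dice_bspline,
                 n_evals = n_eval, converged = fit$convergence == 0),
            class = "bspline_transform")
}

#' @export
print.bspline_transform <- function(x, ...) {
  cat(sprintf(
    "<bspline_transform> Dice %.4f (rigid) -> %.4f (B-spline), max |u| %.2f um\n",
    x$dice_rigid, x$dice_bspline, max(sqrt(x$coef_x^2 + x$coef_y^2))))
  invisible(x)
}

# Displacement field of a bspline_transform at fixed-frame points.
bspline_displacement <- function(t, pts) {
  Bx <- bspline_basis(pts[, 1], t$domain["Lx"])
  By <- bspline_basis(pts[, 2], t$domain["Ly"])
  cbind(rowSums((Bx %*% t$coef_x) * By), rowSums((Bx %*% t$coef_y) * By))
}

#' Apply a transform chain to points
#'
#' Each element's forward map is applied in order: 2D rigid/similarity
#' transforms map fixed-frame to moving-frame coordinates; B-spline
#' transforms apply their rigid initialization plus the displacement field;
#' 3D landmark fits apply rotation + translation. Points outside a
#' B-spline's domain get zero displacement and are flagged in the
#' `out_of_domain` attribute.
#'
#' @param chain A transform or list of transforms (`rigid_transform`,
#'   `bspline_transform`, `rigid3d`).
#' @param points n x 2 (or n x 3 for `rigid3d`) matrix.
#' @return Mapped points with attribute `out_of_domain`.
#' @export
apply_transform_points <- function(chain, points) {
  if (!is.list(chain) || inherits(chain, c("rigid_transform",
                                           "bspline_transform", "rigid3d"))) {
    chain <- list(chain)
  }
  pts <- as.matrix(points)
  flagged <- rep(FALSE, nrow(pts))
  for (t in chain) {
    if (inherits(t, "rigid_transform")) {
      pts <- rigid2d_map(t, pts)
    } else if (inherits(t, "bspline_transform")) {
      out <- pts[, 1] < 0 | pts[, 1] > t$domain["Lx"] |
        pts[, 2] < 0 | pts[, 2] > t$domain["Ly"]
      u <- bspline_displacement(t, pts)
      u[out, ] <- 0
      flagged <- flagged | out
      pts <- rigid2d_map(t$init, pts) + u
    } else if (inherits(t, "rigid3d")) {
      pts <- t(t$rotation %*% t(pts)) +
        matrix(t$translation, nrow(pts), 3, byrow = TRUE)
    } else {
      nm_abort("INVALID_ARGUMENT", "unknown transform type in chain")
    }
  }
  attr(pts, "out_of_domain") <- flagged
  pts
}

#' Percent size difference implied by a similarity transform
#'
#' `(1 - scale) x 100`: positive when the moving structures are smaller
#' than the fixed ones (e.g. scale 0.915 means 8.5% smaller), negative when
#' larger.
#'
#' @param transform A similarity-mode `rigid_transform`.
#' @return Signed percent.
#' @export
percent_size_difference <- function(transform) {
  if (!inherits(transform, "rigid_transform") || transform$mode != "similarity") {
    nm_abort("MODE_MISMATCH", "size difference requires a similarity transform")
  }
  (1 - transform$scale) * 100
}
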