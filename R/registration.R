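#' B-spline control-point lattice level
#'
#' One resolution level of a cyclic spatiotemporal free-form deformation:
#' a regular spatial grid of control points with cubic B-spline kernels and a
#' periodic cubic B-spline in time.  The displacement evaluated at frame 0 is
#' subtracted, so the reference frame is exactly fixed.
#'
#' @param origin world position (mm) of spatial control point (0, 0, 0)
#' @param spacing control-point spacing (mm), length 3
#' @param dims number of control points per axis (>= 4, or 1 for a flat axis
#'   in 2D mode)
#' @param n_temporal number of periodic temporal control points
#' @param coef optional coefficient vector (default all zero), length
#'   `prod(dims) * n_temporal * 3`, ordered control point (x fastest), then
#'   temporal index, then displacement component
#' @return list describing the level
#' @export
bspline_lattice <- function(origin, spacing, dims, n_temporal = 4, coef = NULL) {
  dims <- as.integer(dims)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (any(spacing <= 0)) abort("lattice spacing must be positive")
  if (any(dims < 1) || any(dims != 1 & dims < 4))
    abort("each lattice axis needs >= 4 control points (or exactly 1 in 2D mode)")
  n <- prod(dims) * n_temporal * 3
  if (is.null(coef)) coef <- numeric(n)
  if (length(coef) != n) abort("coefficient vector has wrong length")
  list(origin = as.numeric(origin), spacing = as.numeric(spacing),
       dims = dims, n_temporal = as.integer(n_temporal),
       coef = as.numeric(coef))
}

# lattice level whose support covers [lower, upper] with margin
level_covering <- function(lower, upper, spacing, n_temporal) {
  dims <- integer(3)
  origin <- numeric(3)
  for (a in 1:3) {
    if (upper[a] - lower[a] < 1e-9 && spacing[a] <= 0) { # flat axis (2D)
      dims[a] <- 1L; origin[a] <- lower[a]; next
    }
    origin[a] <- lower[a] - spacing[a]
    dims[a] <- ceiling((upper[a] - origin[a]) / spacing[a]) + 4L
  }
  bspline_lattice(origin, pmax(spacing, 1e-9), dims, n_temporal)
}

#' Cyclic motion field
#'
#' A fitted multi-level control-point lattice exposing the dense cyclic
#' displacement `u(x, t)` in mm with `u(x, 0) = 0`.
#'
#' @param levels list of [bspline_lattice()] levels, coarse to fine
#' @param n_frames frames per cycle (the temporal period)
#' @return object of class `motion_field`
#' @export
motion_field <- function(levels, n_frames) {
  sp <- t(vapply(levels, function(l) l$spacing, numeric(3)))
  if (nrow(sp) > 1 && any(diff(sp[, 1]) > 1e-9))
    warn("lattice levels are not ordered coarse to fine")
  structure(list(levels = levels, n_frames = as.integer(n_frames)),
            class = "motion_field")
}

#' @export
print.motion_field <- function(x, ...) {
  cat("<motion_field> ", length(x$levels), " level(s), period ",
      x$n_frames, " frames\n", sep = "")
  for (l in x$levels)
    cat("  level: ", paste(l$dims, collapse = "x"), " CPs, spacing ",
        paste(signif(l$spacing, 3), collapse = "x"), " mm, ",
        l$n_temporal, " temporal CPs\n", sep = "")
  invisible(x)
}

#' Evaluate a motion field's displacement
#'
#' Tensor-product cubic B-spline in space and periodic cubic B-spline in
#' time, summed over levels, with the frame-0 evaluation subtracted so that
#' `u(x, 0) = 0` exactly.  Points outside the lattice support receive zero
#' displacement and are flagged.
#'
#' @param motion a [motion_field()]
#' @param points N x 3 matrix of world points (mm)
#' @param t frame time (continuous, periodic)
#' @return N x 3 displacement matrix (mm) with logical attribute `outside`
#' @export
evaluate_displacement <- function(motion, points, t) {
  points <- rbind(points)
  res <- eval_displacement_cpp(motion$levels, points, t, motion$n_frames)
  if (any(res$outside))
    warn(sprintf("%d point(s) outside lattice support; zero displacement used",
                 sum(res$outside)))
  u <- res$u
  attr(u, "outside") <- res$outside
  u
}

#' Normalised mutual information of two images
#'
#' `NMI = (H(A) + H(B)) / H(A, B)` from a joint histogram with `bins`
#' equal-width bins per axis spanning each image's own intensity range.
#' A constant image gives the degenerate value 1.
#'
#' @param a,b numeric arrays on the same grid
#' @param bins histogram bins per axis (>= 8)
#' @return scalar in (1, 2]
#' @export
nmi <- function(a, b, bins = 32) {
  if (!identical(dim(a), dim(b))) abort("images must share a grid")
  if (bins < 8) abort("use at least 8 histogram bins")
  a <- as.numeric(a); b <- as.numeric(b)
  ra <- range(a); rb <- range(b)
  if (diff(ra) < 1e-12 || diff(rb) < 1e-12) return(1)
  ia <- pmin(floor((a - ra[1]) / diff(ra) * bins), bins - 1)
  ib <- pmin(floor((b - rb[1]) / diff(rb) * bins), bins - 1)
  joint <- tabulate(ia * bins + ib + 1, nbins = bins * bins)
  p <- joint / sum(joint)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  pj <- matrix(p, bins, bins)
  (ent(rowSums(pj)) + ent(colSums(pj))) / ent(p)
}

#' Bending-energy and sparsity penalties of a motion field
#'
#' Bending energy is the discretised integral (over the control-point grids,
#' per temporal control point) of squared second spatial differences of the
#' displacement coefficients; sparsity is the smoothed L1 norm
#' `sum(sqrt(c^2 + eps^2) - eps)` over all coefficients.
#'
#' @param motion a [motion_field()]
#' @param eps L1 smoothing epsilon (mm)
#' @return list with `bending_energy` and `sparsity`
#' @export
regularisers <- function(motion, eps = 0.01) {
  regularisers_cpp(motion$levels, eps)
}

#' Registration configuration
#'
#' @param sw sparsity weight (>= 0)
#' @param be bending-energy weight (>= 0)
#' @param bins histogram bins for the similarity metric
#' @param max_iter optimiser iteration cap per level (recycled over levels)
#' @param tol relative objective-change tolerance
#' @param eps smoothed-L1 epsilon (mm)
#' @param level_factors spatial control-point spacing of each level as a
#'   fraction of the image extent, coarse to fine
#' @param n_temporal periodic temporal control points
#' @param grad_thresh image-gradient magnitude below which voxels are skipped
#'   in the similarity gradient
#' @param seed recorded for provenance (the optimiser itself is deterministic)
#' @return object of class `registration_config`
#' @export
registration_config <- function(sw = 1e-4, be = 1e-3, bins = 32,
                                max_iter = c(60, 40), tol = 1e-5, eps = 0.01,
                                level_factors = c(1 / 4, 1 / 8),
                                n_temporal = 4, grad_thresh = 1e-6, seed = 1) {
  if (sw < 0 || be < 0 || !is.finite(sw) || !is.finite(be))
    abort("SW and BE must be finite and >= 0")
  if (bins < 8) abort("bins must be >= 8")
  structure(list(sw = sw, be = be, bins = as.integer(bins),
                 max_iter = max_iter, tol = tol, eps = eps,
                 level_factors = level_factors,
                 n_temporal = as.integer(n_temporal),
                 grad_thresh = grad_thresh, seed = seed),
            class = "registration_config")
}

image_geometry <- function(images) {
  d <- dim(images$frames[[1]])
  list(dims = as.integer(d), spacing = images$spacing, origin = images$origin,
       extent = d * images$spacing)
}

# default lattice levels covering an image series' field of view
levels_for_images <- function(images, config) {
  g <- image_geometry(images)
  lower <- g$origin
  upper <- g$origin + (g$dims - 1) * g$spacing
  lapply(config$level_factors, function(f) {
    sp <- ifelse(g$dims == 1, 0, g$extent * f)
    level_covering(lower, upper, sp, config$n_temporal)
  })
}

#' Register a gated image series
#'
#' Simultaneous cyclic non-rigid registration of all later frames to the
#' first (end-diastolic) frame.  The ED frame is resampled through
#' `id + u(., t)` and compared with each later frame (pull-back), so the
#' fitted displacement directly propagates ED material points.  The
#' objective
#' `sum_t -NMI(frame0(x + u(x, t)), frame_t) + BE * bending + SW * sparsity`
#' is minimised coarse-to-fine over the lattice levels with L-BFGS using the
#' analytic gradient.
#'
#' @param images an [image_series()]
#' @param config a [registration_config()]
#' @param levels optional explicit lattice levels (otherwise derived from
#'   `config$level_factors`)
#' @return a [motion_field()] with attached `log` (objective trace tibble)
#'   and `diagnostics`
#' @export
register_series <- function(images, config = registration_config(),
                            levels = NULL) {
  g <- image_geometry(images)
  F <- length(images$frames)
  if (F < 2) abort("need at least 2 frames")
  if (is.null(levels)) levels <- levels_for_images(images, config)
  moving <- as.numeric(images$frames[[1]])
  fixed <- lapply(images$frames[-1], as.numeric)
  tvals <- seq_len(F - 1)
  maxit <- rep(config$max_iter, length.out = length(levels))

  log_rows <- list()
  diagnostics <- list()
  for (l in seq_along(levels)) {
    np <- length(levels[[l]]$coef)
    cache <- new.env(parent = emptyenv())
    cache$par <- NULL
    evaluate <- function(par) {
      if (!is.null(cache$par) && identical(par, cache$par)) return(cache$res)
      levels[[l]]$coef <<- par
      res <- ffd_objective_cpp(levels, moving, g$dims, g$origin, g$spacing,
                               fixed, tvals, F, config$bins, config$sw,
                               config$be, config$eps, l - 1L,
                               config$grad_thresh)
      if (!is.finite(res$value))
        abort("registration objective became non-finite")
      cache$par <- par
      cache$res <- res
      log_rows[[length(log_rows) + 1L]] <<-
        tibble(level = l, value = res$value,
               bending_energy = res$bending_energy, sparsity = res$sparsity)
      res
    }
    fit <- optim(levels[[l]]$coef,
                 fn = function(p) evaluate(p)$value,
                 gr = function(p) evaluate(p)$grad,
                 method = "L-BFGS-B",
                 control = list(maxit = maxit[l], factr = config$tol / 1e-15,
                                pgtol = 0))
    levels[[l]]$coef <- fit$par
    if (fit$convergence != 0 && fit$convergence != 1)
      warn(sprintf("level %d optimiser stopped early (code %d): %s",
                   l, fit$convergence, fit$message))
    diagnostics[[l]] <- list(value = fit$value, convergence = fit$convergence,
                             counts = fit$counts)
  }
  out <- motion_field(levels, F)
  attr(out, "log") <- dplyr::bind_rows(log_rows)
  attr(out, "diagnostics") <- diagnostics
  attr(out, "config") <- config
  out
}

#' Warp an image through a motion field
#'
#' Pull-back resampling: `out(x) = img(x + u(x, t))` with trilinear
#' interpolation, matching the registration's warping direction.
#'
#' @param img 3D array with `spacing`/`origin` attributes
#' @param motion a [motion_field()]
#' @param t frame time
#' @param spacing,origin grid geometry if not carried as attributes
#' @return warped array with the same geometry attributes
#' @export
warp_image <- function(img, motion, t, spacing = attr(img, "spacing"),
                       origin = attr(img, "origin")) {
  out <- warp_image_cpp(as.numeric(img), as.integer(dim(img)), origin,
                        spacing, motion$levels, t, motion$n_frames)
  out <- array(out, dim(img))
  attr(out, "spacing") <- spacing
  attr(out, "origin") <- origin
  out
}

# sparse 1D cubic B-spline basis matrix: rows = sample coords, cols = CPs
bspline_basis_1d <- function(s, n) {
  if (n == 1) return(Matrix::sparseMatrix(i = seq_along(s), j = rep(1, length(s)),
                                          x = 1, dims = c(length(s), 1)))
  s <- pmin(pmax(s, 0), n - 3 - 1e-9)
  ib <- pmin(floor(s), n - 4)
  u <- s - ib
  w <- cbind((1 - u)^3 / 6,
             (3 * u^3 - 6 * u^2 + 4) / 6,
             (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
             u^3 / 6)
  i <- rep(seq_along(s), 4)
  j <- as.vector(outer(ib, 1:4, `+`))
  Matrix::sparseMatrix(i = i, j = j, x = as.vector(w), dims = c(length(s), n))
}

#' Fit a motion field to an analytic motion
#'
#' Least-squares projection of a known displacement field (for example a
#' [synth_motion()] ground truth) onto a control-point lattice, sampled on a
#' regular space-time grid.  Used to build synthetic image series whose true
#' motion lies exactly in the registration's representation space.
#'
#' @param motion a [synth_motion()] object, or a function `(points, t)`
#'   returning an N x 3 displacement matrix
#' @param levels lattice levels to fit (fitted sequentially on residuals)
#' @param lower,upper corners of the sampling box (mm)
#' @param n_frames temporal period (frames)
#' @param n_samples spatial samples per axis
#' @param ridge Tikhonov regularisation added to the normal equations
#' @return a [motion_field()]
#' @export
fit_motion_field <- function(motion, levels, lower, upper, n_frames,
                             n_samples = 15, ridge = 1e-6) {
  disp_fn <- if (inherits(motion, "ground_truth_motion")) {
    function(p, t) apply_motion(motion, p, t) - p
  } else motion
  xs <- lapply(1:3, function(a) {
    if (upper[a] - lower[a] < 1e-9) lower[a]
    else seq(lower[a], upper[a], length.out = n_samples)
  })
  tset <- seq_len(n_frames - 1)
  grid <- as.matrix(expand.grid(x = xs[[1]], y = xs[[2]], z = xs[[3]]))
  targets <- do.call(rbind, lapply(tset, function(t) disp_fn(grid, t)))

  for (l in seq_along(levels)) {
    lv <- levels[[l]]
    B1 <- lapply(1:3, function(a)
      bspline_basis_1d((xs[[a]] - lv$origin[a]) / lv$spacing[a], lv$dims[a]))
    w0 <- temporal_weights_cpp(0, n_frames, lv$n_temporal)
    Bt <- do.call(rbind, lapply(tset, function(t)
      temporal_weights_cpp(t, n_frames, lv$n_temporal) - w0))
    Bs <- Matrix::kronecker(B1[[3]], Matrix::kronecker(B1[[2]], B1[[1]]))
    D <- Matrix::kronecker(Matrix::Matrix(Bt, sparse = TRUE), Bs)
    A <- Matrix::crossprod(D) + ridge * Matrix::Diagonal(ncol(D))
    resid <- targets
    if (l > 1) {
      partial <- motion_field(levels[seq_len(l - 1)], n_frames)
      pred <- do.call(rbind, lapply(tset, function(t)
        eval_displacement_cpp(partial$levels, grid, t, n_frames)$u))
      resid <- targets - pred
    }
    coef <- sapply(1:3, function(comp)
      as.numeric(Matrix::solve(A, Matrix::crossprod(D, resid[, comp]))))
    levels[[l]]$coef <- as.numeric(coef)
  }
  motion_field(levels, n_frames)
}
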