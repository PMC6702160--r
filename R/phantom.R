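# Synthetic paired-visit DCE phantom with analytic ground truth.
#
# The phantom emulates the study design this package targets: a pre-treatment
# visit and an early-treatment visit of a breast DCE-MRI exam, each with a
# pre-contrast volume and two post-contrast volumes, plus a smooth invertible
# inter-visit deformation (tumour shrinkage) and a controllable change in the
# enhancement curve. Everything needed to validate downstream stages is
# returned as closed-form truth.

#' One DCE-MRI visit: three timepoints on a shared grid
#'
#' @param vol_t0,vol_t1,vol_t2 [volume_grid()]s: pre-contrast and two
#'   post-contrast volumes on the same grid.
#' @param times numeric length-3, acquisition times in minutes, strictly
#'   increasing (default 0, 2.5, 7.5).
#' @return An object of class `dce_study`.
#' @export
dce_study <- function(vol_t0, vol_t1, vol_t2, times = c(0, 2.5, 7.5)) {
  stopifnot(is_volume_grid(vol_t0), is_volume_grid(vol_t1),
            is_volume_grid(vol_t2))
  if (!same_grid(vol_t0, vol_t1) || !same_grid(vol_t0, vol_t2))
    stop("all three volumes must share one grid")
  times <- as.numeric(times)
  if (length(times) != 3L || any(diff(times) <= 0))
    stop("times must be 3 strictly increasing values (minutes)")
  structure(list(vol_t0 = vol_t0, vol_t1 = vol_t1, vol_t2 = vol_t2,
                 times = times), class = "dce_study")
}

#' @export
print.dce_study <- function(x, ...) {
  d <- dim(x$vol_t0$values)
  cat(sprintf("<dce_study> %d x %d x %d voxels, times %s min\n",
              d[1], d[2], d[3], paste(x$times, collapse = ", ")))
  invisible(x)
}

#' Specification of a synthetic paired-visit phantom
#'
#' Defines an ellipsoidal tumour with a smooth (sigmoid) boundary embedded in
#' uniform background tissue, three-timepoint enhancement curves per tissue
#' class for both visits, a forward (pre to early) deformation composed of an
#' affine map about the tumour centre plus optional Gaussian-bump
#' perturbations, a smooth multiplicative bias field, and additive Gaussian
#' noise.
#'
#' Defaults describe a mildly responding tumour: a uniform 0.92 linear
#' contraction (volume ratio about 0.78) with one 1.5 mm bump, and post-
#' contrast enhancement reduced by roughly 10 percent at the early visit.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing_mm numeric length-3, voxel size (> 0).
#' @param tumor_center world coordinates (mm) of the ellipsoid centre;
#'   defaults to the grid centre.
#' @param tumor_radii ellipsoid semi-axes in mm.
#' @param edge_width_mm width of the sigmoid tumour boundary (mm).
#' @param background_curve intensities of background tissue at t0, t1, t2.
#' @param tumor_curve intensities of tumour tissue at t0, t1, t2
#'   (pre-treatment visit).
#' @param tumor_curve_early tumour curve at the early-treatment visit; the
#'   difference from `tumor_curve` is the intended kinetic change.
#' @param background_curve_early background curve at the early visit.
#' @param times acquisition times (minutes).
#' @param affine 3x3 matrix: linear part of the forward deformation about
#'   `tumor_center`.
#' @param shift_mm translation of the forward deformation (mm).
#' @param bumps list of Gaussian perturbations, each
#'   `list(center =, width_mm =, amplitude_mm =)` with `amplitude_mm` a
#'   3-vector; displacement added as `a * exp(-|x - c|^2 / (2 w^2))`.
#' @param noise_sd additive Gaussian noise sd (intensity units).
#' @param bias_amplitude log-scale amplitude of the multiplicative bias
#'   field (0.2 gives roughly +-20 percent).
#' @param bias_scale_mm correlation length of the bias field.
#' @param seed integer RNG seed; same spec + seed gives bit-identical output.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48, 48, 48),
                         spacing_mm = c(1, 1, 1),
                         tumor_center = NULL,
                         tumor_radii = c(10, 8, 7),
                         edge_width_mm = 1.5,
                         background_curve = c(100, 104, 106),
                         tumor_curve = c(100, 220, 190),
                         tumor_curve_early = c(100, 196, 175),
                         background_curve_early = background_curve,
                         times = c(0, 2.5, 7.5),
                         affine = diag(0.92, 3),
                         shift_mm = c(0, 0, 0),
                         bumps = list(list(center = NULL, width_mm = 6,
                                           amplitude_mm = c(1.5, 0, 0))),
                         noise_sd = 1,
                         bias_amplitude = 0.05,
                         bias_scale_mm = 24,
                         seed = 1L) {
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(spacing_mm <= 0)) stop("spacing_mm must be > 0 per axis")
  grid_shape <- rep_len(as.integer(grid_shape), 3L)
  if (is.null(tumor_center))
    tumor_center <- (grid_shape - 1) * spacing_mm / 2
  bumps <- lapply(bumps, function(b) {
    if (is.null(b$center)) b$center <- tumor_center
    b
  })
  spec <- structure(list(
    grid_shape = grid_shape, spacing_mm = spacing_mm,
    tumor_center = as.numeric(tumor_center),
    tumor_radii = rep_len(as.numeric(tumor_radii), 3L),
    edge_width_mm = edge_width_mm,
    background_curve = as.numeric(background_curve),
    tumor_curve = as.numeric(tumor_curve),
    tumor_curve_early = as.numeric(tumor_curve_early),
    background_curve_early = as.numeric(background_curve_early),
    times = as.numeric(times),
    affine = affine, shift_mm = as.numeric(shift_mm), bumps = bumps,
    noise_sd = noise_sd, bias_amplitude = bias_amplitude,
    bias_scale_mm = bias_scale_mm, seed = as.integer(seed)),
    class = "phantom_spec")
  spec
}

# Analytic forward displacement u(x) = T(x) - x at world points (n x 3).
phantom_displacement_at <- function(spec, pts) {
  rel <- sweep(pts, 2, spec$tumor_center)
  u <- rel %*% (t(spec$affine) - diag(3))
  u <- sweep(u, 2, spec$shift_mm, "+")
  for (b in spec$bumps) {
    dd <- sweep(pts, 2, b$center)
    g <- exp(-rowSums(dd^2) / (2 * b$width_mm^2))
    u <- u + outer(g, b$amplitude_mm)
  }
  u
}

# Analytic spatial gradient dT/dx at world points: n x 9 matrix
# (column-major 3x3 per row).
phantom_gradT_at <- function(spec, pts) {
  n <- nrow(pts)
  G <- matrix(rep(as.vector(spec$affine), each = n), nrow = n)
  for (b in spec$bumps) {
    dd <- sweep(pts, 2, b$center)
    g <- exp(-rowSums(dd^2) / (2 * b$width_mm^2))
    # d/dx_j [a_i g(x)] = -a_i (x_j - c_j) / w^2 * g
    for (j in 1:3) for (i in 1:3) {
      G[, (j - 1) * 3 + i] <- G[, (j - 1) * 3 + i] -
        b$amplitude_mm[i] * dd[, j] / b$width_mm^2 * g
    }
  }
  G
}

# Smooth tumour membership weight in [0, 1] at world points.
phantom_tumor_weight <- function(spec, pts) {
  rel <- sweep(pts, 2, spec$tumor_center)
  ed <- sqrt(rowSums(sweep(rel, 2, spec$tumor_radii, "/")^2))
  r_eff <- exp(mean(log(spec$tumor_radii)))
  stats::plogis((1 - ed) * r_eff / spec$edge_width_mm)
}

phantom_geometry <- function(spec) {
  volume_grid(array(0, dim = spec$grid_shape), spec$spacing_mm, c(0, 0, 0))
}

# Smooth multiplicative bias field: smoothed white noise, unit mean.
make_bias_field <- function(dim3, spacing, amplitude, scale_mm) {
  if (amplitude <= 0) return(array(1, dim = dim3))
  w <- array(stats::rnorm(prod(dim3)), dim = dim3)
  s <- gauss_smooth3(w, scale_mm, spacing)
  s <- s - mean(s)
  sdv <- stats::sd(as.vector(s))
  if (sdv > 0) s <- s / sdv
  f <- exp(amplitude * s)
  f / mean(f)
}

#' Generate a synthetic paired-visit DCE study with ground truth
#'
#' Builds the pre-treatment visit analytically on the grid, then synthesises
#' the early-treatment visit by evaluating the tissue model at the preimage
#' of each voxel under the forward deformation (obtained by fixed-point
#' inversion of the displacement), applying the early-visit enhancement
#' curves, and finally degrading both visits with a multiplicative bias field
#' and additive Gaussian noise.
#'
#' The generator refuses deformations whose analytic Jacobian is not
#' strictly positive at every grid point, so the returned truth is always an
#' invertible, orientation-preserving map.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `pre` and `early` ([dce_study()]s) and
#'   `truth`, itself a list with `true_displacement`
#'   ([displacement_field()], pre grid), `true_stretches` (n-voxel x 3 matrix
#'   of sorted principal stretches from the analytic transform gradient),
#'   `true_jacobian` (3D array, analytic `det` of the transform gradient),
#'   `tumor_mask` ([volume_grid()], binary), `true_kinetic_delta` (list of
#'   3D arrays: intended per-voxel change in PE, WIS, WOS, SER), and
#'   `tumor_weight` (3D array, smooth membership).
#' @export
make_study_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- phantom_geometry(spec)
  pts <- grid_world_coords(geom)
  d <- spec$grid_shape

  # Analytic Jacobian of the forward map must be positive everywhere.
  G <- phantom_gradT_at(spec, pts)
  detG <- G[, 1] * (G[, 5] * G[, 9] - G[, 8] * G[, 6]) -
    G[, 4] * (G[, 2] * G[, 9] - G[, 8] * G[, 3]) +
    G[, 7] * (G[, 2] * G[, 6] - G[, 5] * G[, 3])
  if (min(detG) <= 0)
    stop(sprintf(
      "deformation spec rejected: analytic Jacobian is nonpositive (min %.4g)",
      min(detG)))

  u <- phantom_displacement_at(spec, pts)
  Tfield <- displacement_field(array(u, dim = c(d, 3L)),
                               spec$spacing_mm, geom$origin)

  w_pre <- phantom_tumor_weight(spec, pts)
  blend <- function(w, bg, tum) bg + w * (tum - bg)

  pre_vals <- lapply(1:3, function(t)
    array(blend(w_pre, spec$background_curve[t], spec$tumor_curve[t]),
          dim = d))

  # Early visit: evaluate tissue model at T^{-1}(y), analytically, using the
  # fixed-point inverse of the forward displacement.
  if (length(spec$bumps) == 0) {
    Ainv <- solve(spec$affine)
    rel <- sweep(sweep(pts, 2, spec$shift_mm), 2, spec$tumor_center)
    pre_pts <- sweep(rel %*% t(Ainv), 2, spec$tumor_center, "+")
  } else {
    Vinv <- invert_field(Tfield)
    pre_pts <- pts + field_u_matrix(Vinv)
  }
  w_early <- phantom_tumor_weight(spec, pre_pts)
  early_vals <- lapply(1:3, function(t)
    array(blend(w_early, spec$background_curve_early[t],
                spec$tumor_curve_early[t]), dim = d))

  # Degrade both visits: independent bias fields and noise draws.
  degraded <- with_seed(spec$seed, {
    lapply(list(pre_vals, early_vals), function(vols) {
      bias <- make_bias_field(d, spec$spacing_mm, spec$bias_amplitude,
                              spec$bias_scale_mm)
      lapply(vols, function(v) {
        v <- v * bias
        if (spec$noise_sd > 0)
          v <- v + array(stats::rnorm(prod(d), sd = spec$noise_sd), dim = d)
        v
      })
    })
  })

  as_study <- function(vols) {
    dce_study(volume_grid(vols[[1]], spec$spacing_mm, geom$origin),
              volume_grid(vols[[2]], spec$spacing_mm, geom$origin),
              volume_grid(vols[[3]], spec$spacing_mm, geom$origin),
              times = spec$times)
  }

  # Truth: principal stretches from the analytic transform gradient.
  lam <- sqrt_eigvals_sym3(gram3(G))

  # Intended kinetic change: features of the clean early curve minus features
  # of the clean pre curve, per voxel (tissue class is material, so both are
  # evaluated at the pre-treatment position).
  kin_pre <- curve_kinetics(
    lapply(1:3, function(t) blend(w_pre, spec$background_curve[t],
                                  spec$tumor_curve[t])), spec$times)
  kin_early <- curve_kinetics(
    lapply(1:3, function(t) blend(w_pre, spec$background_curve_early[t],
                                  spec$tumor_curve_early[t])), spec$times)
  delta <- lapply(c("PE", "WIS", "WOS", "SER"), function(f)
    array(kin_early[[f]] - kin_pre[[f]], dim = d))
  names(delta) <- c("PE", "WIS", "WOS", "SER")

  truth <- list(
    true_displacement = Tfield,
    true_stretches = lam,
    true_jacobian = array(detG, dim = d),
    tumor_mask = volume_grid(array(as.numeric(w_pre > 0.5), dim = d),
                             spec$spacing_mm, geom$origin),
    tumor_weight = array(w_pre, dim = d),
    true_kinetic_delta = delta)

  list(pre = as_study(degraded[[1]]), early = as_study(degraded[[2]]),
       truth = truth)
}
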