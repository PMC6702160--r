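# Displacement-field container, construction helpers, warping and inversion.

#' Per-voxel displacement field
#'
#' Stores the displacement `u(x)` (mm, world coordinates) on the fixed
#' (pre-treatment) grid. The transform convention is `T(x) = x + u(x)`,
#' mapping fixed-grid world coordinates into the moving (early-treatment)
#' image.
#'
#' @param u numeric 4D array `[nx, ny, nz, 3]`, displacement in mm.
#' @param spacing,origin grid geometry of the fixed image.
#' @param flagged optional logical: field returned by a run that failed its
#'   quality gate (e.g. registration non-convergence).
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(u, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                               flagged = FALSE) {
  u <- as.array(u)
  if (length(dim(u)) != 4L || dim(u)[4] != 3L)
    stop("u must be a 4D array with 3 components in the 4th dimension")
  if (any(!is.finite(u)))
    stop("displacement field must be finite everywhere")
  structure(list(u = u, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), flagged = isTRUE(flagged)),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  d <- dim(x$u)
  mg <- sqrt(x$u[, , , 1]^2 + x$u[, , , 2]^2 + x$u[, , , 3]^2)
  cat(sprintf("<displacement_field> %d x %d x %d voxels, |u| mean %.3g mm, max %.3g mm%s\n",
              d[1], d[2], d[3], mean(mg), max(mg),
              if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

field_grid_dim <- function(T) dim(T$u)[1:3]

# n x 3 matrix of displacement vectors in voxel (column-major) order.
field_u_matrix <- function(T) {
  d <- dim(T$u)
  matrix(T$u, nrow = prod(d[1:3]), ncol = 3L)
}

#' Identity displacement field on a grid
#'
#' @param vol a [volume_grid()] supplying geometry.
#' @return A zero [displacement_field()].
#' @export
identity_field <- function(vol) {
  d <- dim(vol$values)
  displacement_field(array(0, dim = c(d, 3L)), vol$spacing, vol$origin)
}

#' Displacement field of an affine map about a centre
#'
#' Builds `T(x) = centre + A (x - centre) + shift`, i.e.
#' `u(x) = (A - I)(x - centre) + shift`, sampled on the grid of `vol`.
#'
#' @param vol a [volume_grid()] supplying geometry.
#' @param A 3x3 matrix.
#' @param shift translation in mm (length 3).
#' @param centre fixed point of the linear part, world mm (length 3).
#' @return A [displacement_field()].
#' @export
affine_field <- function(vol, A, shift = c(0, 0, 0), centre = c(0, 0, 0)) {
  stopifnot(is_volume_grid(vol), all(dim(A) == c(3, 3)))
  pts <- grid_world_coords(vol)
  rel <- sweep(pts, 2, centre)
  u <- rel %*% (t(A) - diag(3))
  u <- sweep(u, 2, shift, "+")
  d <- dim(vol$values)
  displacement_field(array(u, dim = c(d, 3L)), vol$spacing, vol$origin)
}

# Evaluate T(x) = x + u(x) for fixed-grid world points; u sampled trilinearly.
apply_transform <- function(T, points) {
  fake_vol <- list(spacing = T$spacing, origin = T$origin)
  idx <- world_to_index(points, fake_vol)
  out <- points
  for (c in 1:3)
    out[, c] <- points[, c] + interp3(T$u[, , , c], idx, "linear")$values
  out
}

#' Warp a volume or mask through a displacement field
#'
#' Computes `output(x) = input(T(x))` on the fixed grid, sampling the input
#' at the mapped world coordinates. Masks should use nearest-neighbour
#' interpolation, which keeps them binary.
#'
#' @param vol a [volume_grid()] to sample (the moving image).
#' @param T a [displacement_field()] on the fixed grid.
#' @param interp `"linear"` or `"nearest"`.
#' @return A `volume_grid` on the fixed grid, with attribute `"inside"`
#'   (logical array) marking voxels whose mapped position fell inside the
#'   moving image extent.
#' @export
warp <- function(vol, T, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  stopifnot(is_volume_grid(vol), inherits(T, "displacement_field"))
  d <- field_grid_dim(T)
  fixed_geom <- volume_grid(array(0, dim = d), T$spacing, T$origin)
  pts <- apply_transform(T, grid_world_coords(fixed_geom))
  smp <- interp3(vol$values, world_to_index(pts, vol), interp)
  out <- volume_grid(array(smp$values, dim = d), T$spacing, T$origin)
  attr(out, "inside") <- array(smp$inside, dim = d)
  out
}

# Fixed-point inversion of a displacement field: finds v with
# v(y) = -u(y + v(y)), so that (x + u)(y + v(y)) returns to y.
# Iterates v_{k+1}(y) = -u(y + v_k(y)); tolerance in voxels.
invert_field <- function(T, tol_voxel = 1e-3, max_iter = 50L) {
  d <- field_grid_dim(T)
  geom <- volume_grid(array(0, dim = d), T$spacing, T$origin)
  y <- grid_world_coords(geom)
  v <- matrix(0, nrow = nrow(y), ncol = 3L)
  fake_vol <- list(spacing = T$spacing, origin = T$origin)
  tol_mm <- tol_voxel * min(T$spacing)
  for (it in seq_len(max_iter)) {
    idx <- world_to_index(y + v, fake_vol)
    vn <- v
    for (c in 1:3)
      vn[, c] <- -interp3(T$u[, , , c], idx, "linear")$values
    delta <- max(abs(vn - v))
    v <- vn
    if (delta < tol_mm) break
  }
  displacement_field(array(v, dim = c(d, 3L)), T$spacing, T$origin)
}
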