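# Core image containers and low-level grid numerics shared by every module.

#' 3D scalar image on a regular grid
#'
#' The basic imaging unit: a 3D array of intensities plus voxel spacing and
#' world origin (millimetres). Voxel centre `i` (1-based index) sits at world
#' coordinate `origin + (i - 1) * spacing` along each axis.
#'
#' @param values numeric 3D array of voxel intensities.
#' @param spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @param origin numeric length-3, world coordinate of the first voxel centre.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("values must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite numbers")
  if (any(!is.finite(values)))
    stop("values must be finite")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

is_volume_grid <- function(x) inherits(x, "volume_grid")

same_grid <- function(a, b, tol = 1e-8) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

# World-coordinate arrays of every voxel centre, as an n x 3 matrix
# (column-major voxel order, matching as.vector on the value array).
grid_world_coords <- function(vol) {
  d <- dim(vol$values)
  i <- rep(seq_len(d[1]), times = d[2] * d[3])
  j <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
  k <- rep(seq_len(d[3]), each = d[1] * d[2])
  cbind(vol$origin[1] + (i - 1) * vol$spacing[1],
        vol$origin[2] + (j - 1) * vol$spacing[2],
        vol$origin[3] + (k - 1) * vol$spacing[3])
}

# Continuous 1-based voxel index of world points (n x 3) on a grid.
world_to_index <- function(points, vol) {
  cbind((points[, 1] - vol$origin[1]) / vol$spacing[1] + 1,
        (points[, 2] - vol$origin[2]) / vol$spacing[2] + 1,
        (points[, 3] - vol$origin[3]) / vol$spacing[3] + 1)
}

# Trilinear / nearest-neighbour sampling of a 3D array at continuous 1-based
# voxel indices (n x 3 matrix). Out-of-extent positions clamp to the nearest
# edge voxel; `inside` records which points fell within the voxel-centre hull.
interp3 <- function(values, idx, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  d <- dim(values)
  x <- idx[, 1]; y <- idx[, 2]; z <- idx[, 3]
  inside <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  x <- pmin.int(pmax.int(x, 1), d[1])
  y <- pmin.int(pmax.int(y, 1), d[2])
  z <- pmin.int(pmax.int(z, 1), d[3])
  if (interp == "nearest") {
    lin <- (round(z) - 1) * d[1] * d[2] + (round(y) - 1) * d[1] + round(x)
    return(list(values = values[lin], inside = inside))
  }
  x0 <- pmin.int(floor(x), d[1] - 1L); y0 <- pmin.int(floor(y), d[2] - 1L)
  z0 <- pmin.int(floor(z), d[3] - 1L)
  if (d[1] == 1L) x0 <- rep(1, length(x))
  if (d[2] == 1L) y0 <- rep(1, length(y))
  if (d[3] == 1L) z0 <- rep(1, length(z))
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  sx <- if (d[1] > 1L) 1L else 0L
  sy <- if (d[2] > 1L) 1L else 0L
  sz <- if (d[3] > 1L) 1L else 0L
  nxy <- d[1] * d[2]
  base <- (z0 - 1) * nxy + (y0 - 1) * d[1] + x0
  v000 <- values[base]
  v100 <- values[base + sx]
  v010 <- values[base + sy * d[1]]
  v110 <- values[base + sx + sy * d[1]]
  v001 <- values[base + sz * nxy]
  v101 <- values[base + sx + sz * nxy]
  v011 <- values[base + sy * d[1] + sz * nxy]
  v111 <- values[base + sx + sy * d[1] + sz * nxy]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  list(values = c0 * (1 - fz) + c1 * fz, inside = inside)
}

# Separable Gaussian smoothing of a 3D array with a physical sigma (mm).
# Truncated discrete kernel (4 sigma), renormalised near the edges so a
# constant array is reproduced exactly.
gauss_smooth3 <- function(values, sigma_mm, spacing) {
  d <- dim(values)
  out <- values
  for (ax in 1:3) {
    sig_vox <- sigma_mm / spacing[ax]
    if (sig_vox <= 0) next
    n <- d[ax]
    if (n == 1L) next
    pos <- seq_len(n)
    K <- exp(-outer(pos, pos, "-")^2 / (2 * sig_vox^2))
    K[abs(outer(pos, pos, "-")) > ceiling(4 * sig_vox)] <- 0
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(out, perm)
    m <- matrix(a, nrow = n)
    a <- array(K %*% m, dim = d[perm])
    out <- aperm(a, order(perm))
  }
  out
}

# Central-difference gradient of a 3D array in world units (per mm);
# one-sided differences on boundary faces. Returns list of three arrays.
grad3 <- function(values, spacing) {
  d <- dim(values)
  g <- vector("list", 3)
  for (ax in 1:3) {
    n <- d[ax]
    ga <- array(0, dim = d)
    if (n >= 2L) {
      idx <- function(lo, hi) {
        sel <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
        sel[[ax]] <- seq.int(lo, hi)
        sel
      }
      slice <- function(sel) do.call(`[`, c(list(values), sel, list(drop = FALSE)))
      assign_slice <- function(arr, sel, val) {
        do.call(`[<-`, c(list(arr), sel, list(val)))
      }
      if (n >= 3L) {
        interior <- idx(2L, n - 1L)
        ga <- assign_slice(ga, interior,
                           (slice(idx(3L, n)) - slice(idx(1L, n - 2L))) /
                             (2 * spacing[ax]))
      }
      ga <- assign_slice(ga, idx(1L, 1L),
                         (slice(idx(2L, 2L)) - slice(idx(1L, 1L))) / spacing[ax])
      ga <- assign_slice(ga, idx(n, n),
                         (slice(idx(n, n)) - slice(idx(n - 1L, n - 1L))) / spacing[ax])
    }
    g[[ax]] <- ga
  }
  g
}

# Spacing-aware 7-point discrete Laplacian with replicated edges.
laplacian3 <- function(values, spacing) {
  d <- dim(values)
  out <- array(0, dim = d)
  for (ax in 1:3) {
    n <- d[ax]
    if (n < 2L) next
    sel <- function(lo, hi) {
      s <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      s[[ax]] <- pmin.int(pmax.int(seq.int(lo, hi), 1L), n)
      s
    }
    sl <- function(s) do.call(`[`, c(list(values), s, list(drop = FALSE)))
    out <- out + (sl(sel(2L, n + 1L)) - 2 * values + sl(sel(0L, n - 1L))) /
      spacing[ax]^2
  }
  out
}

#' Resample a volume to a new voxel spacing
#'
#' The output grid keeps the input origin and covers the same physical
#' extent; voxel centres follow `origin + index * spacing`. Samples falling
#' outside the input extent take the nearest edge value.
#'
#' @param vol a [volume_grid()].
#' @param target_spacing_mm numeric length-3 (or scalar), new spacing in mm.
#' @param interp `"linear"` (default) or `"nearest"`.
#' @return A resampled `volume_grid`.
#' @export
resample <- function(vol, target_spacing_mm, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  stopifnot(is_volume_grid(vol))
  sp <- rep_len(as.numeric(target_spacing_mm), 3L)
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("target_spacing_mm must be positive")
  d <- dim(vol$values)
  extent <- (d - 1) * vol$spacing
  nd <- pmax(1L, as.integer(floor(extent / sp + 1e-9)) + 1L)
  out <- volume_grid(array(0, dim = nd), spacing = sp, origin = vol$origin)
  pts <- grid_world_coords(out)
  smp <- interp3(vol$values, world_to_index(pts, vol), interp)
  out$values <- array(smp$values, dim = nd)
  out
}
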