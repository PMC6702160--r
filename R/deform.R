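# Voxel-wise deformation features from a displacement field: transform
# gradient, principal stretches, and the Jacobian / anisotropic deformation
# index (ADI) / slab-rod index (SRI) maps.

#' Per-voxel scalar feature map
#'
#' A scalar field restricted to a support mask (typically the pre-treatment
#' functional tumour volume), with a validity flag per voxel so degenerate
#' voxels are flagged rather than silently dropped.
#'
#' @param name feature name, e.g. `"Jacobian"`, `"ADI"`, `"SRI"`, `"PE"`,
#'   `"PRM_PE"`.
#' @param values 3D array; `NA` outside the mask.
#' @param mask logical 3D array: the support.
#' @param valid logical 3D array: mask voxels whose value is trustworthy.
#' @param spacing,origin grid geometry.
#' @return An object of class `feature_map`.
#' @export
feature_map <- function(name, values, mask, valid = mask,
                        spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(identical(dim(values), dim(mask)),
            identical(dim(values), dim(valid)))
  values[!mask] <- NA_real_
  structure(list(name = name, values = values, mask = mask,
                 valid = valid & mask, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  v <- x$values[x$valid]
  cat(sprintf("<feature_map> %s: %d mask voxels (%d valid), range [%.4g, %.4g]\n",
              x$name, sum(x$mask), sum(x$valid),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

# Coerce a mask argument (NULL, volume_grid, or array) to a logical array.
as_mask_array <- function(mask, d) {
  if (is.null(mask)) return(array(TRUE, dim = d))
  if (is_volume_grid(mask)) mask <- mask$values
  if (!identical(dim(mask), as.integer(d)) && !identical(dim(mask), d))
    stopifnot(identical(as.integer(dim(mask)), as.integer(d)))
  array(mask > 0.5 | mask == TRUE, dim = d) & TRUE
}

#' Spatial gradient of a transform T(x) = x + u(x)
#'
#' Central differences in world (mm) units on interior voxels, one-sided on
#' boundary faces; boundary voxels are flagged. The result stores the full
#' 3x3 matrix `dT_i/dx_j = I + du_i/dx_j` per voxel.
#'
#' @param T a [displacement_field()].
#' @return An object of class `gradient_field`: per-voxel 3x3 matrices as an
#'   `n x 9` matrix `G` (column-major within each voxel, so column
#'   `(j-1)*3 + i` holds `dT_i/dx_j`), plus a logical `boundary` flag.
#' @export
displacement_gradient <- function(T) {
  stopifnot(inherits(T, "displacement_field"))
  d <- field_grid_dim(T)
  n <- prod(d)
  G <- matrix(0, nrow = n, ncol = 9L)
  for (i in 1:3) {
    gi <- grad3(T$u[, , , i], T$spacing)
    for (j in 1:3)
      G[, (j - 1L) * 3L + i] <- as.vector(gi[[j]]) + as.numeric(i == j)
  }
  boundary <- array(FALSE, dim = d)
  for (ax in 1:3) {
    if (d[ax] < 3L) { boundary[] <- TRUE; next }
    sel <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    sel[[ax]] <- c(1L, d[ax])
    boundary <- do.call(`[<-`, c(list(boundary), sel, list(TRUE)))
  }
  structure(list(G = G, dim = d, spacing = T$spacing, origin = T$origin,
                 boundary = as.vector(boundary)),
            class = "gradient_field")
}

# Per-voxel Gram matrix C = G G^T of n x 9 column-major 3x3 matrices,
# returned as n x 6 (c11, c22, c33, c12, c13, c23).
gram3 <- function(G) {
  g <- function(i, j) G[, (j - 1L) * 3L + i]
  cbind(g(1,1)^2 + g(1,2)^2 + g(1,3)^2,
        g(2,1)^2 + g(2,2)^2 + g(2,3)^2,
        g(3,1)^2 + g(3,2)^2 + g(3,3)^2,
        g(1,1)*g(2,1) + g(1,2)*g(2,2) + g(1,3)*g(2,3),
        g(1,1)*g(3,1) + g(1,2)*g(3,2) + g(1,3)*g(3,3),
        g(2,1)*g(3,1) + g(2,2)*g(3,2) + g(2,3)*g(3,3))
}

# Per-voxel determinant of n x 9 column-major 3x3 matrices.
det3 <- function(G) {
  g <- function(i, j) G[, (j - 1L) * 3L + i]
  g(1,1) * (g(2,2) * g(3,3) - g(2,3) * g(3,2)) -
    g(1,2) * (g(2,1) * g(3,3) - g(2,3) * g(3,1)) +
    g(1,3) * (g(2,1) * g(3,2) - g(2,2) * g(3,1))
}

# Eigenvalues of symmetric 3x3 matrices (n x 6 packed), descending, by the
# trigonometric closed form; numerically safe for repeated eigenvalues.
eigvals_sym3 <- function(C) {
  c11 <- C[, 1]; c22 <- C[, 2]; c33 <- C[, 3]
  c12 <- C[, 4]; c13 <- C[, 5]; c23 <- C[, 6]
  q <- (c11 + c22 + c33) / 3
  p2 <- (c11 - q)^2 + (c22 - q)^2 + (c33 - q)^2 +
    2 * (c12^2 + c13^2 + c23^2)
  p <- sqrt(pmax(p2 / 6, 0))
  e1 <- e2 <- e3 <- q
  nz <- p > 0
  if (any(nz)) {
    b11 <- (c11[nz] - q[nz]) / p[nz]; b22 <- (c22[nz] - q[nz]) / p[nz]
    b33 <- (c33[nz] - q[nz]) / p[nz]
    b12 <- c12[nz] / p[nz]; b13 <- c13[nz] / p[nz]; b23 <- c23[nz] / p[nz]
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    phi <- acos(pmin(pmax(detB / 2, -1), 1)) / 3
    e1[nz] <- q[nz] + 2 * p[nz] * cos(phi)
    e3[nz] <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    e2[nz] <- 3 * q[nz] - e1[nz] - e3[nz]
  }
  m <- cbind(e1, e2, e3)
  dimnames(m) <- NULL
  m
}

# Sorted principal stretches (singular values of G) via sqrt of the Gram
# eigenvalues; input n x 6 packed symmetric matrices.
sqrt_eigvals_sym3 <- function(C) {
  ev <- eigvals_sym3(C)
  lam <- sqrt(pmax(ev, 0))
  colnames(lam) <- NULL
  lam
}

#' Principal stretches of the transform per voxel
#'
#' The default (`stretch_mode = "singular"`) takes the principal stretches
#' as the singular values of the transform gradient, so their product equals
#' `det` of the gradient (the local volume ratio). The alternative mode
#' `"squared"` returns the raw eigenvalues of `G G^T` (the squared
#' stretches), available for comparison.
#'
#' @param gradT a [displacement_gradient()] result.
#' @param stretch_mode `"singular"` (default) or `"squared"`.
#' @return An object of class `stretch_map`: `lambda` is an `n x 3` matrix
#'   sorted descending per voxel; `valid` flags voxels with finite,
#'   positive stretches.
#' @export
principal_stretches <- function(gradT, stretch_mode = c("singular", "squared")) {
  stretch_mode <- match.arg(stretch_mode)
  stopifnot(inherits(gradT, "gradient_field"))
  finite <- rowSums(!is.finite(gradT$G)) == 0L
  G <- gradT$G
  G[!finite, ] <- diag(3)  # placeholder; flagged invalid below
  ev <- eigvals_sym3(gram3(G))
  lam <- if (stretch_mode == "singular") sqrt(pmax(ev, 0)) else ev
  valid <- finite & lam[, 3] > 0
  structure(list(lambda = lam, valid = valid, dim = gradT$dim,
                 spacing = gradT$spacing, origin = gradT$origin,
                 boundary = gradT$boundary, mode = stretch_mode),
            class = "stretch_map")
}

stretch_geometry <- function(s) list(dim = s$dim, spacing = s$spacing,
                                     origin = s$origin)

#' Jacobian (local volume ratio) map
#'
#' `J = lambda1 * lambda2 * lambda3`, the early/pre volume ratio per voxel:
#' values below 1 indicate local contraction, above 1 local expansion. When
#' the transform gradient is supplied the product is cross-checked against
#' its determinant and disagreeing voxels are flagged.
#'
#' @param stretches a [principal_stretches()] result.
#' @param mask optional support mask (array or [volume_grid()]); defaults to
#'   the full grid.
#' @param gradT optional [displacement_gradient()] for the determinant
#'   cross-check (tolerance 1e-6 relative on orientation-preserving voxels).
#' @return A [feature_map()] named `"Jacobian"`.
#' @export
jacobian_map <- function(stretches, mask = NULL, gradT = NULL) {
  stopifnot(inherits(stretches, "stretch_map"))
  d <- stretches$dim
  J <- stretches$lambda[, 1] * stretches$lambda[, 2] * stretches$lambda[, 3]
  valid <- stretches$valid
  if (!is.null(gradT)) {
    dt <- det3(gradT$G)
    pos <- dt > 0
    bad <- pos & abs(J - dt) > 1e-6 * pmax(1, abs(dt))
    valid <- valid & !bad
  }
  m <- as_mask_array(mask, d)
  feature_map("Jacobian", array(J, dim = d), m, array(valid, dim = d),
              stretches$spacing, stretches$origin)
}

#' Anisotropic deformation index (ADI) map
#'
#' `ADI = sqrt(((l1 - l2)/l2)^2 + ((l2 - l3)/l3)^2)`: zero for isotropic
#' (shape-preserving) deformation, growing without bound with anisotropy.
#' Denominator stretches are clamped below at 1e-8 and clamped voxels are
#' flagged.
#'
#' @inheritParams jacobian_map
#' @return A [feature_map()] named `"ADI"`.
#' @export
adi_map <- function(stretches, mask = NULL) {
  stopifnot(inherits(stretches, "stretch_map"))
  d <- stretches$dim
  eps <- 1e-8
  l1 <- stretches$lambda[, 1]
  l2 <- pmax(stretches$lambda[, 2], eps)
  l3 <- pmax(stretches$lambda[, 3], eps)
  clamped <- stretches$lambda[, 2] < eps | stretches$lambda[, 3] < eps
  adi <- sqrt(((l1 - l2) / l2)^2 + ((l2 - l3) / l3)^2)
  m <- as_mask_array(mask, d)
  feature_map("ADI", array(adi, dim = d), m,
              array(stretches$valid & !clamped, dim = d),
              stretches$spacing, stretches$origin)
}

#' Slab-rod index (SRI) map
#'
#' `SRI = atan(l3 (l1 - l2) / (l2 (l2 - l3))) / (pi/2)`, in `[0, 1]`:
#' values near 1 mean the anisotropic deformation acts along a single axis
#' (rod-like, `l1 > l2 = l3`); values near 0 mean it acts along two axes
#' (slab-like, `l1 = l2 > l3`). Degenerate cases: a vanishing denominator
#' with positive numerator takes the limiting value 1; a fully isotropic
#' voxel (`l1 = l2 = l3`) is 0 by convention and flagged isotropic.
#'
#' @inheritParams jacobian_map
#' @param tol relative tolerance used to detect the degenerate numerator /
#'   denominator cases.
#' @return A [feature_map()] named `"SRI"`, with attribute `"isotropic"`
#'   (logical array).
#' @export
sri_map <- function(stretches, mask = NULL, tol = 1e-9) {
  stopifnot(inherits(stretches, "stretch_map"))
  d <- stretches$dim
  l1 <- stretches$lambda[, 1]; l2 <- stretches$lambda[, 2]
  l3 <- stretches$lambda[, 3]
  scale <- pmax(l1, 1)
  num <- l3 * (l1 - l2)
  den <- l2 * (l2 - l3)
  iso <- (l1 - l3) <= tol * scale
  sri <- rep(0, length(l1))
  deg <- !iso & den <= tol * scale^2
  gen <- !iso & !deg
  sri[deg] <- ifelse(num[deg] > 0, 1, 0)
  sri[gen] <- atan(num[gen] / den[gen]) / (pi / 2)
  sri <- pmin(pmax(sri, 0), 1)
  m <- as_mask_array(mask, d)
  fm <- feature_map("SRI", array(sri, dim = d), m,
                    array(stretches$valid, dim = d),
                    stretches$spacing, stretches$origin)
  attr(fm, "isotropic") <- array(iso, dim = d)
  fm
}
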