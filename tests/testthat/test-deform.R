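# Transform gradient, principal stretches, and the Jacobian/ADI/SRI maps.

test_that("the gradient of a zero displacement is the identity matrix", {
  Tf <- identity_field(volume_grid(array(0, dim = c(8, 8, 8))))
  gT <- displacement_gradient(Tf)
  expect_lt(max(abs(sweep(gT$G, 2, as.vector(diag(3))))), 1e-14)
})

test_that("central differences are exact on linear fields, spacing-aware", {
  A <- matrix(c(0.1, 0.02, 0, -0.03, -0.05, 0.01, 0, 0.04, 0.08), 3, 3)
  for (sp in list(c(1, 1, 1), c(1, 1, 3))) {
    vol <- volume_grid(array(0, dim = c(10, 10, 10)), spacing = sp)
    Tf <- affine_field(vol, diag(3) + A)
    gT <- displacement_gradient(Tf)
    interior <- !gT$boundary
    dev <- sweep(gT$G[interior, ], 2, as.vector(diag(3) + A))
    expect_lt(max(abs(dev)), 1e-10)
  }
})

test_that("principal stretches handle identity, rotations, and diagonal maps", {
  mk_grad <- function(M) {
    structure(list(G = matrix(as.vector(M), 1, 9), dim = c(1L, 1L, 1L),
                   spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   boundary = FALSE), class = "gradient_field")
  }
  expect_equal(principal_stretches(mk_grad(diag(3)))$lambda[1, ], c(1, 1, 1))
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(principal_stretches(mk_grad(R))$lambda[1, ], c(1, 1, 1),
               tolerance = 1e-12)
  expect_equal(principal_stretches(mk_grad(diag(c(2, 0.5, 1))))$lambda[1, ],
               c(2, 1, 0.5), tolerance = 1e-12)
  # squared mode returns the raw Gram eigenvalues
  expect_equal(principal_stretches(mk_grad(diag(c(2, 0.5, 1))),
                                   "squared")$lambda[1, ],
               c(4, 1, 0.25), tolerance = 1e-12)
})

test_that("stretches from the closed form match per-voxel SVD to 1e-8", {
  set.seed(13)
  d <- c(16, 16, 16)
  u <- array(0, dim = c(d, 3))
  for (c in 1:3)
    u[, , , c] <- gauss_smooth3_test(array(rnorm(prod(d)), dim = d), 3) * 6
  gT <- displacement_gradient(displacement_field(u))
  lam <- principal_stretches(gT)$lambda
  sv <- t(apply(gT$G, 1, function(g) svd(matrix(g, 3, 3))$d))
  expect_lt(max(abs(lam - sv)), 1e-8)
})

test_that("Jacobian, ADI and SRI reproduce their analytic plug-in values", {
  expect_equal(jacobian_map(stretch_fixture(c(1, 1, 1)))$values[1], 1)
  expect_equal(jacobian_map(stretch_fixture(c(2, 1, 1)))$values[1], 2)
  expect_equal(adi_map(stretch_fixture(c(1, 1, 1)))$values[1], 0)
  expect_equal(adi_map(stretch_fixture(c(2, 1, 1)))$values[1], 1)
  expect_equal(adi_map(stretch_fixture(c(3, 2, 1)))$values[1],
               sqrt(0.25 + 1), tolerance = 1e-12)
  expect_equal(sri_map(stretch_fixture(c(2, 1, 1)))$values[1], 1)
  expect_equal(sri_map(stretch_fixture(c(2, 2, 1)))$values[1], 0)
  expect_equal(sri_map(stretch_fixture(c(3, 2, 1)))$values[1],
               atan(0.5) / (pi / 2), tolerance = 1e-12)
  # isotropic voxels are flagged as such
  fm <- sri_map(stretch_fixture(c(1.3, 1.3, 1.3)))
  expect_equal(fm$values[1], 0)
  expect_true(attr(fm, "isotropic")[1])
})

test_that("a uniform affine field yields constant maps at their closed-form values", {
  A <- diag(c(1.2, 0.9, 0.8))
  vol <- volume_grid(array(0, dim = c(10, 10, 10)))
  gT <- displacement_gradient(affine_field(vol, A))
  s <- principal_stretches(gT)
  J <- jacobian_map(s, gradT = gT)
  adi <- adi_map(s)
  sri <- sri_map(s)
  interior <- array(!gT$boundary, dim = c(10, 10, 10))
  expect_lt(max(abs(J$values[interior] - 0.864)), 1e-6)
  sv <- sort(svd(A)$d, decreasing = TRUE)
  adi_true <- sqrt(((sv[1] - sv[2]) / sv[2])^2 + ((sv[2] - sv[3]) / sv[3])^2)
  sri_true <- atan(sv[3] * (sv[1] - sv[2]) / (sv[2] * (sv[2] - sv[3]))) / (pi / 2)
  expect_lt(max(abs(adi$values[interior] - adi_true)), 1e-6)
  expect_lt(max(abs(sri$values[interior] - sri_true)), 1e-6)
})

test_that("SRI stays in [0,1] and ADI nonnegative on random smooth fields", {
  set.seed(17)
  for (rep in 1:3) {
    d <- c(12, 12, 12)
    u <- array(0, dim = c(d, 3))
    for (c in 1:3)
      u[, , , c] <- gauss_smooth3_test(array(rnorm(prod(d)), dim = d), 2.5) * 5
    s <- principal_stretches(displacement_gradient(displacement_field(u)))
    adi <- adi_map(s); sri <- sri_map(s)
    expect_true(all(adi$values[adi$valid] >= 0))
    expect_true(all(sri$values >= 0 & sri$values <= 1))
    # sorted descending everywhere
    expect_true(all(s$lambda[, 1] >= s$lambda[, 2] - 1e-12))
    expect_true(all(s$lambda[, 2] >= s$lambda[, 3] - 1e-12))
  }
})

test_that("Jacobian disagreement with the determinant flags voxels", {
  vol <- volume_grid(array(0, dim = c(8, 8, 8)))
  gT <- displacement_gradient(affine_field(vol, diag(c(1.1, 1, 0.95))))
  s <- principal_stretches(gT)
  J <- jacobian_map(s, gradT = gT)
  interior <- !gT$boundary
  expect_true(all(J$valid[array(interior, dim = c(8, 8, 8))]))
})
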