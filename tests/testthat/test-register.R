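# Attributes, mutual saliency, the registration cost, warping, and identity
# recovery of the baseline registration (phantom recovery runs in the
# acceptance suite).

test_that("attributes of a constant image are exactly zero after standardisation", {
  v <- volume_grid(array(5, dim = c(12, 12, 12)))
  af <- compute_attributes(v, 2)
  expect_equal(max(abs(af$A)), 0)
  expect_error(compute_attributes(v, 2, mask = array(FALSE, dim = c(12, 12, 12))),
               "mask")
})

test_that("attribute computation is deterministic and ramp derivatives are analytic", {
  ramp <- volume_grid(array(rep(0:15, 256), dim = c(16, 16, 16)))
  a1 <- compute_attributes(ramp, 1)
  a2 <- compute_attributes(ramp, 1)
  expect_identical(a1$A, a2$A)
  # beyond the smoothing kernel's reach (4 sigma) the gradient magnitude is
  # constant (= slope 1) and the Laplacian vanishes
  gm <- a1$raw[[2]][6:11, 6:11, 6:11]
  lap <- a1$raw[[3]][6:11, 6:11, 6:11]
  expect_lt(diff(range(gm)), 1e-9)
  expect_lt(max(abs(lap)), 1e-9)
  # normalisation holds over the mask
  for (j in seq_len(ncol(a1$A))) {
    if (sd(a1$A[, j]) > 0) {
      expect_lt(abs(mean(a1$A[, j])), 1e-6)
      expect_lt(abs(sd(a1$A[, j]) - 1), 1e-6)
    }
  }
})

test_that("mutual saliency ranks distinctive matches above uniform texture", {
  v <- array(100, dim = c(24, 24, 24))
  v[12, 12, 12] <- 300
  img <- volume_grid(v)
  af <- compute_attributes(img, 2)
  Tid <- identity_field(img)
  w_blob <- mutual_saliency(af, af, Tid, c(12, 12, 12))
  w_uniform <- mutual_saliency(af, af, Tid, c(5, 5, 5))
  expect_gt(w_blob, w_uniform)
  expect_true(w_blob <= 1 && w_uniform >= 0)
})

test_that("identical constant images give saliency one half; off-image maps give zero", {
  img <- volume_grid(array(5, dim = c(16, 16, 16)))
  af <- compute_attributes(img, 2)
  expect_equal(mutual_saliency(af, af, identity_field(img), c(8, 8, 8)), 0.5,
               tolerance = 1e-5)
  T_out <- displacement_field(array(1000, dim = c(16, 16, 16, 3)))
  expect_equal(mutual_saliency(af, af, T_out, c(8, 8, 8)), 0)
})

test_that("the cost is zero for self-matching and scales quadratically", {
  sp <- quiet_spec(grid = c(16, 16, 16))
  pair <- make_study_pair(sp)
  af <- compute_attributes(pair$pre$vol_t1, 2)
  expect_equal(evaluate_cost(af, af, identity_field(pair$pre$vol_t1)), 0)
  # doubling all attribute differences quadruples the data term
  am <- af
  am$A <- af$A + 0.5
  am2 <- af
  am2$A <- af$A + 1.0
  Tid <- identity_field(pair$pre$vol_t1)
  sal <- rep(1, prod(dim(pair$pre$vol_t1$values)))
  e1 <- evaluate_cost(af, am, Tid, saliency = sal)
  e2 <- evaluate_cost(af, am2, Tid, saliency = sal)
  expect_equal(e2 / e1, 4, tolerance = 1e-9)
  expect_gte(e1, 0)
})

test_that("the cost is non-decreasing with growing misalignment", {
  sp <- quiet_spec(grid = c(20, 20, 20), affine = diag(3), bumps = list())
  pair <- make_study_pair(sp)
  vol <- pair$pre$vol_t1
  af <- compute_attributes(vol, 2)
  costs <- vapply(0:5, function(s)
    evaluate_cost(af, af, affine_field(vol, diag(3), shift = c(s, 0, 0))),
    numeric(1))
  expect_equal(costs[1], 0)
  expect_true(all(diff(costs) >= -1e-9))
})

test_that("warping through the identity field is the identity operator", {
  set.seed(31)
  v <- volume_grid(array(runif(1000), dim = c(10, 10, 10)))
  w <- warp(v, identity_field(v))
  expect_equal(w$values, v$values, tolerance = 1e-12)
})

test_that("a one-voxel translation moves a delta by one voxel", {
  v <- array(0, dim = c(9, 9, 9)); v[5, 5, 5] <- 1
  img <- volume_grid(v)
  Tsh <- affine_field(img, diag(3), shift = c(1, 0, 0))
  w <- warp(img, Tsh)
  expect_equal(w$values[4, 5, 5], 1)
  expect_equal(sum(w$values), 1)
})

test_that("nearest-neighbour warping keeps masks binary", {
  set.seed(32)
  m <- volume_grid(array(as.numeric(runif(1728) > 0.6), dim = c(12, 12, 12)))
  u <- array(rnorm(1728 * 3, 0, 1.5), dim = c(12, 12, 12, 3))
  w <- warp(m, displacement_field(u), "nearest")
  expect_true(all(w$values %in% c(0, 1)))
})

test_that("registering an image to itself returns a near-zero field", {
  sp <- quiet_spec(grid = c(20, 20, 20))
  pair <- make_study_pair(sp)
  Tf <- register_baseline(pair$pre$vol_t1, pair$pre$vol_t1,
                          list(max_iter = 30L))
  u <- field_u_test(Tf)
  expect_lt(mean(sqrt(rowSums(u^2))), 0.1)
  expect_false(Tf$flagged)
})

test_that("registration reduces the cost relative to the identity field", {
  sp <- quiet_spec(grid = c(20, 20, 20), affine = diag(3), bumps = list(),
                   shift_mm = c(1.5, 0, 0),
                   tumor_curve_early = c(100, 220, 190))
  pair <- make_study_pair(sp)
  Tf <- register_baseline(pair$pre$vol_t1, pair$early$vol_t1,
                          list(max_iter = 40L))
  expect_lte(attr(Tf, "cost"), attr(Tf, "cost_identity"))
})
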