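# Kinetic feature maps, FTV segmentation, response maps, aggregates.

study_from_values <- function(v0, v1, v2, times = c(0, 2.5, 7.5)) {
  d <- c(2, 2, 2)
  dce_study(volume_grid(array(v0, dim = d)), volume_grid(array(v1, dim = d)),
            volume_grid(array(v2, dim = d)), times)
}

test_that("kinetic plug-in values for a wash-out curve", {
  st <- study_from_values(100, 200, 150)
  k <- kinetic_maps(st)
  expect_equal(k$PE$values[1], 1.0)
  expect_equal(k$t_PE[1], 2.5)
  expect_equal(k$WIS$values[1], 0.4)
  expect_equal(k$WOS$values[1], -10)
  expect_equal(k$SER$values[1], 0.5)
})

test_that("kinetic plug-in values for a persistent-enhancement curve", {
  st <- study_from_values(100, 150, 200)
  k <- kinetic_maps(st)
  expect_equal(k$PE$values[1], 1.0)
  expect_equal(k$t_PE[1], 7.5)
  expect_equal(k$WIS$values[1], 1 / 7.5)
  expect_equal(k$WOS$values[1], 0)   # peak at t2 branch
  expect_equal(k$SER$values[1], 2.0)
  # the alternative wash-out denominator uses t2 - t1
  k2 <- kinetic_maps(st, wos_denominator = "t2_minus_t1")
  expect_equal(k2$WOS$values[1], 50 / 5)
})

test_that("flat curves are flagged with zeroed features", {
  st <- study_from_values(100, 100, 100)
  k <- kinetic_maps(st)
  expect_equal(k$PE$values[1], 0)
  expect_equal(k$WIS$values[1], 0)
  expect_equal(k$SER$values[1], 0)
  expect_true(k$flags$no_enhancement[1])
  expect_true(is.na(k$t_PE[1]))
})

test_that("SER equals 1 whenever the two post-contrast frames agree", {
  st <- study_from_values(100, 180, 180)
  expect_equal(kinetic_maps(st)$SER$values[1], 1)
})

test_that("nonpositive baseline voxels are flagged, not propagated", {
  st <- study_from_values(c(100, 0, rep(100, 6)), 200, 150)
  k <- kinetic_maps(st)
  expect_true(k$flags$nonpositive_t0[2])
  expect_equal(k$PE$values[2], 0)
  expect_false(k$PE$valid[2])
  expect_equal(k$PE$values[1], 1.0)
})

test_that("FTV segmentation isolates the enhancing ellipsoid exactly", {
  sp <- quiet_spec(grid = c(28, 28, 28), affine = diag(3), bumps = list(),
                   edge_width_mm = 0.25)
  pair <- make_study_pair(sp)
  # baseline is 100 in both classes, so PE is linear in the tumour weight w:
  # PE(w) = (4 + 116 w) / 100, and the PE threshold matching the w = 0.5
  # membership boundary is 0.62
  ftv <- segment_ftv(pair$pre, pe_min = 0.62)
  truth <- pair$truth$tumor_mask$values > 0.5
  expect_equal(ftv$values > 0.5, truth)
  expect_equal(attr(ftv, "volume_cm3"), sum(truth) / 1000)
})

test_that("an unreachable PE threshold yields an empty mask with a warning", {
  sp <- quiet_spec(grid = c(16, 16, 16))
  pair <- make_study_pair(sp)
  expect_warning(ftv <- segment_ftv(pair$pre, pe_min = 99), "empty")
  expect_true(attr(ftv, "empty"))
  expect_equal(sum(ftv$values), 0)
})

test_that("keep-largest retains only the bigger of two enhancing blobs", {
  d <- c(24, 24, 24)
  v0 <- array(100, dim = d)
  v1 <- array(100, dim = d)
  # big blob radius 4 at (8,8,8); small blob radius 2 at (18,18,18)
  pts <- grid_coords_test(d)
  big <- matrix(sqrt(rowSums(sweep(pts, 2, c(7, 7, 7))^2)) <= 4, d[1])
  small <- sqrt(rowSums(sweep(pts, 2, c(17, 17, 17))^2)) <= 2
  v1[sqrt(rowSums(sweep(pts, 2, c(7, 7, 7))^2)) <= 4] <- 250
  v1[small] <- 250
  st <- dce_study(volume_grid(v0), volume_grid(array(v1, dim = d)),
                  volume_grid(array(v1 * 0.9, dim = d)))
  ftv <- segment_ftv(st, pe_min = 0.7)
  expect_true(sum(ftv$values) > 0)
  sel <- which(ftv$values > 0.5)
  expect_true(all(sel %in% which(
    sqrt(rowSums(sweep(pts, 2, c(7, 7, 7))^2)) <= 4)))
  expect_false(any(ftv$values[array(small, dim = d)] > 0.5))
})

test_that("response maps vanish for identical studies under the identity transform", {
  sp <- quiet_spec(grid = c(20, 20, 20))
  pair <- make_study_pair(sp)
  st <- pair$pre
  Tid <- identity_field(st$vol_t0)
  m <- pair$truth$tumor_mask$values > 0.5
  gT <- displacement_gradient(Tid)
  J <- jacobian_map(principal_stretches(gT), m, gT)
  kin <- kinetic_maps(st, m)
  kin_full <- kinetic_maps(st)
  for (f in c("PE", "WIS", "WOS", "SER")) {
    prm <- prm_map(kin[[f]], kin_full[[f]], Tid, J)
    expect_equal(max(abs(prm$values[prm$valid])), 0)
  }
})

test_that("response-map arithmetic follows its defining identity", {
  d <- c(2, 2, 2)
  mk <- function(vals, name) feature_map(name, array(vals, dim = d),
                                         array(TRUE, dim = d))
  Tid <- identity_field(volume_grid(array(0, dim = d)))
  # J = 1, F_early = 1.5, F_pre = 1.0 -> 0.5
  p1 <- prm_map(mk(1.0, "PE"), mk(1.5, "PE"), Tid, mk(1, "Jacobian"))
  expect_equal(unique(as.vector(p1$values)), 0.5)
  # J = 0.5, F_early = 2.0, F_pre = 1.0 -> 0.0
  p2 <- prm_map(mk(1.0, "PE"), mk(2.0, "PE"), Tid, mk(0.5, "Jacobian"))
  expect_equal(unique(as.vector(p2$values)), 0)
  expect_equal(p2$name, "PRM_PE")
})

test_that("voxels mapped outside the early image are flagged invalid", {
  d <- c(6, 6, 6)
  mk <- function(vals, name) feature_map(name, array(vals, dim = d),
                                         array(TRUE, dim = d))
  Tout <- displacement_field(array(100, dim = c(d, 3)))
  p <- prm_map(mk(1, "PE"), mk(2, "PE"), Tout, mk(1, "Jacobian"))
  expect_false(any(p$valid))
})

test_that("a uniform PE increase is recovered by the mean response map", {
  # same baseline everywhere and equal post-contrast offsets in both tissue
  # classes make the intended PE change exactly uniform (+0.2)
  sp <- quiet_spec(grid = c(20, 20, 20), affine = diag(3), bumps = list(),
                   background_curve = c(100, 150, 120),
                   background_curve_early = c(100, 170, 120),
                   tumor_curve = c(100, 200, 150),
                   tumor_curve_early = c(100, 220, 150))
  pair <- make_study_pair(sp)
  expect_lt(max(abs(pair$truth$true_kinetic_delta$PE - 0.2)), 1e-12)
  Tid <- identity_field(pair$pre$vol_t0)
  m <- pair$truth$tumor_mask$values > 0.5
  gT <- displacement_gradient(Tid)
  J <- jacobian_map(principal_stretches(gT), m, gT)
  prm <- prm_map(kinetic_maps(pair$pre, m)$PE, kinetic_maps(pair$early)$PE,
                 Tid, J)
  expect_lt(abs(mean(prm$values[prm$valid]) - 0.2) / 0.2, 0.02)
})

test_that("aggregate features follow the relative-change definition", {
  sp <- quiet_spec(grid = c(16, 16, 16))
  pair <- make_study_pair(sp)
  kin <- kinetic_maps(pair$pre, pair$truth$tumor_mask$values > 0.5)
  # doubled means: d_f = (4 - 2)/4 = 0.5 via direct construction
  d <- c(2, 2, 2)
  mk_set <- function(v) {
    st <- dce_study(volume_grid(array(100, dim = d)),
                    volume_grid(array(100 * (1 + v), dim = d)),
                    volume_grid(array(100 * (1 + v / 2), dim = d)))
    kinetic_maps(st)
  }
  agg <- aggregate_features(mk_set(2), mk_set(4), 1, 1)
  expect_equal(unname(agg["d_PE"]), 0.5)
  # identical visits: all zero changes, unit volume ratio, exactly 5 values
  agg0 <- aggregate_features(kin, kin, 2, 2)
  expect_length(agg0, 5)
  expect_equal(unname(agg0["ftv_ratio"]), 1)
  expect_equal(unname(agg0[c("d_PE", "d_WIS", "d_WOS", "d_SER")]),
               rep(0, 4))
  expect_error(aggregate_features(kin, kin, 0, 1), "ftv1")
})
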