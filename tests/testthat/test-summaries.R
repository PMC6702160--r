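# Heterogeneity indices and the 7 + 5 per-tumour feature vector.

test_that("fraction_increased counts strictly positive change", {
  expect_equal(fraction_increased(map_fixture(c(0.2, -0.1, 0.0, 0.5))), 0.5)
  expect_equal(fraction_increased(map_fixture(c(-1, -0.2, -3))), 0)
  expect_equal(fraction_increased(map_fixture(c(1.2, 0.8, 1.5, 1.0)),
                                  threshold = 1), 0.5)
  expect_warning(
    out <- fraction_increased(feature_map("x", array(1, dim = c(1, 1, 1)),
                                          array(TRUE, dim = c(1, 1, 1)),
                                          array(FALSE, dim = c(1, 1, 1)))),
    "no valid")
  expect_true(is.na(out))
})

test_that("fraction_increased is invariant under increasing transforms", {
  set.seed(21)
  v <- rnorm(200)
  f <- function(x) exp(x) + x^3
  expect_equal(fraction_increased(map_fixture(v), 0.3),
               fraction_increased(map_fixture(f(v)), f(0.3)))
})

test_that("entropy follows the printed (sign-kept) convention", {
  expect_equal(entropy_index(map_fixture(rep(3.3, 50))), 0)
  # two equally occupied bins
  expect_equal(entropy_index(map_fixture(rep(c(0, 1), 20)), n_bins = 2), -1)
  # uniform over 4 bins
  expect_equal(entropy_index(map_fixture(rep(c(0, 1, 2, 3), 25)),
                             n_bins = 4), -2)
  expect_equal(entropy_index(map_fixture(rep(c(0, 1), 20)), n_bins = 2,
                             convention = "shannon"), 1)
  expect_error(entropy_index(map_fixture(1:5), n_bins = 0), "n_bins")
})

test_that("entropy is bounded by the uniform histogram", {
  set.seed(22)
  for (n_bins in c(4, 16, 32)) {
    v <- runif(500)
    h <- entropy_index(map_fixture(v), n_bins = n_bins)
    expect_gte(h, -log2(n_bins) - 1e-12)
    expect_lte(h, 0)
  }
})

test_that("summarize_tumor emits exactly 7 voxel-wise and 5 aggregate values", {
  set.seed(23)
  maps <- list()
  for (nm in c("Jacobian", "ADI", "SRI", "PRM_PE", "PRM_WIS", "PRM_WOS",
               "PRM_SER"))
    maps[[nm]] <- map_fixture(rnorm(40), nm)
  agg <- c(ftv_ratio = 0.8, d_PE = -0.1, d_WIS = 0.2, d_WOS = 0.05,
           d_SER = 0)
  s <- summarize_tumor(maps, agg, 10, 8)
  expect_length(s$voxelwise, 7)
  expect_length(s$aggregate, 5)
  expect_true(all(s$voxelwise[startsWith(names(s$voxelwise), "frac")] >= 0 &
                    s$voxelwise[startsWith(names(s$voxelwise), "frac")] <= 1))
  expect_error(summarize_tumor(maps[-3], agg, 10, 8), "SRI")
})

test_that("summaries are invariant to voxel order", {
  set.seed(24)
  v <- rnorm(60)
  perm <- sample(60)
  maps1 <- maps2 <- list()
  for (nm in c("Jacobian", "ADI", "SRI", "PRM_PE", "PRM_WIS", "PRM_WOS",
               "PRM_SER")) {
    maps1[[nm]] <- map_fixture(v, nm)
    maps2[[nm]] <- map_fixture(v[perm], nm)
  }
  agg <- c(ftv_ratio = 1, d_PE = 0, d_WIS = 0, d_WOS = 0, d_SER = 0)
  expect_equal(summarize_tumor(maps1, agg, 5, 5)$voxelwise,
               summarize_tumor(maps2, agg, 5, 5)$voxelwise)
})

test_that("a no-change phantom collapses every index to zero", {
  sp <- quiet_spec(grid = c(18, 18, 18), affine = diag(3), bumps = list(),
                   tumor_curve_early = c(100, 220, 190),
                   background_curve_early = c(100, 104, 106))
  pair <- make_study_pair(sp)
  m <- pair$truth$tumor_mask$values > 0.5
  Tid <- identity_field(pair$pre$vol_t0)
  gT <- displacement_gradient(Tid)
  s <- principal_stretches(gT)
  J <- jacobian_map(s, m, gT)
  maps <- list(Jacobian = J, ADI = adi_map(s, m), SRI = sri_map(s, m))
  kin <- kinetic_maps(pair$pre, m)
  kin_full <- kinetic_maps(pair$early)
  for (f in c("PE", "WIS", "WOS", "SER"))
    maps[[paste0("PRM_", f)]] <- prm_map(kin[[f]], kin_full[[f]], Tid, J)
  agg <- aggregate_features(kin, kinetic_maps(pair$early, m), 1, 1)
  summ <- summarize_tumor(maps, agg, 1, 1)
  expect_equal(unname(summ$voxelwise[c("frac_jacobian", "frac_PRM_PE",
                                       "frac_PRM_WIS", "frac_PRM_WOS",
                                       "frac_PRM_SER", "entropy_ADI",
                                       "entropy_SRI")]),
               rep(0, 7))
})
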