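# Model fitting, performance metrics, CV selection, consensus refit, risk
# stratification.

baseline_covs <- c("age", "race", "hormone_status", "ftv2_cm3")

test_that("AUC and C-statistic reproduce their worked examples", {
  expect_equal(performance(c(0.9, 0.8, 0.2, 0.1),
                           data.frame(pcr = c(1, 1, 0, 0)), "logistic"), 1)
  expect_equal(performance(c(0.9, 0.2, 0.15, 0.1),
                           data.frame(pcr = c(1, 0, 1, 0)), "logistic"), 0.75)
  expect_equal(performance(c(3, 2, 1),
                           data.frame(rfs_time = c(1, 2, 3),
                                      rfs_event = c(1, 1, 1)), "cox"), 1)
  expect_warning(out <- performance(c(1, 2), data.frame(pcr = c(1, 1)),
                                    "logistic"), "single")
  expect_true(is.na(out))
})

test_that("rank-based metrics match brute-force enumeration with ties", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    tb <- random_outcome_table(n, "logistic")
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # ties likely
    if (length(unique(tb$pcr)) == 2)
      expect_identical(performance(s, tb, "logistic"), auc_brute(tb$pcr, s))
    tb2 <- random_outcome_table(n, "cox")
    s2 <- sample(seq(0, 2, 0.25), n, replace = TRUE)
    bf <- cindex_brute(tb2$rfs_time, tb2$rfs_event, s2)
    if (!is.na(bf))
      expect_identical(performance(s2, tb2, "cox"), bf)
  }
})

test_that("a null covariate's coefficient lands within 2 SE of zero and AIC is definitional", {
  tb <- simulate_cohort(cohort_spec(n_patients = 400L, seed = 43L))
  ft <- fit_outcome_model(tb, c(baseline_covs, "d_PE"), "logistic")
  expect_lt(abs(ft$coefficients[["d_PE"]]), 2 * ft$se[["d_PE"]])
  expect_equal(ft$aic, 2 * ft$k - 2 * ft$loglik)
  ftc <- fit_outcome_model(tb, c(baseline_covs, "d_PE"), "cox")
  expect_equal(ftc$aic, 2 * ftc$k - 2 * ftc$loglik)
  expect_lt(abs(ftc$coefficients[["d_PE"]]), 2 * ftc$se[["d_PE"]])
})

test_that("missing pCR rows are excluded from logistic fits only", {
  tb <- simulate_cohort(cohort_spec(n_patients = 120L,
                                    pcr_missing_rate = 0.1, seed = 44L))
  ft <- fit_outcome_model(tb, baseline_covs, "logistic")
  expect_equal(ft$n, sum(!is.na(tb$pcr)))
  ftc <- fit_outcome_model(tb, baseline_covs, "cox")
  expect_equal(ftc$n, nrow(tb))
})

test_that("cv_select builds one nested model per candidate and is reproducible", {
  tb <- simulate_cohort(cohort_spec(n_patients = 150L, seed = 45L))
  rep1 <- cv_select(tb, baseline_covs, feature_names()[1:7], "logistic",
                    k = 5, seed = 9L)
  for (f in rep1$folds)
    expect_length(f$nested_aic, 7)
  rep2 <- cv_select(tb, baseline_covs, feature_names()[1:7], "logistic",
                    k = 5, seed = 9L)
  expect_identical(rep1$selection_counts, rep2$selection_counts)
  expect_identical(rep1$test_metrics, rep2$test_metrics)
  # candidate order does not matter under a fixed seed
  rep3 <- cv_select(tb, baseline_covs, rev(feature_names()[1:7]), "logistic",
                    k = 5, seed = 9L)
  expect_identical(rep1$selection_counts, rep3$selection_counts)
  # folds partition the analyzed rows
  expect_equal(sort(unlist(lapply(1:5, function(i)
    which(rep1$fold_assignment == i)))), seq_len(nrow(tb)))
})

test_that("an informative feature is selected in most folds and refit with the right sign", {
  cs <- cohort_spec(n_patients = 400L,
                    pcr_coefficients = c(frac_jacobian = log(3)), seed = 21L)
  tb <- simulate_cohort(cs)
  rep_cv <- cv_select(tb, baseline_covs, feature_names()[1:7], "logistic",
                      k = 5, seed = 5L)
  expect_gte(rep_cv$selection_counts[["frac_jacobian"]], 4)
  cons <- consensus_refit(rep_cv, tb, baseline_covs, "logistic")
  expect_true("frac_jacobian" %in% cons$consensus)
  expect_gt(cons$full$coefficients[["frac_jacobian"]], 0)
  expect_gte(cons$lrt_stat, 0)
})

test_that("consensus membership follows the 4-of-5 rule and degenerates gracefully", {
  tb <- simulate_cohort(cohort_spec(n_patients = 150L, seed = 46L))
  fake_report <- function(counts) {
    structure(list(selection_counts = counts, k = 5L), class = "cv_report")
  }
  r4 <- consensus_refit(fake_report(c(d_PE = 4L, d_WIS = 3L)), tb,
                        baseline_covs, "logistic")
  expect_identical(r4$consensus, "d_PE")
  r0 <- consensus_refit(fake_report(c(d_PE = 2L)), tb, baseline_covs,
                        "logistic")
  expect_identical(r0$consensus, character(0))
  expect_equal(r0$lrt_p, 1)
  expect_identical(r0$full$covariates, r0$baseline$covariates)
})

test_that("risk stratification splits evenly and flags degenerate scores", {
  tb <- simulate_cohort(cohort_spec(n_patients = 200L,
                                    rfs_coefficients = c(d_PE = log(2)),
                                    censor_rate = 0.7, seed = 31L))
  ft <- fit_outcome_model(tb, "d_PE", "cox")
  rs <- risk_stratify(ft, tb)
  expect_equal(unname(table(rs$groups)["low"]), 100)
  expect_equal(unname(table(rs$groups)["high"]), 100)
  expect_lt(rs$logrank_p, 0.05)
  expect_true(is.finite(rs$survival_ratio_at_median_time))
  # degenerate: constant predictor
  tb2 <- tb
  tb2$d_PE <- 1
  ft2 <- suppressWarnings(fit_outcome_model(tb2, "d_PE", "cox"))
  expect_warning(rs2 <- risk_stratify(ft2, tb2), "single group|identical")
  expect_true(rs2$flagged)
})

test_that("hormone status can enter as two dummies instead of an ordinal score", {
  tb <- simulate_cohort(cohort_spec(n_patients = 200L, seed = 47L))
  ft <- fit_outcome_model(tb, baseline_covs, "logistic",
                          hormone_coding = "dummy")
  expect_true(all(c("hormone_her2", "hormone_tn") %in%
                    names(ft$coefficients)))
})
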