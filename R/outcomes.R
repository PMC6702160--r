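# The statistical protocol: baseline-plus-feature logistic and Cox models,
# AUC / Harrell's C, five-fold cross-validation with univariable ranking and
# nested best-subset selection by AIC, consensus refit with a likelihood-
# ratio test, and risk-signature survival stratification.

default_baseline_covariates <- function() {
  c("age", "race", "hormone_status", "ftv2_cm3")
}

# Build the numeric design matrix for a covariate list: continuous columns
# z-scored (centers/scales reusable for new data), race passed through as
# 0/1, hormone status as an ordinal 1-3 score (or two dummies).
build_design <- function(table, covariates, scaling = NULL,
                         hormone_coding = "ordinal") {
  cols <- list()
  for (nm in covariates) {
    if (!nm %in% names(table)) stop("covariate not in table: ", nm)
    x <- table[[nm]]
    if (nm == "hormone_status" && hormone_coding == "dummy") {
      cols[["hormone_her2"]] <- as.numeric(x == 2)
      cols[["hormone_tn"]] <- as.numeric(x == 3)
    } else if (nm %in% c("race", "hormone_status")) {
      cols[[nm]] <- as.numeric(x)
    } else {
      cols[[nm]] <- as.numeric(x)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  binaryish <- vapply(seq_len(ncol(X)), function(j)
    colnames(X)[j] %in% c("race", "hormone_status", "hormone_her2",
                          "hormone_tn"), logical(1))
  if (is.null(scaling)) {
    centers <- ifelse(binaryish, 0, colMeans(X))
    scales <- rep(1, ncol(X))
    for (j in which(!binaryish)) {
      s <- stats::sd(X[, j])
      scales[j] <- if (is.finite(s) && s > 0) s else 1
    }
    names(centers) <- names(scales) <- colnames(X)
    scaling <- list(centers = centers, scales = scales)
  }
  X <- sweep(X, 2, scaling$centers[colnames(X)])
  X <- sweep(X, 2, scaling$scales[colnames(X)], "/")
  list(X = X, scaling = scaling)
}

analyzed_rows <- function(table, family) {
  if (family == "logistic") which(!is.na(table$pcr))
  else which(!is.na(table$rfs_time) & !is.na(table$rfs_event))
}

#' Fit a baseline or augmented outcome model
#'
#' Maximum-likelihood logistic regression for pCR or partial-likelihood Cox
#' regression for recurrence-free survival. Continuous covariates are
#' z-scored before fitting (so odds/hazard ratios are per standardised
#' unit); `race` enters as 0/1 and `hormone_status` as an ordinal 1-3 score
#' by default (a two-dummy coding is available). Rows with missing pCR are
#' excluded from logistic fits only.
#'
#' @param table a cohort table (see [simulate_cohort()]).
#' @param covariates character vector of column names.
#' @param family `"logistic"` or `"cox"`.
#' @param hormone_coding `"ordinal"` (default) or `"dummy"`.
#' @return An object of class `fit_result`: coefficient table with
#'   standard errors, 95 percent CIs, p-values, odds/hazard `ratios`,
#'   `loglik`, `aic` (`2k - 2 loglik`), the scaling used, and a `flagged`
#'   indicator for non-convergence or separation-like pathologies.
#' @export
fit_outcome_model <- function(table, covariates,
                              family = c("logistic", "cox"),
                              hormone_coding = c("ordinal", "dummy")) {
  family <- match.arg(family)
  hormone_coding <- match.arg(hormone_coding)
  rows <- analyzed_rows(table, family)
  if (length(rows) < 10L) stop("need at least 10 analyzable rows")
  tab <- table[rows, , drop = FALSE]
  if (family == "cox" && sum(tab$rfs_event) < 1L)
    stop("cox fit needs at least one event")
  des <- build_design(tab, covariates, hormone_coding = hormone_coding)
  X <- des$X
  flagged <- FALSE
  if (family == "logistic") {
    df <- data.frame(.y = tab$pcr, X, check.names = FALSE)
    fit <- withCallingHandlers(
      stats::glm(.y ~ ., data = df, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  conditionMessage(w))) {
          flagged <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    if (!fit$converged) flagged <- TRUE
    sm <- summary(fit)$coefficients
    coefs <- stats::coef(fit)
    ll <- as.numeric(stats::logLik(fit))
    k <- length(coefs)
  } else {
    df <- data.frame(.time = tab$rfs_time, .event = tab$rfs_event, X,
                     check.names = FALSE)
    fit <- tryCatch(
      survival::coxph(survival::Surv(.time, .event) ~ ., data = df),
      warning = function(w) {
        flagged <<- TRUE
        suppressWarnings(
          survival::coxph(survival::Surv(.time, .event) ~ ., data = df))
      })
    sm <- summary(fit)$coefficients[, c("coef", "se(coef)", "z", "Pr(>|z|)"),
                                    drop = FALSE]
    coefs <- stats::coef(fit)
    ll <- fit$loglik[length(fit$loglik)]
    k <- length(coefs)
  }
  if (any(!is.finite(coefs)) || any(abs(coefs) > 15)) flagged <- TRUE
  est <- stats::setNames(sm[, 1], rownames(sm))
  se <- stats::setNames(sm[, 2], rownames(sm))
  pvals <- stats::setNames(sm[, 4], rownames(sm))
  ci <- cbind(lower = est - 1.96 * se, upper = est + 1.96 * se)
  structure(list(
    family = family, covariates = covariates,
    coefficients = est, se = se, ci = ci, p = pvals,
    ratios = exp(est), loglik = ll, k = k, aic = 2 * k - 2 * ll,
    n = nrow(tab), scaling = des$scaling,
    hormone_coding = hormone_coding, model = fit, flagged = flagged),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s, n = %d, loglik = %.2f, AIC = %.2f%s\n",
              x$family, x$n, x$loglik, x$aic,
              if (x$flagged) " [flagged]" else ""))
  tb <- data.frame(coef = x$coefficients, se = x$se,
                   ratio = x$ratios, p = x$p)
  print(round(tb, 4))
  invisible(x)
}

#' Risk score (linear predictor) of a fitted model on a table
#'
#' Applies the stored standardisation and coefficients to new rows. For
#' logistic fits the intercept is included; for Cox fits the score is the
#' usual centred linear predictor.
#'
#' @param fit a [fit_outcome_model()] result.
#' @param table cohort table rows to score.
#' @return Numeric vector of risk scores.
#' @export
predict_risk <- function(fit, table) {
  des <- build_design(table, fit$covariates, scaling = fit$scaling,
                      hormone_coding = fit$hormone_coding)
  nm <- colnames(des$X)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0  # singular (dropped) columns contribute nothing
  if (fit$family == "logistic") {
    as.numeric(beta[["(Intercept)"]] + des$X %*% beta[nm])
  } else {
    as.numeric(des$X %*% beta[nm])
  }
}

#' Predictive performance: AUC or Harrell's C
#'
#' For pCR the area under the ROC curve via the rank (Mann-Whitney)
#' formulation, with score ties counting 0.5. For survival Harrell's
#' concordance over usable pairs: the patient with the shorter observed
#' time must have had an event; pairs censored before the other's event are
#' excluded; score ties count 0.5.
#'
#' @param scores numeric risk scores aligned with the rows of `table`.
#' @param table cohort table (uses `pcr` or `rfs_time`/`rfs_event`).
#' @param family `"logistic"` or `"cox"`.
#' @return Scalar in `[0, 1]`; `NA` with a warning when undefined (single
#'   outcome class or no usable pairs).
#' @export
performance <- function(scores, table, family = c("logistic", "cox")) {
  family <- match.arg(family)
  if (family == "logistic") {
    keep <- !is.na(table$pcr)
    y <- table$pcr[keep]; s <- scores[keep]
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    if (n1 == 0 || n0 == 0) {
      warning("AUC undefined: single outcome class")
      return(NA_real_)
    }
    r <- rank(s)
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  } else {
    t <- table$rfs_time; e <- table$rfs_event; s <- scores
    n <- length(t)
    ti <- matrix(t, n, n); tj <- t(ti)
    ei <- matrix(e, n, n)
    si <- matrix(s, n, n); sj <- t(si)
    usable <- ti < tj & ei == 1
    if (!any(usable)) {
      warning("C-statistic undefined: no usable pairs")
      return(NA_real_)
    }
    conc <- (si > sj) + 0.5 * (si == sj)
    sum(conc[usable]) / sum(usable)
  }
}

# Stratified fold assignment: shuffle within each stratum, deal round-robin.
stratified_folds <- function(strata, k) {
  fold <- integer(length(strata))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated feature ranking and nested best-subset selection
#'
#' For each of `k` stratified folds: (1) on training rows only, every
#' candidate feature is scored by the apparent (training-set) performance of
#' baseline + candidate and candidates are ranked (ties broken by lower
#' training AIC, then alphabetically); (2) the nested sequence
#' baseline + top-j candidates (j = 1..m) is fitted and the model with the
#' lowest training AIC is chosen; (3) the chosen model is refitted on the
#' training rows and scored on the held-out fold. Folds are stratified by
#' the outcome (pCR) or the event indicator (RFS); a Cox training fold
#' without events triggers a fresh stratified redraw (logged in the report).
#'
#' @param table cohort table.
#' @param baseline_covariates character vector, e.g.
#'   `c("age", "race", "hormone_status", "ftv2_cm3")`.
#' @param candidate_features character vector of feature columns (nonempty).
#' @param family `"logistic"` or `"cox"`.
#' @param k number of folds (>= 2).
#' @param seed integer seed; fixes folds and hence the whole report.
#' @return An object of class `cv_report`: per-fold rankings, selected
#'   subsets and test metrics; `mean_metric`, `sd_metric`;
#'   `selection_counts` per candidate; `folds` assignment; `redraws` count.
#' @export
cv_select <- function(table, baseline_covariates, candidate_features,
                      family = c("logistic", "cox"), k = 5L, seed = 1L) {
  family <- match.arg(family)
  if (length(candidate_features) == 0L) stop("candidates must be nonempty")
  if (k < 2L) stop("k must be >= 2")
  rows <- analyzed_rows(table, family)
  tab <- table[rows, , drop = FALSE]
  strata <- if (family == "logistic") tab$pcr else tab$rfs_event
  redraws <- 0L
  fold <- with_seed(seed, {
    f <- stratified_folds(strata, k)
    if (family == "cox") {
      ok <- function(f) all(vapply(seq_len(k), function(i)
        sum(tab$rfs_event[f != i]) >= 1 && sum(f == i) >= 2, logical(1)))
      while (!ok(f) && redraws < 20L) {
        redraws <- redraws + 1L
        f <- stratified_folds(strata, k)
      }
    }
    f
  })
  cand <- sort(candidate_features)
  folds_out <- vector("list", k)
  sel_counts <- stats::setNames(rep(0L, length(cand)), cand)
  metrics <- numeric(k)
  for (i in seq_len(k)) {
    train <- tab[fold != i, , drop = FALSE]
    test <- tab[fold == i, , drop = FALSE]
    perf <- aic <- stats::setNames(numeric(length(cand)), cand)
    for (f in cand) {
      ft <- fit_outcome_model(train, c(baseline_covariates, f), family)
      perf[f] <- performance(predict_risk(ft, train), train, family)
      aic[f] <- ft$aic
    }
    ord <- order(-perf, aic, cand)
    ranked <- cand[ord]
    nested_aic <- numeric(length(ranked))
    for (j in seq_along(ranked)) {
      fj <- fit_outcome_model(train, c(baseline_covariates, ranked[seq_len(j)]),
                              family)
      nested_aic[j] <- fj$aic
    }
    j_best <- which.min(nested_aic)
    selected <- ranked[seq_len(j_best)]
    fit_sel <- fit_outcome_model(train, c(baseline_covariates, selected),
                                 family)
    metrics[i] <- performance(predict_risk(fit_sel, test), test, family)
    sel_counts[selected] <- sel_counts[selected] + 1L
    folds_out[[i]] <- list(ranked = ranked, ranking_performance = perf[ord],
                           nested_aic = nested_aic, selected = selected,
                           test_metric = metrics[i])
  }
  structure(list(folds = folds_out, fold_assignment = fold,
                 rows = rows, k = k, family = family,
                 baseline_covariates = baseline_covariates,
                 candidates = cand, test_metrics = metrics,
                 mean_metric = mean(metrics), sd_metric = stats::sd(metrics),
                 selection_counts = sel_counts, redraws = redraws,
                 seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s, %d folds: mean metric %.3f (sd %.3f)\n",
              x$family, x$k, x$mean_metric, x$sd_metric))
  cat("  selection counts:\n")
  print(x$selection_counts)
  invisible(x)
}

#' Consensus refit and likelihood-ratio comparison
#'
#' Features selected in at least 80 percent of the folds (4 of 5 for k = 5)
#' form the consensus set; baseline and baseline-plus-consensus models are
#' refitted on the full analyzed table and compared by the likelihood-ratio
#' test with degrees of freedom equal to the number of added features. An
#' empty consensus set returns the baseline fit twice with p = 1.
#'
#' @param report a [cv_select()] result.
#' @param table the cohort table the report was built from.
#' @param baseline_covariates baseline covariate names.
#' @param family `"logistic"` or `"cox"`.
#' @return List with `full` and `baseline` ([fit_outcome_model()] results),
#'   `consensus` (character), `lrt_stat`, `lrt_df`, `lrt_p`.
#' @export
consensus_refit <- function(report, table, baseline_covariates,
                            family = c("logistic", "cox")) {
  family <- match.arg(family)
  stopifnot(inherits(report, "cv_report"))
  need <- ceiling(0.8 * report$k)
  consensus <- names(report$selection_counts)[report$selection_counts >= need]
  base_fit <- fit_outcome_model(table, baseline_covariates, family)
  if (length(consensus) == 0L) {
    return(list(full = base_fit, baseline = base_fit,
                consensus = character(0),
                lrt_stat = 0, lrt_df = 0L, lrt_p = 1))
  }
  full_fit <- fit_outcome_model(table, c(baseline_covariates, consensus),
                                family)
  stat <- max(0, 2 * (full_fit$loglik - base_fit$loglik))
  df <- full_fit$k - base_fit$k
  list(full = full_fit, baseline = base_fit, consensus = consensus,
       lrt_stat = stat, lrt_df = df,
       lrt_p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Median-split risk stratification with Kaplan-Meier comparison
#'
#' Computes each patient's risk signature (the Cox linear predictor), splits
#' the cohort at the median (ties to low risk), and compares the two groups
#' by Kaplan-Meier curves and the two-sided log-rank test. Also reports the
#' ratio of the groups' Kaplan-Meier survival estimates at the median
#' follow-up time (low over high, so larger means better separation).
#'
#' @param fit a Cox [fit_outcome_model()] result.
#' @param table cohort table to stratify.
#' @return List with `groups` (factor low/high), `km_curves` (data frame of
#'   time / survival / group), `logrank_p`, `survival_ratio_at_median_time`,
#'   `median_time`, and `flagged` (single-group degenerate case).
#' @export
risk_stratify <- function(fit, table) {
  stopifnot(inherits(fit, "fit_result"))
  if (fit$family != "cox") stop("risk_stratify requires a cox fit")
  lp <- predict_risk(fit, table)
  med <- stats::median(lp)
  if (all(lp == lp[1])) {
    warning("all risk scores identical: single group")
    return(list(groups = factor(rep("low", nrow(table)),
                                levels = c("low", "high")),
                km_curves = NULL, logrank_p = NA_real_,
                survival_ratio_at_median_time = NA_real_,
                median_time = NA_real_, flagged = TRUE))
  }
  groups <- factor(ifelse(lp > med, "high", "low"), levels = c("low", "high"))
  if (length(unique(groups)) < 2L) {
    warning("median split produced a single group")
    return(list(groups = groups, km_curves = NULL, logrank_p = NA_real_,
                survival_ratio_at_median_time = NA_real_,
                median_time = NA_real_, flagged = TRUE))
  }
  df <- data.frame(time = table$rfs_time, event = table$rfs_event,
                   group = groups)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  logrank_p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  km <- data.frame(time = sf$time, survival = sf$surv,
                   group = rep(c("low", "high"),
                               times = sf$strata[c("group=low", "group=high")]))
  med_t <- stats::median(df$time)
  surv_at <- function(g) {
    kmg <- km[km$group == g, , drop = FALSE]
    s <- c(1, kmg$survival)[findInterval(med_t, c(0, kmg$time))]
    s
  }
  s_low <- surv_at("low"); s_high <- surv_at("high")
  ratio <- if (is.finite(s_high) && s_high > 0) s_low / s_high else NA_real_
  list(groups = groups, km_curves = km, logrank_p = logrank_p,
       survival_ratio_at_median_time = ratio, median_time = med_t,
       flagged = FALSE)
}
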