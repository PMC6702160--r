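# Simulated patient cohorts: covariates drawn from the trial's demographic
# mix, imaging features from a parametric generator (or full phantom runs),
# and outcomes from known logistic (pCR) and proportional-hazards (RFS)
# models with independent right censoring.

#' Names of the per-tumour imaging features
#'
#' Seven voxel-wise heterogeneity indices and five aggregate features, in
#' the column order used throughout the package.
#' @return Character vector of length 12.
#' @export
feature_names <- function() {
  c("frac_jacobian", "frac_PRM_PE", "frac_PRM_WIS", "frac_PRM_WOS",
    "frac_PRM_SER", "entropy_ADI", "entropy_SRI",
    "ftv_ratio", "d_PE", "d_WIS", "d_WOS", "d_SER")
}

#' Specification of a simulated cohort
#'
#' Outcomes follow known models on standardised features: pCR is Bernoulli
#' with logit equal to `qlogis(baseline_event_rate)` plus the pCR linear
#' predictor; recurrence-free survival times are exponential with hazard
#' `baseline_hazard * exp(linear predictor)`, censored by independent
#' uniform administrative censoring calibrated to `censor_rate`.
#'
#' Defaults mirror a locally advanced breast cancer neoadjuvant trial
#' population: pCR prevalence near 0.30, about 30 percent of patients with
#' an event over a few years of follow-up, age near 48, and a three-level
#' hormone-receptor classification.
#'
#' @param n_patients number of patients (>= 2).
#' @param pcr_coefficients named numeric: log-odds per standardised unit for
#'   any feature or covariate column.
#' @param rfs_coefficients named numeric: log-hazards per standardised unit.
#' @param baseline_event_rate pCR probability at zero linear predictor.
#' @param baseline_hazard exponential event rate per year at zero linear
#'   predictor.
#' @param censor_rate target fraction of censored patients, in `[0, 1]`.
#' @param horizon_years administrative follow-up cap used when
#'   `censor_rate = 1`.
#' @param age_mean,age_sd age distribution (years).
#' @param race_prob probability of the reference race group (white or
#'   Hispanic, coded 1).
#' @param hormone_probs probabilities of the three hormone-receptor classes
#'   (HR+/HER2-, HER2+, triple-negative).
#' @param pcr_missing_rate fraction of patients with missing pCR.
#' @param seed integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 132L,
                        pcr_coefficients = c(),
                        rfs_coefficients = c(),
                        baseline_event_rate = 0.30,
                        baseline_hazard = 0.12,
                        censor_rate = 0.70,
                        horizon_years = 8,
                        age_mean = 48, age_sd = 9,
                        race_prob = 0.8,
                        hormone_probs = c(0.4, 0.3, 0.3),
                        pcr_missing_rate = 0,
                        seed = 1L) {
  if (n_patients < 2L) stop("n_patients must be >= 2")
  if (censor_rate < 0 || censor_rate > 1) stop("censor_rate must be in [0, 1]")
  if (length(pcr_coefficients) && any(!is.finite(pcr_coefficients)))
    stop("non-finite pcr_coefficients")
  if (length(rfs_coefficients) && any(!is.finite(rfs_coefficients)))
    stop("non-finite rfs_coefficients")
  structure(list(n_patients = as.integer(n_patients),
                 pcr_coefficients = pcr_coefficients,
                 rfs_coefficients = rfs_coefficients,
                 baseline_event_rate = baseline_event_rate,
                 baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate,
                 horizon_years = horizon_years,
                 age_mean = age_mean, age_sd = age_sd,
                 race_prob = race_prob,
                 hormone_probs = hormone_probs / sum(hormone_probs),
                 pcr_missing_rate = pcr_missing_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Default parametric feature generator: independent draws with plausible
# marginals for each index family (fractions in (0,1), nonpositive
# entropies, a positive volume ratio, centred relative changes).
default_feature_generator <- function(n) {
  out <- data.frame(
    frac_jacobian = stats::rbeta(n, 2, 2),
    frac_PRM_PE = stats::rbeta(n, 2, 2),
    frac_PRM_WIS = stats::rbeta(n, 2, 2),
    frac_PRM_WOS = stats::rbeta(n, 2, 2),
    frac_PRM_SER = stats::rbeta(n, 2, 2),
    entropy_ADI = -pmin(stats::rgamma(n, shape = 8, rate = 2.5), 5),
    entropy_SRI = -pmin(stats::rgamma(n, shape = 8, rate = 2.5), 5),
    ftv_ratio = stats::rlnorm(n, log(0.8), 0.4),
    d_PE = stats::rnorm(n, 0, 0.5),
    d_WIS = stats::rnorm(n, 0, 0.5),
    d_WOS = stats::rnorm(n, 0, 0.5),
    d_SER = stats::rnorm(n, 0, 0.5))
  out
}

# Administrative horizon giving the requested expected censored fraction
# under uniform censoring C ~ U(0, h) against exponential event rates.
solve_censor_horizon <- function(rates, censor_rate, cap = 1e4) {
  f <- function(h) mean((1 - exp(-rates * h)) / (rates * h)) - censor_rate
  if (f(cap) > 0) return(cap)
  stats::uniroot(f, c(1e-8, cap), tol = 1e-10)$root
}

#' Simulate a cohort table with known outcome models
#'
#' @param cspec a [cohort_spec()].
#' @param feature_generator function of `n` returning a data frame with the
#'   12 columns of [feature_names()]; defaults to a parametric generator.
#'   Linear predictors apply the specified coefficients to z-scored feature
#'   columns (and to `age`; `race` and `hormone_status` enter as coded).
#' @return A `data.frame` (cohort table) with columns `id`, `age`, `race`
#'   (1 = white or Hispanic, 0 = other), `hormone_status` (1 = HR+/HER2-,
#'   2 = HER2+, 3 = triple-negative), `ftv1_cm3`, `ftv2_cm3`, the 12
#'   features, `pcr` (0/1/NA), `rfs_time` (years, > 0), `rfs_event` (0/1).
#' @export
simulate_cohort <- function(cspec, feature_generator = NULL) {
  stopifnot(inherits(cspec, "cohort_spec"))
  if (is.null(feature_generator)) feature_generator <- default_feature_generator
  n <- cspec$n_patients
  with_seed(cspec$seed, {
    feats <- as.data.frame(feature_generator(n))
    missing_cols <- setdiff(feature_names(), names(feats))
    if (length(missing_cols))
      stop("feature_generator must supply columns: ",
           paste(missing_cols, collapse = ", "))
    feats <- feats[feature_names()]
    tab <- data.frame(
      id = seq_len(n),
      age = stats::rnorm(n, cspec$age_mean, cspec$age_sd),
      race = stats::rbinom(n, 1, cspec$race_prob),
      hormone_status = sample.int(3, n, replace = TRUE,
                                  prob = cspec$hormone_probs))
    tab$ftv1_cm3 <- stats::rlnorm(n, log(30), 0.6)
    tab$ftv2_cm3 <- tab$ftv1_cm3 * feats$ftv_ratio
    tab <- cbind(tab, feats)

    zscore <- function(x) {
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0) return(rep(0, length(x)))
      (x - mean(x)) / s
    }
    lp_of <- function(coefs) {
      lp <- rep(0, n)
      for (nm in names(coefs)) {
        if (!nm %in% names(tab)) stop("unknown coefficient target: ", nm)
        x <- tab[[nm]]
        if (nm %in% c("race", "hormone_status")) lp <- lp + coefs[[nm]] * x
        else lp <- lp + coefs[[nm]] * zscore(x)
      }
      lp
    }

    lp_pcr <- lp_of(cspec$pcr_coefficients)
    p_pcr <- stats::plogis(stats::qlogis(cspec$baseline_event_rate) + lp_pcr)
    tab$pcr <- stats::rbinom(n, 1, p_pcr)
    if (cspec$pcr_missing_rate > 0)
      tab$pcr[stats::runif(n) < cspec$pcr_missing_rate] <- NA

    lp_rfs <- lp_of(cspec$rfs_coefficients)
    rates <- cspec$baseline_hazard * exp(lp_rfs)
    t_event <- stats::rexp(n, rate = rates)
    if (cspec$censor_rate >= 1) {
      tab$rfs_time <- stats::runif(n, 0, cspec$horizon_years)
      tab$rfs_event <- 0L
    } else if (cspec$censor_rate <= 0) {
      tab$rfs_time <- t_event
      tab$rfs_event <- 1L
    } else {
      h <- solve_censor_horizon(rates, cspec$censor_rate)
      cens <- stats::runif(n, 0, h)
      tab$rfs_time <- pmin(t_event, cens)
      tab$rfs_event <- as.integer(t_event <= cens)
    }
    tab$rfs_time <- pmax(tab$rfs_time, 1e-8)
    tab
  })
}
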