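#' Default six-cluster population profiles
#'
#' The published per-cluster feature means for the six prognostic clusters
#' (hemoglobin g/dL, BMI, involved lymph nodes, tumor size mm, age years,
#' lymphocytes G/L, comorbidity prevalence, ER-positive prevalence,
#' SBR-high prevalence), together with default dispersions (15\% of each
#' feature's cross-cluster range, floored for the node count), equal mixing
#' weights, and default 5-year mortality rates of 0.12 for the three
#' good-prognosis clusters (0, 1, 4), 0.25 for cluster 2, 0.30 for
#' cluster 5 and 0.40 for the poorest cluster 3 — consistent with the
#' published bounds (good clusters above 80\% survival, worst cluster at
#' least 35\% mortality).
#'
#' @return a list of 6 \code{cluster_profile} lists with fields
#'   \code{cluster_id}, \code{feature_means}, \code{feature_sds},
#'   \code{mortality_5y}, \code{weight}.
#' @export
default_profiles <- function() {
  feat <- c("hemoglobin", "bmi", "n_nodes", "tumor_size", "age",
            "lymphocytes", "comorbidity", "er_positive", "sbr_high")
  means <- rbind(
    c(13.4, 25.0, 0.6, 19.6, 75.8, 1.8, 0.0, 1.0, 0.0),
    c(13.3, 28.4, 0.8, 19.3, 76.3, 2.1, 1.0, 1.0, 0.1),
    c(13.0, 24.9, 1.6, 26.1, 77.8, 2.1, 0.4, 0.0, 0.7),
    c(13.0, 28.9, 6.2, 65.8, 77.4, 1.6, 0.3, 0.8, 0.5),
    c(13.3, 25.6, 1.0, 23.1, 79.2, 3.4, 0.0, 1.0, 0.8),
    c(11.9, 23.0, 0.8, 30.6, 80.5, 1.6, 0.9, 1.0, 0.6))
  colnames(means) <- feat
  rng <- apply(means, 2, function(x) diff(range(x)))
  sds <- pmax(0.15 * rng, c(0, 0, 0.3, 0, 0, 0, 0, 0, 0))
  mortality <- c(0.12, 0.12, 0.25, 0.40, 0.12, 0.30)
  lapply(0:5, function(k) {
    structure(list(cluster_id = k,
                   feature_means = means[k + 1, ],
                   feature_sds = sds,
                   mortality_5y = mortality[k + 1],
                   weight = 1 / 6),
              class = "cluster_profile")
  })
}

#' Configuration for the synthetic-cohort generator
#'
#' @param n cohort size (>= 1).
#' @param seed integer RNG seed.
#' @param profiles list of cluster profiles; defaults to
#'   \code{\link{default_profiles}}.
#' @param chemo_rate marginal chemotherapy probability (default 0.12).
#' @param chemo_hazard_ratio multiplicative effect of chemotherapy on the
#'   death hazard (default 1 = no benefit); either a scalar or one value
#'   per cluster.
#' @param chemo_bias log-odds shift of treatment probability toward
#'   high-mortality clusters (default 0 = treatment independent of risk).
#' @param censor_rate_after_5y probability that a 5-year survivor's
#'   administrative censoring time is drawn uniformly on [60, 120] months
#'   (otherwise follow-up runs to 120 months).
#' @return an object of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n, seed = 1L, profiles = default_profiles(),
                          chemo_rate = 0.12, chemo_hazard_ratio = 1,
                          chemo_bias = 0, censor_rate_after_5y = 1) {
  if (n < 1) stop_oncotwin("n must be >= 1", class = "oncotwin_config_error")
  if (chemo_rate < 0 || chemo_rate > 1)
    stop_oncotwin("chemo_rate must lie in [0, 1]",
                  class = "oncotwin_config_error")
  if (any(chemo_hazard_ratio <= 0))
    stop_oncotwin("hazard ratios must be positive",
                  class = "oncotwin_config_error")
  w <- vapply(profiles, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-8)
    stop_oncotwin("cluster weights must sum to 1",
                  class = "oncotwin_config_error")
  if (any(vapply(profiles, function(p) any(p$feature_sds <= 0), logical(1))))
    stop_oncotwin("feature_sds must be positive",
                  class = "oncotwin_config_error")
  hr <- rep_len(chemo_hazard_ratio, length(profiles))
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 profiles = profiles, chemo_rate = chemo_rate,
                 chemo_hazard_ratio = hr, chemo_bias = chemo_bias,
                 censor_rate_after_5y = censor_rate_after_5y),
            class = "cohort_config")
}

# per-cluster treatment probabilities, recentred so the marginal stays
# approximately chemo_rate
chemo_probs <- function(config) {
  m <- vapply(config$profiles, `[[`, numeric(1), "mortality_5y")
  if (config$chemo_rate %in% c(0, 1)) return(rep(config$chemo_rate, length(m)))
  stats::plogis(stats::qlogis(config$chemo_rate) +
                  config$chemo_bias * (m - mean(m)))
}

#' Generate a seeded synthetic cohort
#'
#' Draws cluster membership from the profile weights, continuous features
#' from truncated normal distributions around the cluster means (age
#' truncated at 70; sizes, counts and blood values at 0; node counts
#' rounded to integers), binary features from the cluster prevalences, and
#' survival from an exponential model whose 5-year death probability equals
#' the cluster's \code{mortality_5y}; chemotherapy (assigned with
#' probability \code{chemo_rate}, optionally risk-biased) multiplies the
#' hazard by \code{chemo_hazard_ratio}.  Survivors are administratively
#' censored on [60, 120] months, so every record passes the eligibility and
#' complete-case filters.  The true cluster id is recorded as hidden ground
#' truth.  Output is byte-identical for identical configurations.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return a cohort \code{data.frame} with an extra \code{true_cluster}
#'   column.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop_oncotwin("config must be a cohort_config",
                  class = "oncotwin_config_error")
  set.seed(config$seed)
  n <- config$n
  w <- vapply(config$profiles, `[[`, numeric(1), "weight")
  cl <- sample(seq_along(w), n, replace = TRUE, prob = w) # 1-based
  mu <- t(vapply(config$profiles, `[[`, numeric(9), "feature_means"))
  sd <- t(vapply(config$profiles, `[[`, numeric(9), "feature_sds"))
  col <- function(f) list(m = mu[cl, f], s = sd[cl, f])
  hb <- col("hemoglobin"); bmi <- col("bmi"); nn <- col("n_nodes")
  ts <- col("tumor_size"); ag <- col("age"); ly <- col("lymphocytes")
  hemoglobin <- rtnorm_lower(n, hb$m, hb$s, 0)
  bmi_v <- rtnorm_lower(n, bmi$m, bmi$s, 10)
  n_nodes <- pmax(0, round(stats::rnorm(n, nn$m, nn$s)))
  tumor_size <- rtnorm_lower(n, ts$m, ts$s, 0)
  age <- rtnorm_lower(n, ag$m, ag$s, 70)
  lymphocytes <- rtnorm_lower(n, ly$m, ly$s, 0.1)
  comorb <- stats::rbinom(n, 1, mu[cl, "comorbidity"]) == 1
  er_pos <- stats::rbinom(n, 1, mu[cl, "er_positive"]) == 1
  sbr_high <- stats::rbinom(n, 1, mu[cl, "sbr_high"]) == 1
  # immunohistochemistry percentages consistent with the 10% positivity rule;
  # PR positivity only among ER-positive tumors, so HR status tracks the
  # cluster's ER prevalence
  er_percent <- ifelse(er_pos, stats::runif(n, 10, 100), stats::runif(n, 0, 9.9))
  pr_pos <- er_pos & stats::runif(n) < 0.85
  pr_percent <- ifelse(pr_pos, stats::runif(n, 10, 100), stats::runif(n, 0, 9.9))
  sbr_grade <- ifelse(sbr_high, 3L, ifelse(stats::runif(n) < 0.22, 1L, 2L))

  received_chemo <- stats::runif(n) < chemo_probs(config)[cl]

  mortality <- vapply(config$profiles, `[[`, numeric(1), "mortality_5y")
  lambda <- -log(1 - mortality[cl]) / 60
  lambda <- lambda * ifelse(received_chemo, config$chemo_hazard_ratio[cl], 1)
  event_time <- stats::rexp(n, pmax(lambda, 1e-12))
  censor <- ifelse(stats::runif(n) < config$censor_rate_after_5y,
                   stats::runif(n, 60, 120), 120)
  death <- event_time <= censor
  followup_months <- pmin(event_time, censor)
  # relapse: documented for all cancer deaths; among 5-year survivors it
  # occurs at half the cluster's mortality rate
  survived_5y <- !(death & followup_months <= 60)
  relapse <- !survived_5y | stats::runif(n) < mortality[cl] / 2

  out <- data.frame(
    patient_id = sprintf("S%05d", seq_len(n)),
    age = age, bmi = bmi_v, tumor_size = tumor_size,
    sbr_grade = sbr_grade, n_nodes = n_nodes,
    er_percent = er_percent, pr_percent = pr_percent,
    hemoglobin = hemoglobin, lymphocytes = lymphocytes,
    has_comorbidity = comorb, received_chemo = received_chemo,
    followup_months = followup_months, death = death, relapse = relapse,
    true_cluster = cl - 1L)
  attr(out, "hr_mode") <- "percent"
  out
}

#' Re-assign chemotherapy flags
#'
#' Draws each patient's \code{received_chemo} as Bernoulli with the
#' configured marginal rate, optionally shifted in log-odds toward
#' high-mortality clusters.  Survival fields are left untouched; use
#' \code{\link{generate_cohort}} when the treatment effect should propagate
#' into outcomes.
#'
#' @param cohort a generated cohort with a \code{true_cluster} column.
#' @param config a \code{\link{cohort_config}}.
#' @return the cohort with updated \code{received_chemo}.
#' @export
assign_chemotherapy <- function(cohort, config) {
  p <- chemo_probs(config)[cohort$true_cluster + 1L]
  cohort$received_chemo <- stats::runif(nrow(cohort)) < p
  cohort
}
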