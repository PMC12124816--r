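# In-code fixtures: small hand-built cohorts and helpers shared by the suite.

# a cohort data.frame with sensible defaults, any field overridable
make_cohort <- function(n = 5, age = 75, bmi = 25, tumor_size = 20,
                        sbr_grade = 2, n_nodes = 0, er_percent = 80,
                        pr_percent = 60, hemoglobin = 13.4,
                        lymphocytes = 1.8, has_comorbidity = FALSE,
                        received_chemo = FALSE, followup_months = 72,
                        death = FALSE, relapse = FALSE) {
  df <- data.frame(
    patient_id = sprintf("T%03d", seq_len(n)),
    age = rep_len(age, n), bmi = rep_len(bmi, n),
    tumor_size = rep_len(tumor_size, n),
    sbr_grade = rep_len(sbr_grade, n), n_nodes = rep_len(n_nodes, n),
    er_percent = rep_len(er_percent, n), pr_percent = rep_len(pr_percent, n),
    hemoglobin = rep_len(hemoglobin, n),
    lymphocytes = rep_len(lymphocytes, n),
    has_comorbidity = rep_len(has_comorbidity, n),
    received_chemo = rep_len(received_chemo, n),
    followup_months = rep_len(followup_months, n),
    death = rep_len(death, n), relapse = rep_len(relapse, n))
  attr(df, "hr_mode") <- "percent"
  df
}

write_cohort_file <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# well-separated 9-dimensional Gaussian blobs with known labels
make_blobs <- function(n_per = 50, centers = NULL, sd = 0.5, seed = 1) {
  set.seed(seed)
  if (is.null(centers)) centers <- blob_centers_6()
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 9)
  k <- nrow(centers)
  X <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(stats::rnorm(n_per * ncol(centers), mean = 0, sd = sd),
           ncol = ncol(centers)) +
      matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)))
  list(x = X, labels = rep(seq_len(k), each = n_per))
}

# default 6-blob centers in 9D, pairwise far apart
blob_centers_6 <- function(scale = 12) {
  m <- matrix(0, 6, 9)
  for (i in 1:6) m[i, i] <- scale
  m
}
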