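test_that("treatment neighbors match the brute-force distance oracle", {
  set.seed(1)
  coords <- matrix(rnorm(30), 10, 3)
  chemo <- rep(c(TRUE, FALSE), each = 5)
  q <- c(0.1, -0.2, 0.3)
  nb <- select_treatment_neighbors(q, coords, chemo, k = 3)
  d <- sqrt(colSums((t(coords) - q)^2))
  expect_equal(nb$chemo, which(chemo)[order(d[chemo])][1:3])
  expect_equal(nb$nochemo, which(!chemo)[order(d[!chemo])][1:3])
  expect_length(intersect(nb$chemo, nb$nochemo), 0)
  # exactly k per arm when both arms have enough patients
  coords2 <- matrix(rnorm(120), 40, 3)
  nb2 <- select_treatment_neighbors(q, coords2, rep(c(TRUE, FALSE), 20),
                                    k = 15)
  expect_length(nb2$chemo, 15)
  expect_length(nb2$nochemo, 15)
  # insufficient arm error names the arm
  err <- tryCatch(select_treatment_neighbors(q, coords, chemo, k = 8),
                  error = identity)
  expect_s3_class(err, "oncotwin_insufficient_arm_error")
  expect_match(conditionMessage(err), "chemotherapy")
})

test_that("Kaplan-Meier estimate matches hand product-limit values", {
  # three deaths at 6, 12, 18 months: S = 2/3, 1/3, 0
  km <- km_estimate(c(6, 12, 18), c(TRUE, TRUE, TRUE))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # censoring shrinks the risk set without a step: hand computation for
  # times 5+ (censored), 10 (death), 15 (death): S(10)=1*(1-1/2)=1/2,
  # S(15)=1/2*(1-1/1)=0
  km2 <- km_estimate(c(5, 10, 15), c(FALSE, TRUE, TRUE))
  expect_equal(surv_at(km2, c(4, 10, 15)), c(1, 1 / 2, 0))
  # no events: flat at 1
  km3 <- km_estimate(c(10, 20, 30), c(FALSE, FALSE, FALSE))
  expect_true(all(km3$surv == 1))
  # without censoring, S equals the empirical survivor fraction
  set.seed(2)
  t4 <- round(rexp(40, 0.02), 1)
  km4 <- km_estimate(t4, rep(TRUE, 40))
  for (tt in c(10, 30, 60)) expect_equal(surv_at(km4, tt), mean(t4 > tt))
  # invariant to input ordering
  o <- sample(40)
  km5 <- km_estimate(t4[o], rep(TRUE, 40))
  expect_equal(km5$surv, km4$surv)
  expect_error(km_estimate(numeric(0), logical(0)),
               class = "oncotwin_empty_error")
})

test_that("log-rank test matches a hand observed-minus-expected table", {
  # identical groups: statistic 0, p 1
  lr0 <- logrank_test(c(6, 12, 18), c(1, 1, 0), c(6, 12, 18), c(1, 1, 0))
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p_value, 1)
  # independent oracle: accumulate O-E and hypergeometric variance by hand
  ta <- c(3, 6, 9, 12, 15); ea <- c(1, 1, 1, 0, 1)
  tb <- c(4, 8, 10, 14, 20); eb <- c(0, 1, 0, 1, 1)
  time <- c(ta, tb); event <- c(ea, eb)
  grp <- rep(c(1, 2), each = 5)
  oe <- 0; vv <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at_risk <- time >= tt
    n1 <- sum(at_risk & grp == 1); n <- sum(at_risk)
    d <- sum(event == 1 & time == tt)
    oe <- oe + sum(event == 1 & time == tt & grp == 1) - d * n1 / n
    if (n > 1) vv <- vv + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  oracle_stat <- oe^2 / vv
  lr <- logrank_test(ta, ea, tb, eb)
  expect_equal(lr$statistic, oracle_stat, tolerance = 1e-10)
  expect_equal(lr$p_value, pchisq(oracle_stat, 1, lower.tail = FALSE))
  # invariant under swapping group labels
  lr_sw <- logrank_test(tb, eb, ta, ea)
  expect_equal(lr_sw$statistic, lr$statistic)
  expect_error(logrank_test(numeric(0), logical(0), tb, eb),
               class = "oncotwin_empty_error")
})

test_that("kernel density estimate is floored, normalized and unimodal", {
  set.seed(3)
  pts <- matrix(rnorm(60), 20, 3)
  f <- estimate_pdf(pts)
  far <- matrix(50, 4, 3)
  expect_true(all(f(far) >= 1e-12))          # floor everywhere
  # integrates to ~1 over a wide grid (quadrature oracle)
  g <- seq(-5, 5, length.out = 28)
  grid <- as.matrix(expand.grid(g, g, g))
  step <- diff(g)[1]
  expect_equal(sum(f(grid)) * step^3, 1, tolerance = 0.05)
  # higher density at the centroid than 5 bandwidths away
  ctr <- colMeans(pts)
  h <- apply(pts, 2, sd) * 20^(-1 / 7)
  expect_gt(f(ctr), f(ctr + 5 * h))
  expect_error(estimate_pdf(pts[1, , drop = FALSE]),
               class = "oncotwin_domain_error")
  degen <- pts; degen[, 2] <- 7
  expect_error(estimate_pdf(degen), class = "oncotwin_domain_error")
})

test_that("symmetrized KL matches the Gaussian closed form and its axioms", {
  set.seed(4)
  P <- matrix(rnorm(900), ncol = 3)
  expect_equal(symmetric_kl(P, P), 0)                    # identical samples
  Q <- matrix(rnorm(900), ncol = 3) + 2
  expect_equal(symmetric_kl(P, Q), symmetric_kl(Q, P))   # exact symmetry
  expect_gte(symmetric_kl(P, Q), 0)
  # two unit-variance 3D Gaussians offset by delta: symmetrized KL = delta^2
  delta <- 1.5
  A <- matrix(rnorm(2000 * 3), ncol = 3)
  B <- matrix(rnorm(2000 * 3), ncol = 3); B[, 1] <- B[, 1] + delta
  expect_equal(symmetric_kl(A, B), delta^2, tolerance = 0.15)
})

test_that("KL permutation test is calibrated and detects separation", {
  set.seed(5)
  A <- matrix(rnorm(75), 25, 3); B <- matrix(rnorm(75), 25, 3)
  r <- kl_permutation_test(A, B, B = 200, seed = 9)
  expect_length(r$permuted_kls, 200)
  expect_gte(r$p_value, 0); expect_lte(r$p_value, 1)
  expect_gt(r$p_value, 0.05)                 # same distribution: comparable
  expect_true(r$comparable)
  sep <- kl_permutation_test(A, B + 8, B = 200, seed = 9)
  expect_lte(sep$p_value, 0.01)              # far-separated blobs
  expect_false(sep$comparable)
  # the plus-one estimator never returns exactly zero
  sep1 <- kl_permutation_test(A, B + 8, B = 200, seed = 9, plus_one = TRUE)
  expect_equal(sep1$p_value, 1 / 201)
  expect_error(kl_permutation_test(A, B, B = 0),
               class = "oncotwin_config_error")
})

test_that("benefit report detects a real chemotherapy effect when arms mix", {
  cfg <- cohort_config(n = 1500, seed = 9, chemo_rate = 0.5,
                       chemo_hazard_ratio = c(1, 1, 1, 0.3, 1, 1))
  cohort <- generate_cohort(cfg)
  sp <- split_reference_model(cohort, 0.5, seed = 9)
  ref <- fit_reference(sp$reference)
  emb <- fit_clusters(fit_embedding(score_cohort(ref, sp$model), seed = 9))
  # a poor-prognosis query profile (large node-positive high-grade tumor)
  q <- c(age = 77.4, tumor_size = 65.8, grade_high = 1, n_nodes = 6,
         hr_positive = 1, hemoglobin = 13, lymphocytes = 1.6, bmi = 28.9,
         comorbidity = 0)
  rep <- assemble_benefit_report(score_cohort(ref, q), emb, sp$model,
                                 B = 200, seed = 3)
  expect_length(rep$neighborhood$chemo, 15)
  expect_gt(rep$survival_60m[["chemo"]], rep$survival_60m[["nochemo"]])
  expect_true(rep$kl_result$comparable)
  expect_false(grepl("WARNING", rep$verdict))
})

test_that("non-comparable arms trigger the heterogeneity warning", {
  # hand-built manifold: treated and untreated patients in two far blobs
  set.seed(7)
  coords <- rbind(matrix(rnorm(60, sd = 0.3), 20, 3),
                  matrix(rnorm(60, sd = 0.3), 20, 3) + 10)
  model <- structure(list(coords = coords,
                          train_deviations = cbind(coords,
                                                   matrix(0, 40, 6))),
                     class = "manifold_model")
  df <- make_cohort(40,
    received_chemo = rep(c(TRUE, FALSE), each = 20),
    followup_months = 72, death = FALSE)
  qdev <- c(5, 5, 5, 0, 0, 0, 0, 0, 0)
  rep <- assemble_benefit_report(qdev, model, df, k = 15, B = 100, seed = 1)
  expect_false(rep$kl_result$comparable)
  expect_match(rep$verdict, "heterogeneity")
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(rep); grDevices::dev.off()
  expect_true(file.exists(f))
})
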