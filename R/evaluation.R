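#' Per-cluster stratified train/test split
#'
#' Splits clustered model data 70/30 (by default) within every cluster:
#' the training share is rounded up per cluster, singleton clusters go
#' entirely to training (with a warning), and the two index sets are a
#' disjoint partition of the input.
#'
#' @param labels integer cluster labels.
#' @param train_fraction training fraction per cluster (default 0.7).
#' @param seed integer seed.
#' @return list of integer index vectors \code{train} and \code{test}.
#' @export
stability_split <- function(labels, train_fraction = 0.7, seed = 1L) {
  set.seed(seed)
  train <- integer(0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) == 1) {
      warning("cluster ", cl, " has a single member; placed in training")
      train <- c(train, idx)
    } else {
      n_tr <- ceiling(train_fraction * length(idx))
      train <- c(train, sort(sample(idx, n_tr)))
    }
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Manifold stability validation
#'
#' Repeats, for \code{n_init} seeded initializations: split the clustered
#' model data 70/30 per cluster, refit the embedding on the training share
#' only, project the test share onto the fresh manifold, and -- per
#' original cluster -- test with the symmetrized-KL permutation test
#' whether the cluster's training points and projected test points share a
#' distribution.  The protocol passes when every cluster's median p-value
#' over the initializations exceeds 0.05 (stable clusters re-form around
#' their own projected members).
#'
#' @param deviations deviation matrix of the model data.
#' @param labels cluster labels from the original manifold.
#' @param n_init number of manifold initializations (default 10).
#' @param B permutations per test (default 200).
#' @param seed integer seed.
#' @param train_fraction per-cluster training share (default 0.7).
#' @return an object of class \code{"stability_report"} with the full
#'   p-value matrix (initializations x clusters), per-cluster medians and
#'   the overall verdict.
#' @export
stability_validate <- function(deviations, labels, n_init = 10L, B = 200L,
                               seed = 1L, train_fraction = 0.7) {
  deviations <- as.matrix(deviations)
  clusters <- sort(unique(labels))
  sizes <- table(labels)
  if (length(clusters) < 2 || any(sizes < 4))
    stop_oncotwin("need >= 2 clusters with >= 4 members each",
                  class = "oncotwin_domain_error")
  pmat <- matrix(NA_real_, n_init, length(clusters),
                 dimnames = list(NULL, paste0("cluster_", clusters)))
  for (i in seq_len(n_init)) {
    sp <- stability_split(labels, train_fraction, seed = seed + i)
    emb <- fit_embedding(deviations[sp$train, , drop = FALSE],
                         seed = seed + 1000L + i)
    proj <- project(emb, deviations[sp$test, , drop = FALSE])
    for (jc in seq_along(clusters)) {
      tr <- emb$coords[labels[sp$train] == clusters[jc], , drop = FALSE]
      te <- proj[labels[sp$test] == clusters[jc], , drop = FALSE]
      if (nrow(te) < 2 || nrow(tr) < 2) next
      pmat[i, jc] <- kl_permutation_test(tr, te, B = B,
                                         seed = seed + 2000L + i)$p_value
    }
  }
  med <- apply(pmat, 2, stats::median, na.rm = TRUE)
  structure(list(n_initializations = n_init, p_values = pmat,
                 per_cluster_median_p = med, pass = all(med > 0.05)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Manifold stability over", x$n_initializations, "initializations\n")
  print(round(x$per_cluster_median_p, 3))
  cat("  verdict:", if (x$pass) "STABLE (all median p > 0.05)"
      else "UNSTABLE (some median p <= 0.05)", "\n")
  invisible(x)
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Predictive power of the nine predictors
#'
#' Evaluates 5-year mortality prediction from the raw predictor matrix
#' with a random forest and a support vector classifier under stratified
#' 5-fold cross-validation: per-classifier mean/SD AUC (SVC decision
#' values feed the ROC) and accuracy, plus an impurity-based importance
#' ranking (percentages summing to 100) from a forest refit on all data.
#'
#' @param x numeric predictor matrix.
#' @param y logical/0-1 outcome (TRUE = death within 5 years).
#' @param seed integer seed.
#' @param folds number of CV folds (default 5).
#' @return an object of class \code{"predictive_report"}.
#' @export
evaluate_predictors <- function(x, y, seed = 1L, folds = 5L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    stop_oncotwin("both outcome classes must be present",
                  class = "oncotwin_evaluation_error")
  fold <- stratified_folds(y, folds, seed)
  res <- list(rfc = list(auc = c(), acc = c()),
              svc = list(auc = c(), acc = c()))
  set.seed(seed)
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- fold == f
    yf <- factor(y[tr], levels = c(0, 1))
    rf <- randomForest::randomForest(x[tr, , drop = FALSE], yf)
    rf_score <- stats::predict(rf, x[te, , drop = FALSE],
                               type = "prob")[, "1"]
    sv <- e1071::svm(x[tr, , drop = FALSE], yf, kernel = "radial",
                     scale = TRUE)
    dv <- attr(stats::predict(sv, x[te, , drop = FALSE],
                              decision.values = TRUE), "decision.values")
    # orient decision values so that larger means class "1"
    sv_score <- if (startsWith(colnames(dv)[1], "1")) dv[, 1] else -dv[, 1]
    auc <- function(score) as.numeric(pROC::auc(pROC::roc(
      response = y[te], predictor = as.numeric(score), quiet = TRUE,
      levels = c(0, 1), direction = "<")))
    res$rfc$auc <- c(res$rfc$auc, auc(rf_score))
    res$svc$auc <- c(res$svc$auc, auc(sv_score))
    res$rfc$acc <- c(res$rfc$acc, mean((rf_score > 0.5) == (y[te] == 1)))
    res$svc$acc <- c(res$svc$acc, mean((sv_score > 0) == (y[te] == 1)))
  }
  rf_all <- randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                       importance = FALSE)
  imp <- randomForest::importance(rf_all)[, "MeanDecreaseGini"]
  imp_pct <- 100 * imp / sum(imp)
  ranking <- data.frame(predictor = names(sort(imp_pct, decreasing = TRUE)),
                        importance_pct = as.numeric(sort(imp_pct,
                                                         decreasing = TRUE)))
  structure(list(
    rfc = list(mean_auc = mean(res$rfc$auc), sd_auc = stats::sd(res$rfc$auc),
               mean_accuracy = mean(res$rfc$acc),
               sd_accuracy = stats::sd(res$rfc$acc)),
    svc = list(mean_auc = mean(res$svc$auc), sd_auc = stats::sd(res$svc$auc),
               mean_accuracy = mean(res$svc$acc),
               sd_accuracy = stats::sd(res$svc$acc)),
    importance_ranking = ranking, folds = folds),
    class = "predictive_report")
}

#' @export
print.predictive_report <- function(x, ...) {
  cat(sprintf("Random forest : AUC %.2f (SD %.2f), accuracy %.2f (SD %.2f)\n",
              x$rfc$mean_auc, x$rfc$sd_auc, x$rfc$mean_accuracy,
              x$rfc$sd_accuracy))
  cat(sprintf("SVC           : AUC %.2f (SD %.2f), accuracy %.2f (SD %.2f)\n",
              x$svc$mean_auc, x$svc$sd_auc, x$svc$mean_accuracy,
              x$svc$sd_accuracy))
  cat("Importance ranking (%):\n")
  print(x$importance_ranking, row.names = FALSE, digits = 3)
  invisible(x)
}
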