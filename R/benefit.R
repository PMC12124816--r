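#' Nearest treated and untreated neighbors of a manifold point
#'
#' Selects, independently per treatment arm, the \code{k} patients whose
#' embedded 3D coordinates are closest (Euclidean) to the query point; ties
#' are broken by row index.
#'
#' @param query numeric 3D coordinate.
#' @param coords n x 3 matrix of embedded patient coordinates.
#' @param received_chemo logical vector aligned with \code{coords}.
#' @param k neighbors per arm (default 15).
#' @return an object of class \code{"treatment_neighborhood"} with integer
#'   index vectors \code{chemo} and \code{nochemo}.
#' @export
select_treatment_neighbors <- function(query, coords, received_chemo,
                                       k = 15L) {
  coords <- as.matrix(coords)
  d2 <- drop(pdist2(matrix(query, nrow = 1), coords))
  pick <- function(arm, name) {
    idx <- which(arm)
    if (length(idx) < k)
      stop_oncotwin("fewer than k = ", k, " patients in the ", name,
                    " arm (", length(idx), " available)",
                    class = "oncotwin_insufficient_arm_error")
    idx[order(d2[idx])[seq_len(k)]]
  }
  structure(list(query = query,
                 chemo = pick(received_chemo, "chemotherapy"),
                 nochemo = pick(!received_chemo, "no-chemotherapy"),
                 k = k),
            class = "treatment_neighborhood")
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function; censored patients
#' leave the risk set without producing a step.
#'
#' @param times follow-up times in months (>= 0).
#' @param events logical/0-1 event (death) indicators.
#' @return an object of class \code{"survival_curve"} with \code{time},
#'   \code{surv}, \code{n_risk}, \code{n_event} and the underlying
#'   \code{survfit} object.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0)
    stop_oncotwin("empty survival input", class = "oncotwin_empty_error")
  if (length(times) != length(events))
    stop_oncotwin("times and events must have equal length",
                  class = "oncotwin_domain_error")
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, fit = fit),
            class = "survival_curve")
}

#' Evaluate a survival curve at given times
#'
#' @param curve a \code{\link{km_estimate}} result.
#' @param t times (months).
#' @return survival probabilities, right-continuous step function.
#' @export
surv_at <- function(curve, t) {
  vapply(t, function(tt) {
    below <- curve$time <= tt
    if (!any(below)) 1 else curve$surv[max(which(below))]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank chi-square comparing the
#' survival distributions of two groups.
#'
#' @param times_a,events_a follow-up and event indicators, group A.
#' @param times_b,events_b follow-up and event indicators, group B.
#' @return list with \code{statistic} and \code{p_value}.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0 || length(times_b) == 0)
    stop_oncotwin("both groups must be non-empty",
                  class = "oncotwin_empty_error")
  time <- c(times_a, times_b)
  event <- as.integer(c(events_a, events_b))
  if (sum(event) == 0)  # no deaths in either arm: identical flat curves
    return(list(statistic = 0, p_value = 1))
  group <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  stat <- sd$chisq
  if (!is.finite(stat)) stat <- 0
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1,
                                                 lower.tail = FALSE))
}

#' Gaussian kernel density estimate over 3D points
#'
#' Product Gaussian kernel with Scott's-rule bandwidths (per-dimension
#' standard deviation times \eqn{n^{-1/(d+4)}}).  The returned evaluator is
#' floored at \code{eps} so log-densities stay finite; with \code{loo =
#' TRUE} (used when the evaluation points are the sample itself) each
#' point's own kernel is left out, giving a leave-one-out estimate of the
#' underlying density rather than a self-inflated one.
#'
#' @param points n x d matrix (n >= 2) of sample points.
#' @param eps density floor (default 1e-12).
#' @return a function \code{f(newpoints, loo = FALSE)} returning densities.
#' @export
estimate_pdf <- function(points, eps = 1e-12) {
  points <- as.matrix(points)
  n <- nrow(points); d <- ncol(points)
  if (n < 2)
    stop_oncotwin("at least 2 points are required for a density estimate",
                  class = "oncotwin_domain_error")
  h <- apply(points, 2, stats::sd) * n^(-1 / (d + 4))
  if (any(!is.finite(h)) || any(h <= 0))
    stop_oncotwin("degenerate sample: zero spread in some dimension",
                  class = "oncotwin_domain_error")
  norm_const <- 1 / ((2 * pi)^(d / 2) * prod(h))
  function(newpoints, loo = FALSE) {
    if (is.null(dim(newpoints))) newpoints <- matrix(newpoints, nrow = 1)
    z <- 0
    for (j in seq_len(d))
      z <- z + outer(newpoints[, j], points[, j], "-")^2 / h[j]^2
    K <- exp(-z / 2)
    if (loo) {
      diag(K) <- 0
      dens <- rowSums(K) * norm_const / (n - 1)
    } else {
      dens <- rowSums(K) * norm_const / n
    }
    pmax(dens, eps)
  }
}

#' Symmetrized Kullback-Leibler divergence between two point clouds
#'
#' \eqn{D(P||Q) + D(Q||P)}, each term Monte-Carlo estimated on the own
#' group's sample points with \code{eps}-floored kernel density estimates:
#' own-group densities are evaluated leave-one-out (avoiding the strong
#' self-inflation bias of the plug-in estimator), the other group's
#' density directly.  Symmetric by construction; the estimate is truncated
#' at zero, so identical samples give exactly 0 and the divergence is
#' never negative.  Truncation does not affect the upper tail used by the
#' permutation test.
#'
#' @param samples_p,samples_q n x d matrices (n, m >= 2).
#' @param eps density floor.
#' @return a non-negative divergence estimate.
#' @export
symmetric_kl <- function(samples_p, samples_q, eps = 1e-12) {
  samples_p <- as.matrix(samples_p); samples_q <- as.matrix(samples_q)
  fp <- estimate_pdf(samples_p, eps)
  fq <- estimate_pdf(samples_q, eps)
  dpq <- mean(log(fp(samples_p, loo = TRUE)) - log(fq(samples_p)))
  dqp <- mean(log(fq(samples_q, loo = TRUE)) - log(fp(samples_q)))
  max(0, dpq + dqp)
}

#' Permutation test of distributional comparability
#'
#' Tests whether two point clouds could come from the same distribution:
#' the observed symmetrized KL divergence is compared with \code{B}
#' re-computations under random re-splits of the pooled points (group
#' sizes preserved).  The p-value is the proportion of permuted
#' divergences at least as extreme as the observed one; with
#' \code{plus_one = TRUE} the standard (count+1)/(B+1) correction is used
#' instead, which cannot return exactly zero.
#'
#' @param group_a,group_b n x d matrices.
#' @param B number of permutations (default 1000).
#' @param seed integer seed.
#' @param alpha comparability threshold on the p-value (default 0.05).
#' @param plus_one use the (count+1)/(B+1) estimator.
#' @return an object of class \code{"kl_permutation_result"} with
#'   \code{observed_kl}, \code{permuted_kls}, \code{p_value},
#'   \code{comparable}.
#' @export
kl_permutation_test <- function(group_a, group_b, B = 1000L, seed = 1L,
                                alpha = 0.05, plus_one = FALSE) {
  if (B < 1) stop_oncotwin("B must be >= 1", class = "oncotwin_config_error")
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  observed <- symmetric_kl(group_a, group_b)
  pool <- rbind(group_a, group_b)
  na <- nrow(group_a); n <- nrow(pool)
  set.seed(seed)
  permuted <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, na)
    symmetric_kl(pool[idx, , drop = FALSE], pool[-idx, , drop = FALSE])
  }, numeric(1))
  count <- sum(permuted >= observed)
  p <- if (plus_one) (count + 1) / (B + 1) else count / B
  structure(list(observed_kl = observed, permuted_kls = permuted,
                 p_value = p, comparable = p > alpha, alpha = alpha,
                 B = B),
            class = "kl_permutation_result")
}

#' @export
print.kl_permutation_result <- function(x, ...) {
  cat(sprintf("Symmetrized KL permutation test: observed %.4f, p = %.4g (B = %d)\n",
              x$observed_kl, x$p_value, x$B))
  cat("  arms", if (x$comparable) "comparable" else "NOT comparable",
      sprintf("at alpha = %.2f\n", x$alpha))
  invisible(x)
}

#' Individual chemotherapy-benefit report
#'
#' Composes the full per-patient benefit assessment: the query patient's
#' deviation vector is projected onto the manifold, the 15 nearest
#' chemotherapy-treated and 15 nearest untreated patients are selected,
#' their Kaplan-Meier curves compared by log-rank test, and the
#' comparability of the two neighborhoods verified with the symmetrized-KL
#' permutation test.  When the arms are not comparable the verdict carries
#' an explicit heterogeneity warning.
#'
#' @param query_deviation the query patient's 9-dimensional deviation
#'   vector (from \code{\link{score_cohort}}).
#' @param model a fitted (and typically clustered) manifold model.
#' @param cohort the cohort the manifold was fitted on (same row order),
#'   providing treatment flags and follow-up.
#' @param k neighbors per arm (default 15).
#' @param B permutations for the comparability test (default 1000).
#' @param seed integer seed.
#' @return an object of class \code{"benefit_report"}.
#' @export
assemble_benefit_report <- function(query_deviation, model, cohort,
                                    k = 15L, B = 1000L, seed = 1L) {
  point <- drop(project(model, query_deviation))
  chemo <- !is.na(cohort$received_chemo) & cohort$received_chemo
  nb <- select_treatment_neighbors(point, model$coords, chemo, k)
  arm <- function(idx) list(times = cohort$followup_months[idx],
                            events = cohort$death[idx])
  a <- arm(nb$chemo); b <- arm(nb$nochemo)
  km_chemo <- km_estimate(a$times, a$events)
  km_nochemo <- km_estimate(b$times, b$events)
  lr <- logrank_test(a$times, a$events, b$times, b$events)
  kl <- kl_permutation_test(model$coords[nb$chemo, , drop = FALSE],
                            model$coords[nb$nochemo, , drop = FALSE],
                            B = B, seed = seed)
  s60 <- c(chemo = surv_at(km_chemo, 60), nochemo = surv_at(km_nochemo, 60))
  verdict <- sprintf(
    "5-year survival %.0f%% with vs %.0f%% without chemotherapy (log-rank p = %.3g).",
    100 * s60["chemo"], 100 * s60["nochemo"], lr$p_value)
  if (!kl$comparable)
    verdict <- paste(verdict, "WARNING: the two treatment neighborhoods are",
                     "not comparable (KL permutation p =",
                     format(kl$p_value, digits = 3),
                     "); any conclusion must be taken with consideration of",
                     "the heterogeneity of the compared profiles.")
  structure(list(query_point = point, neighborhood = nb,
                 km_chemo = km_chemo, km_nochemo = km_nochemo,
                 survival_60m = s60,
                 logrank_statistic = lr$statistic, logrank_p = lr$p_value,
                 kl_result = kl, verdict = verdict),
            class = "benefit_report")
}

#' @export
print.benefit_report <- function(x, ...) {
  cat("Chemotherapy-benefit report\n")
  cat("  query point: (", paste(sprintf("%.2f", x$query_point),
                                collapse = ", "), ")\n", sep = "")
  cat("  neighbors per arm:", x$neighborhood$k, "\n")
  cat(" ", x$verdict, "\n")
  invisible(x)
}

#' Kaplan-Meier curves and permutation histogram for a benefit report
#'
#' @param x a \code{\link{assemble_benefit_report}} result.
#' @param max_months display truncation (default 120).
#' @param ... unused.
#' @export
plot.benefit_report <- function(x, max_months = 120, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  graphics::plot(NULL, xlim = c(0, max_months), ylim = c(0, 1),
                 xlab = "Months since diagnosis", ylab = "Survival",
                 main = "15 nearest patients per arm")
  for (cv in list(list(x$km_chemo, "firebrick"),
                  list(x$km_nochemo, "steelblue"))) {
    t <- c(0, cv[[1]]$time); s <- c(1, cv[[1]]$surv)
    graphics::lines(stats::stepfun(t[-1], s), do.points = FALSE,
                    col = cv[[2]], lwd = 2, xlim = c(0, max_months))
  }
  graphics::legend("bottomleft", c("chemotherapy", "no chemotherapy"),
                   col = c("firebrick", "steelblue"), lwd = 2, bty = "n")
  kl <- x$kl_result
  graphics::hist(kl$permuted_kls, breaks = 30, col = "lightsteelblue",
                 border = "white", main = sprintf("KL permutation (p = %.3g)",
                                                  kl$p_value),
                 xlab = "Symmetrized KL divergence",
                 xlim = range(c(kl$permuted_kls, kl$observed_kl)))
  graphics::abline(v = kl$observed_kl, col = "red", lwd = 2)
  invisible(x)
}
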