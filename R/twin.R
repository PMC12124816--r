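#' Select the good-outcome reference class
#'
#' Retains patients alive at 5 years with no documented relapse; these are
#' the patients eligible to calibrate the reference model against which all
#' deviations are measured.
#'
#' @param cohort an eligibility-filtered cohort \code{data.frame}.
#' @return the reference-eligible subset.
#' @export
select_reference <- function(cohort) {
  oc <- outcome_5y(cohort)
  cohort[oc$in_reference_class, , drop = FALSE]
}

#' Split a cohort into reference and model data
#'
#' A seeded random fraction of the reference-eligible (good-outcome)
#' patients becomes the reference group; every remaining patient --
#' eligible-but-unselected and ineligible alike -- becomes the model data.
#' The two sets are disjoint and their union is the input, which prevents
#' calibration data from leaking into the scored population.
#'
#' @param cohort a complete-case, eligibility-filtered cohort.
#' @param fraction fraction of reference-eligible patients used for
#'   calibration (default 0.5).
#' @param seed integer seed for the random selection.
#' @return a list with \code{data.frame}s \code{reference} and \code{model}.
#' @export
split_reference_model <- function(cohort, fraction = 0.5, seed = 1L) {
  oc <- outcome_5y(cohort)
  eligible <- which(oc$in_reference_class)
  if (length(eligible) < 2)
    stop_oncotwin("fewer than 2 reference-eligible patients",
                  class = "oncotwin_split_error")
  set.seed(seed)
  take <- sort(sample(eligible, round(fraction * length(eligible))))
  list(reference = cohort[take, , drop = FALSE],
       model = cohort[-take, , drop = FALSE])
}

robust_scale <- function(x) {
  s <- stats::IQR(x) / 1.349
  # degenerate spread (constant predictor, or a binary predictor with
  # prevalence outside the quartiles): leave the predictor on its natural
  # scale rather than inflating it
  if (s < 1e-6) 1 else s
}

#' Calibrate the reference model
#'
#' Stores a robust center (median) and scale (IQR/1.349) per predictor,
#' estimated on the good-outcome reference group, together with the
#' standardized reference matrix and the twin-neighborhood size.  Every
#' downstream deviation is measured in these reference-calibrated units.
#'
#' @param reference reference patients: a cohort \code{data.frame} or a
#'   9-column predictor matrix.
#' @param k_twins number of nearest reference profiles forming a patient's
#'   digital-twin neighborhood (default 15).
#' @return an object of class \code{"reference_model"}.
#' @export
fit_reference <- function(reference, k_twins = 15L) {
  x <- if (is.matrix(reference)) reference else predictor_matrix(reference)
  if (nrow(x) <= k_twins)
    stop_oncotwin("reference size (", nrow(x), ") must exceed k_twins (",
                  k_twins, ")", class = "oncotwin_calibration_error")
  center <- apply(x, 2, stats::median)
  scale <- apply(x, 2, robust_scale)
  z <- sweep(sweep(x, 2, center), 2, scale, "/")
  structure(list(center = center, scale = scale, reference_z = z,
                 k_twins = as.integer(k_twins)),
            class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  cat("Reference model:", nrow(x$reference_z), "good-outcome patients,",
      "k_twins =", x$k_twins, "\n")
  print(round(rbind(center = x$center, scale = x$scale), 3))
  invisible(x)
}

check_fitted <- function(model) {
  if (!inherits(model, "reference_model") || is.null(model$reference_z))
    stop_oncotwin("reference model is not fitted",
                  class = "oncotwin_state_error")
}

standardize <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1,
                                   dimnames = list(NULL, names(x)))
  x <- if (is.matrix(x)) x else predictor_matrix(x)
  sweep(sweep(x, 2, model$center), 2, model$scale, "/")
}

#' Digital-twin deviation scores for a cohort
#'
#' Transforms raw predictor vectors into signed, unit-free deviations from
#' the good-outcome reference group: each predictor is centred on the
#' reference median and scaled by the reference IQR/1.349.  These deviation
#' vectors are the coordinates every downstream stage (embedding,
#' clustering, benefit estimation) operates on.  Rows are scored
#' independently and order is preserved.
#'
#' @param model a fitted \code{\link{fit_reference}} model.
#' @param patients a cohort \code{data.frame}, a predictor matrix, or a
#'   single named 9-vector.
#' @return numeric matrix of deviations, one row per patient.
#' @export
score_cohort <- function(model, patients) {
  check_fitted(model)
  if (is.data.frame(patients)) patients <- predictor_matrix(patients)
  standardize(model, patients)
}

#' Twin-neighborhood lookup
#'
#' Finds, for each patient, the \code{k} nearest reference profiles
#' (Euclidean distance in reference-standardized units; ties broken by
#' reference row order) -- the patient's digital twins.
#'
#' @inheritParams score_cohort
#' @param k neighborhood size; defaults to the model's \code{k_twins}.
#' @return list with integer matrix \code{index} (patients x k) and numeric
#'   matrix \code{distance}.
#' @export
twin_neighbors <- function(model, patients, k = model$k_twins) {
  check_fitted(model)
  z <- score_cohort(model, patients)
  d2 <- pdist2(z, model$reference_z)
  idx <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  dist <- t(vapply(seq_len(nrow(z)),
                   function(i) sqrt(d2[i, idx[i, ]]), numeric(k)))
  list(index = idx, distance = dist)
}

#' Deviation from the digital-twin neighborhood centroid
#'
#' The local complement of \code{\link{score_cohort}}: the standardized
#' patient minus the componentwise mean of its \code{k} nearest reference
#' profiles.  It is the zero vector exactly when the patient coincides with
#' its twin-neighborhood centroid, and is used as a typicality diagnostic
#' (how far a patient sits from the good-outcome profiles most similar to
#' it), not as the embedding input.
#'
#' @inheritParams twin_neighbors
#' @return numeric matrix of local residuals, one row per patient.
#' @export
twin_residual <- function(model, patients, k = model$k_twins) {
  check_fitted(model)
  z <- score_cohort(model, patients)
  nb <- twin_neighbors(model, patients, k)
  centroids <- t(vapply(seq_len(nrow(z)), function(i)
    colMeans(model$reference_z[nb$index[i, ], , drop = FALSE]),
    numeric(ncol(z))))
  z - centroids
}
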