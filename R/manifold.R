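#' Embed deviation vectors into a 3D manifold
#'
#' Reduces the 9-dimensional deviation vectors to three dimensions with a
#' pairwise-controlled manifold approximation (PaCMAP): nearest-neighbor,
#' mid-near and further point pairs are optimized under a three-phase
#' weight schedule so that both local and global structure of the patient
#' population survive the reduction.  The fit is fully seeded and the
#' training deviations are retained so new patients can later be projected
#' without refitting.
#'
#' The neighbor count defaults to 30 (capped below the sample size): binary
#' predictors split each patient subgroup into Bernoulli sub-cells, and a
#' neighborhood large enough to span neighboring sub-cells keeps each
#' subgroup a single connected blob instead of overseparating it.
#'
#' @param deviations numeric matrix of deviation vectors (>= 10 rows).
#' @param seed integer seed controlling pair sampling and initialization.
#' @param n_neighbors nearest-neighbor pair count per point (default 30).
#' @param n_components embedding dimension (default 3).
#' @param n_iters optimization iterations (default 450).
#' @return an object of class \code{"manifold_model"} with the embedding in
#'   \code{$coords}.
#' @export
fit_embedding <- function(deviations, seed = 1L, n_neighbors = 30L,
                          n_components = 3L, n_iters = 450L) {
  deviations <- as.matrix(deviations)
  if (nrow(deviations) < 10)
    stop_oncotwin("at least 10 rows are required to fit an embedding",
                  class = "oncotwin_embedding_error")
  n_neighbors <- max(2L, min(n_neighbors, nrow(deviations) - 2L))
  coords <- pacmap_fit(deviations, n_components = n_components,
                       n_neighbors = n_neighbors, n_iters = n_iters,
                       seed = seed)
  structure(list(coords = coords, train_deviations = deviations,
                 seed = as.integer(seed), n_neighbors = n_neighbors,
                 n_components = n_components,
                 cluster_labels = NULL, bandwidth = NULL,
                 n_clusters = NULL, min_cluster_size = NULL),
            class = "manifold_model")
}

#' Stratify the manifold with mean-shift clustering
#'
#' Labels every embedded point by mean-shift density clustering.  The
#' kernel bandwidth defaults to the pairwise-distance quantile rule
#' (\code{\link{bandwidth_quantile}}); clusters are numbered in order of
#' decreasing size, and clusters smaller than \code{min_size} members are
#' flagged as minor (they keep their labels but are excluded from
#' prognosis labelling).
#'
#' The default quantile is 0.1: with \eqn{k} balanced clusters only about
#' \eqn{1/k} of pairwise distances are within-cluster, so the quantile must
#' stay below that fraction for the bandwidth to reflect within-cluster
#' scale rather than between-cluster separations.
#'
#' @param model a \code{\link{fit_embedding}} result.
#' @param bandwidth kernel bandwidth; \code{NULL} (default) applies the
#'   quantile rule.
#' @param quantile pairwise-distance quantile for the default bandwidth.
#' @param min_size minimum major-cluster size (default 10).
#' @return the model with \code{cluster_labels}, \code{bandwidth},
#'   \code{n_clusters} and \code{major_clusters} filled in.
#' @export
fit_clusters <- function(model, bandwidth = NULL, quantile = 0.1,
                         min_size = 10L) {
  if (!inherits(model, "manifold_model"))
    stop_oncotwin("model must be a manifold_model",
                  class = "oncotwin_state_error")
  if (is.null(bandwidth)) bandwidth <- bandwidth_quantile(model$coords,
                                                          quantile)
  ms <- mean_shift(model$coords, bandwidth)
  model$cluster_labels <- ms$labels
  model$bandwidth <- bandwidth
  model$n_clusters <- max(ms$labels)
  model$min_cluster_size <- as.integer(min_size)
  sizes <- table(ms$labels)
  model$major_clusters <- as.integer(names(sizes))[sizes >= min_size]
  model
}

#' @export
print.manifold_model <- function(x, ...) {
  cat("Manifold model:", nrow(x$coords), "patients embedded in",
      ncol(x$coords), "dimensions\n")
  if (!is.null(x$cluster_labels)) {
    cat("  clusters:", x$n_clusters,
        sprintf("(%d major, bandwidth %.3f)\n",
                length(x$major_clusters), x$bandwidth))
    print(table(cluster = x$cluster_labels))
  } else cat("  clusters: not fitted\n")
  invisible(x)
}

#' Per-cluster profiles and prognosis labels
#'
#' Summarizes each recovered cluster on the original predictor scale:
#' size, the nine feature means, observed 5-year mortality, and a prognosis
#' label -- \code{good} when 5-year survival exceeds 80\%,
#' \code{poor} when 5-year mortality is at least 35\%, otherwise
#' \code{intermediate}.  Minor clusters (below the fitted
#' \code{min_cluster_size}) are reported but labelled \code{minor}.
#'
#' @param model a clustered \code{\link{fit_clusters}} model.
#' @param cohort the cohort the embedding was fitted on (same row order).
#' @return a \code{data.frame}, one row per cluster.
#' @export
summarize_clusters <- function(model, cohort) {
  if (is.null(model$cluster_labels))
    stop_oncotwin("fit_clusters() must be run first",
                  class = "oncotwin_state_error")
  x <- predictor_matrix(cohort)
  oc <- outcome_5y(cohort)
  labels <- model$cluster_labels
  out <- do.call(rbind, lapply(sort(unique(labels)), function(cl) {
    in_cl <- labels == cl
    mort <- mean(!oc$survived_5y[in_cl])
    major <- cl %in% model$major_clusters
    label <- if (!major) "minor"
             else if (1 - mort > 0.80) "good"
             else if (mort >= 0.35) "poor"
             else "intermediate"
    data.frame(cluster_id = cl, size = sum(in_cl),
               t(colMeans(x[in_cl, , drop = FALSE])),
               mortality_5y = mort, prognosis_label = label)
  }))
  rownames(out) <- NULL
  out
}

#' Project new patients onto a fitted manifold
#'
#' Places new deviation vectors into the existing 3D embedding without
#' refitting.  With the default \code{k = 1} a new patient takes the
#' embedded coordinate of its nearest training deviation, which preserves
#' the embedded distribution of projected samples (no interpolation
#' shrinkage); \code{k > 1} switches to distance-weighted interpolation
#' over the \code{k} nearest anchors (weights proportional to inverse
#' squared distance), trading distributional fidelity for smoothness.
#' A point identical to a training row is always mapped exactly onto that
#' row's embedded coordinate, so re-projection of training data is
#' self-consistent; the map is deterministic and repeatable.
#'
#' @param model a fitted \code{\link{fit_embedding}} model.
#' @param deviations matrix (or single vector) of deviation vectors.
#' @param k number of anchor neighbors (default 1).
#' @return numeric matrix of embedded coordinates, one row per input row.
#' @export
project <- function(model, deviations, k = 1L) {
  if (!inherits(model, "manifold_model") || is.null(model$coords))
    stop_oncotwin("manifold model is not fitted",
                  class = "oncotwin_state_error")
  if (is.null(dim(deviations))) deviations <- matrix(deviations, nrow = 1)
  d2 <- pdist2(deviations, model$train_deviations)
  k <- min(k, ncol(d2))
  out <- matrix(0, nrow(deviations), ncol(model$coords))
  for (i in seq_len(nrow(deviations))) {
    nn <- order(d2[i, ])[seq_len(k)]
    dd <- d2[i, nn]
    if (dd[1] < 1e-12) {
      out[i, ] <- model$coords[nn[1], ]
    } else {
      w <- 1 / dd
      out[i, ] <- colSums(model$coords[nn, , drop = FALSE] * w) / sum(w)
    }
  }
  colnames(out) <- colnames(model$coords)
  out
}

#' Static manifold views colored by cluster prognosis
#'
#' Draws the three pairwise 2D views of the 3D manifold, colored by each
#' cluster's observed 5-year mortality (green below 20\%, orange
#' intermediate, red at or above 35\%); an optional new patient is marked
#' with a black star.
#'
#' @param x a clustered \code{\link{fit_clusters}} model.
#' @param cohort cohort used for mortality coloring (optional).
#' @param new_point optional 3D coordinate of a projected patient.
#' @param ... passed to \code{plot}.
#' @export
plot.manifold_model <- function(x, cohort = NULL, new_point = NULL, ...) {
  co <- x$coords
  cols <- "grey40"
  if (!is.null(x$cluster_labels)) {
    if (!is.null(cohort)) {
      s <- summarize_clusters(x, cohort)
      pal <- c(good = "forestgreen", intermediate = "darkorange",
               poor = "firebrick", minor = "grey60")
      cols <- pal[s$prognosis_label[match(x$cluster_labels, s$cluster_id)]]
    } else {
      cols <- grDevices::hcl.colors(max(x$cluster_labels),
                                    "Dark 3")[x$cluster_labels]
    }
  }
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (pr in list(c(1, 2), c(1, 3), c(2, 3))) {
    graphics::plot(co[, pr[1]], co[, pr[2]], col = cols, pch = 16,
                   cex = 0.6, xlab = colnames(co)[pr[1]],
                   ylab = colnames(co)[pr[2]], ...)
    if (!is.null(new_point))
      graphics::points(new_point[pr[1]], new_point[pr[2]], pch = 8,
                       cex = 2, lwd = 2)
  }
  invisible(x)
}
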