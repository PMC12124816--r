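# Mean-shift density clustering with a Gaussian kernel.  Every point is
# iterated up the kernel-density gradient of the fixed data sample; the
# converged modes are merged by single linkage at half the bandwidth and
# clusters are relabelled in order of decreasing size.

#' Bandwidth from the pairwise-distance quantile rule
#'
#' The mean-shift kernel bandwidth is estimated as a quantile of the
#' pairwise Euclidean distances, computed on a deterministic subsample of
#' at most \code{max_points} points (evenly spaced through the data).
#'
#' @param X numeric matrix of points.
#' @param quantile quantile of pairwise distances (default 0.1).
#' @param max_points subsample cap for the distance computation.
#' @return a positive bandwidth.
#' @export
bandwidth_quantile <- function(X, quantile = 0.1, max_points = 1000L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n > max_points)
    X <- X[round(seq(1, n, length.out = max_points)), , drop = FALSE]
  d <- stats::dist(X)
  h <- stats::quantile(d, quantile, names = FALSE)
  if (!is.finite(h) || h <= 0) h <- max(stats::quantile(d, 0.5), 1e-8)
  h
}

mean_shift <- function(X, bandwidth, max_iter = 300L, tol = 1e-4) {
  X <- as.matrix(X)
  n <- nrow(X)
  h2 <- 2 * bandwidth^2
  Y <- X
  for (it in seq_len(max_iter)) {
    W <- exp(-pdist2(Y, X) / h2)
    Ynew <- (W %*% X) / rowSums(W)
    shift <- sqrt(max(rowSums((Ynew - Y)^2)))
    Y <- Ynew
    if (shift < tol * bandwidth) break
  }
  # merge converged modes: single linkage at bandwidth/2
  if (n == 1) {
    labels <- 1L
  } else {
    hc <- stats::hclust(stats::dist(Y), method = "single")
    labels <- stats::cutree(hc, h = bandwidth / 2)
  }
  # relabel by decreasing cluster size (ties by first appearance)
  sizes <- table(labels)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(ord)
  labels <- relabel[labels]
  list(labels = labels, modes = Y, bandwidth = bandwidth)
}
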