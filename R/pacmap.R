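# Pairwise-controlled manifold approximation (PaCMAP), implemented in
# vectorized base R.  Three pair families (nearest neighbors selected on
# locally scaled distances, mid-near pairs, further pairs) are optimized
# with Adam under the published three-phase weight schedule.

pacmap_select_pairs <- function(X, n_neighbors, mn_ratio, fp_ratio) {
  n <- nrow(X)
  d2 <- pdist2(X, X)
  diag(d2) <- Inf
  # local scale: mean squared distance to the 4th-6th nearest neighbor
  sig <- vapply(seq_len(n), function(i) {
    s <- sort(d2[i, ], partial = 6)[4:6]
    mean(s)
  }, numeric(1))
  sig[sig <= 0] <- 1e-10
  scaled <- d2 / outer(sig, sig, function(a, b) sqrt(a * b))
  nb <- t(vapply(seq_len(n), function(i)
    order(scaled[i, ])[seq_len(n_neighbors)], integer(n_neighbors)))
  pairs_nb <- cbind(rep(seq_len(n), n_neighbors), as.vector(nb))

  n_mn <- max(1L, round(n_neighbors * mn_ratio))
  # further pairs cannot exceed the available non-neighbor points
  n_fp <- max(1L, min(round(n_neighbors * fp_ratio),
                      n - n_neighbors - 1L))
  mn_j <- matrix(0L, n, n_mn)
  fp_j <- matrix(0L, n, n_fp)
  for (i in seq_len(n)) {
    for (m in seq_len(n_mn)) {
      cand <- sample.int(n, min(6L, n - 1L))
      cand <- cand[cand != i]
      # second-closest of the sampled candidates
      ord <- cand[order(d2[i, cand])]
      mn_j[i, m] <- ord[min(2L, length(ord))]
    }
    pool <- setdiff(sample.int(n, n), c(i, nb[i, ]))
    fp_j[i, ] <- pool[seq_len(n_fp)]
  }
  list(nb = pairs_nb,
       mn = cbind(rep(seq_len(n), n_mn), as.vector(mn_j)),
       fp = cbind(rep(seq_len(n), n_fp), as.vector(fp_j)))
}

# accumulate per-pair gradient contributions into the n x d gradient
accumulate_grad <- function(grad, idx, contrib) {
  g <- rowsum(contrib, idx)
  rows <- as.integer(rownames(g))
  grad[rows, ] <- grad[rows, ] + g
  grad
}

pacmap_weights <- function(iter, n_iters_phase = c(100, 100, 250)) {
  p1 <- n_iters_phase[1]; p2 <- p1 + n_iters_phase[2]
  if (iter <= p1) {
    t <- iter / p1
    c(nb = 2, mn = 1000 * (1 - t) + 3 * t, fp = 1)
  } else if (iter <= p2) {
    c(nb = 3, mn = 3, fp = 1)
  } else {
    c(nb = 1, mn = 0, fp = 1)
  }
}

pacmap_fit <- function(X, n_components = 3L, n_neighbors = 10L,
                       mn_ratio = 0.5, fp_ratio = 2, n_iters = 450L,
                       lr = 1, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (!is.null(seed)) set.seed(seed)
  pairs <- pacmap_select_pairs(X, n_neighbors, mn_ratio, fp_ratio)
  # PCA initialization, shrunk
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  Y <- matrix(0, n, n_components)
  Y[, seq_len(k)] <- pc$x[, seq_len(k)]
  Y <- Y * 0.01
  if (k < n_components)
    Y[, (k + 1):n_components] <- matrix(stats::rnorm(n * (n_components - k),
                                                     sd = 1e-4),
                                        n, n_components - k)
  m <- matrix(0, n, n_components); v <- matrix(0, n, n_components)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-7
  for (it in seq_len(n_iters)) {
    w <- pacmap_weights(it)
    grad <- matrix(0, n, n_components)
    for (fam in c("nb", "mn", "fp")) {
      p <- pairs[[fam]]
      diff <- Y[p[, 1], , drop = FALSE] - Y[p[, 2], , drop = FALSE]
      dt <- rowSums(diff^2) + 1
      coef <- switch(fam,
        nb = w["nb"] * 20 / (10 + dt)^2,
        mn = w["mn"] * 20000 / (10000 + dt)^2,
        fp = -w["fp"] * 2 / (1 + dt)^2)
      contrib <- diff * coef
      grad <- accumulate_grad(grad, p[, 1], contrib)
      grad <- accumulate_grad(grad, p[, 2], -contrib)
    }
    m <- b1 * m + (1 - b1) * grad
    v <- b2 * v + (1 - b2) * grad^2
    mhat <- m / (1 - b1^it)
    vhat <- v / (1 - b2^it)
    Y <- Y - lr * mhat / (sqrt(vhat) + eps)
  }
  dimnames(Y) <- list(rownames(X), paste0("dim", seq_len(n_components)))
  Y
}
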