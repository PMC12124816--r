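# Internal numeric helpers shared across modules.

# Squared Euclidean distances between rows of A (m x d) and rows of B (n x d).
pdist2 <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# Truncated normal sampler (lower truncation only) via inverse-CDF.
rtnorm_lower <- function(n, mean, sd, lower) {
  plo <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, plo, 1)
  # guard against u == 1 rounding
  u <- pmin(u, 1 - 1e-12)
  stats::qnorm(u, mean, sd)
}

# Adjusted Rand index between two label vectors.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sx <- sum(choose(rowSums(tab), 2))
  sy <- sum(choose(colSums(tab), 2))
  sxy <- sum(choose(tab, 2))
  expected <- sx * sy / choose(n, 2)
  denom <- (sx + sy) / 2 - expected
  if (denom == 0) return(1)
  (sxy - expected) / denom
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_oncotwin <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "oncotwin_error")))
}
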