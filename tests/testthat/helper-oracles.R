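# Independent brute-force oracles used to freeze expected values.

# AUC by exhaustive case-control pair counting
auc_pairs_oracle <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  tot <- 0
  for (x in cs) for (y in ct) {
    tot <- tot + (x > y) + 0.5 * (x == y)
  }
  tot / (length(cs) * length(ct))
}

# DeLong structural components by the naive O(n^2) psi kernel
delong_oracle <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  psi <- outer(cs, ct, function(x, y) (x > y) + 0.5 * (x == y))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  list(v10 = v10, v01 = v01, auc = mean(psi),
       var = stats::var(v10) / length(cs) + stats::var(v01) / length(ct))
}

# exact two-sided signed-rank p by enumeration over all sign assignments
wilcoxon_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Youden threshold by exhaustive scan over all candidate cut points
youden_oracle <- function(probs, labels) {
  cand <- sort(unique(probs))
  best_j <- -Inf; best_t <- cand[1]
  for (t in cand) {
    sens <- mean(probs[labels == 1] >= t)
    spec <- mean(probs[labels == 0] < t)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) { best_j <- j; best_t <- t }
  }
  best_t
}

# monotone-map inversion by bisection, independent of the closed form
physical_dose_bisect_oracle <- function(target, n, ab = 3, tol = 1e-12) {
  f <- function(D) D * (D / n + ab) / (2 + ab) - target
  lo <- 1e-9; hi <- 1000
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
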