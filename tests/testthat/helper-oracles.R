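# Shared fixtures and independent oracles for the test suite.

# 1D toy geometry used across the low-level tests: samples {0,1,2,3},
# grid {0.5, 2.5}. Nearest-grid distances are all 0.5, so h = 0.5.
toyCoords <- function() matrix(c(0, 1, 2, 3), ncol = 1)
toyGrid <- function() matrix(c(0.5, 2.5), ncol = 1)

# Brute-force KL divergence: explicit term-by-term loop, 0 log 0 := 0.
klOracle <- function(p, q) {
  total <- 0
  for (j in seq_along(p)) {
    if (p[j] > 0) total <- total + p[j] * log(p[j] / q[j])
  }
  total
}

# Scalar-formula density oracle: no matrix algebra shared with the package.
densityOracle <- function(coords, grid, h) {
  out <- matrix(0, nrow(coords), nrow(grid))
  for (i in seq_len(nrow(coords))) {
    for (j in seq_len(nrow(grid))) {
      d <- sqrt(sum((coords[i, ] - grid[j, ])^2)) / h
      out[i, j] <- exp(-d^2 / 2)
    }
  }
  out
}

# Per-feature D_KL via the scalar path (computePf + klOracle), used to
# cross-check the vectorized sparse product.
dklLoopOracle <- function(density, activity) {
  q <- colSums(density) / sum(colSums(density))
  vapply(seq_len(nrow(activity)), function(f) {
    y <- as.numeric(activity[f, ])
    if (sum(y) == 0) return(NA_real_)
    p <- as.numeric(crossprod(density, y))
    klOracle(p / sum(p), q)
  }, numeric(1))
}

# Mann-Whitney AUROC of a score for separating positives from negatives.
auroc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Adjusted Rand index between two labellings (closed-form from the
# contingency table).
ariOracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  sumi <- sum(choose(rowSums(tab), 2))
  sumj <- sum(choose(colSums(tab), 2))
  expected <- sumi * sumj / choose(n, 2)
  maxidx <- (sumi + sumj) / 2
  (sumij - expected) / (maxidx - expected)
}

# All permutations of 1..n (n small), for exhaustive permutation-null checks.
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- allPermutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Planted-vs-null truth vector aligned to a result table.
truthFlag <- function(tab, truth) {
  truth$label[match(tab$feature_id, truth$feature_id)] == "planted"
}
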