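# Quasi-variance objective evaluated for an arbitrary candidate solution,
# for comparing the package optimizer against the Nelder-Mead oracle.
qvar_objective <- function(contrast_cov) {
  V <- as.matrix(contrast_cov)
  m <- ncol(V)
  K <- m + 1
  D <- matrix(0, K, K)
  D[1, -1] <- diag(V); D[-1, 1] <- diag(V)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j) D[i + 1, j + 1] <- V[i, i] + V[j, j] - 2 * V[i, j]
  }
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  logd <- log(D[pairs])
  function(v) sum((log(v[pairs[, 1]] + v[pairs[, 2]]) - logd)^2)
}

# The target pairwise contrast variances, in upper-triangle column-major
# order (the same order as outer(v, v, "+")[upper.tri(...)]).
qvar_pairwise <- function(contrast_cov) {
  V <- as.matrix(contrast_cov)
  m <- ncol(V)
  K <- m + 1
  D <- matrix(0, K, K)
  D[1, -1] <- diag(V); D[-1, 1] <- diag(V)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j) D[i + 1, j + 1] <- V[i, i] + V[j, j] - 2 * V[i, j]
  }
  D[upper.tri(D)]
}
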