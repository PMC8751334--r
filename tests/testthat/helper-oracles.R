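# Independent test oracles, kept deliberately naive.

# Adjusted Rand index by exhaustive pair counting.
ari_bruteforce <- function(a, b) {
  n <- length(a)
  s_ab <- s_a <- s_b <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      s_ab <- s_ab + (same_a && same_b)
      s_a <- s_a + same_a
      s_b <- s_b + same_b
    }
  }
  total <- n * (n - 1) / 2
  expected <- s_a * s_b / total
  max_index <- (s_a + s_b) / 2
  if (max_index == expected) return(0)
  (s_ab - expected) / (max_index - expected)
}

# Mean silhouette by direct definition (1-D, Euclidean).
silhouette_bruteforce <- function(x, labels) {
  n <- length(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) mean(abs(x[own] - x[i])[which(own) != i]) else 0
    b <- min(vapply(unique(labels[!own]), function(g) {
      mean(abs(x[labels == g] - x[i]))
    }, numeric(1)))
    s[i] <- if (sum(own) > 1) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# Leading singular triplet via eigendecomposition of the Gram matrix
# (independent of the package's svd path).
leading_triplet <- function(m) {
  e <- eigen(crossprod(m), symmetric = TRUE)
  v <- e$vectors[, 1]
  u <- m %*% v
  list(lambda = e$values[1] / nrow(m), u = u / sqrt(sum(u^2)), v = v)
}

standardized_noise <- function(n_genes, n_cells, seed) {
  m <- withr::with_seed(seed, matrix(rnorm(n_genes * n_cells), n_genes, n_cells))
  standardize_expression(m)
}
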