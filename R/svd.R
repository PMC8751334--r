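#' Scaled singular value decomposition of a processed expression matrix
#'
#' Thin SVD with singular values divided by `sqrt(N_genes)` so the noise
#' bulk matches MP edges `1 +/- sqrt(c)`, `c = N_cells / N_genes`. If the
#' matrix has fewer genes than cells it is transposed internally so the
#' larger axis always plays the "gene" role in the random-matrix formulas;
#' `transposed` records the swap and the returned `u_gene` / `v_cell`
#' always index the *original* gene and cell axes.
#'
#' @param x Numeric matrix, genes in rows and cells in columns, finite
#'   entries (typically the output of [standardize_expression()]).
#' @return An object of class `scaled_svd`: list with `gamma` (non-increasing
#'   scaled singular values), `u_gene`, `v_cell` (unit-norm singular vectors
#'   over genes and cells), `c`, `n_genes`, `n_cells`, `n_major` (the
#'   scaling dimension) and `transposed`.
#' @examples
#' s <- scaled_svd(matrix(rnorm(350 * 201), 350, 201))
#' max(s$gamma)  # near 1 + sqrt(201/350) for pure noise
#' @export
scaled_svd <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop_phiclust("`x` must be a numeric matrix")
  if (any(!is.finite(x))) stop_phiclust("`x` contains non-finite entries")
  transposed <- nrow(x) < ncol(x)
  m <- if (transposed) t(x) else x
  n_major <- nrow(m)
  n_minor <- ncol(m)
  s <- svd(m)
  gamma <- s$d / sqrt(n_major)
  u_major <- s$u
  v_minor <- s$v
  # sign convention: the largest-magnitude entry of each minor-axis
  # (cell-side when not transposed) vector is positive
  flip <- vapply(seq_len(ncol(v_minor)), function(i) {
    v <- v_minor[, i]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  v_minor <- sweep(v_minor, 2, flip, `*`)
  u_major <- sweep(u_major, 2, flip, `*`)
  out <- list(
    gamma = gamma,
    u_gene = if (transposed) v_minor else u_major,
    v_cell = if (transposed) u_major else v_minor,
    c = n_minor / n_major,
    n_genes = nrow(x),
    n_cells = ncol(x),
    n_major = n_major,
    transposed = transposed
  )
  rownames(out$u_gene) <- rownames(x)
  rownames(out$v_cell) <- colnames(x)
  structure(out, class = "scaled_svd")
}

#' @export
print.scaled_svd <- function(x, ...) {
  cat(sprintf(
    "Scaled SVD: %d genes x %d cells (c = %.4f%s), leading gamma = %.4f\n",
    x$n_genes, x$n_cells, x$c, if (x$transposed) ", transposed" else "",
    x$gamma[1]
  ))
  invisible(x)
}

#' Reconstruct the matrix underlying a scaled SVD
#' @param s A `scaled_svd` object.
#' @return The reconstructed genes x cells matrix.
#' @keywords internal
#' @export
reconstruct_svd <- function(s) {
  m <- sqrt(s$n_major) *
    (if (s$transposed) s$v_cell else s$u_gene) %*%
    (s$gamma * t(if (s$transposed) s$u_gene else s$v_cell))
  if (s$transposed) t(m) else m
}
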