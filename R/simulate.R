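# Synthetic-data generators. These define the study conditions under which
# the measure is exercised: planted rank-one signals in i.i.d. noise,
# gamma-Poisson multi-group counts, weighted mixtures of cleaned cluster
# profiles, smooth differentiation paths, and a multiplicative-noise
# variant. All generators are bit-reproducible under `seed` and record the
# ground truth they plant.

#' Planted rank-one signal in i.i.d. noise
#'
#' Noise matrix `X` (i.i.d. standard normal, or Poisson(1) centered and
#' scaled entrywise to mean 0 / variance 1) plus a rank-one signal
#' `sqrt(n_genes) * theta * u v'`, where the cell vector `v` has
#' `pos_cells` entries `+1/sqrt(n_cells)` and the rest negative, and the
#' gene vector `u` analogously with `pos_genes`. In the scaled spectrum the
#' planted component has singular value `theta`; defaults give the
#' 350 x 201 two-population geometry with 67 positive cells and 200
#' positive genes.
#'
#' @param n_genes,n_cells Matrix dimensions.
#' @param theta Planted signal singular value (>= 0; 0 = pure noise).
#' @param noise `"normal"` or `"poisson"`.
#' @param pos_cells,pos_genes Sizes of the positive blocks.
#' @param seed Integer seed.
#' @return A list of class `phiclust_sim`: `matrix`, `labels` (tibble,
#'   pos/neg per cell), `true_theta`, unit-norm `u`/`v`, `generator`.
#' @export
simulate_planted_rank_one <- function(n_genes = 350L, n_cells = 201L,
                                      theta = 2, noise = c("normal", "poisson"),
                                      pos_cells = 67L, pos_genes = 200L,
                                      seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(pos_cells < n_cells, pos_genes < n_genes, theta >= 0)
  v <- c(rep(1, pos_cells), rep(-1, n_cells - pos_cells)) / sqrt(n_cells)
  u <- c(rep(1, pos_genes), rep(-1, n_genes - pos_genes)) / sqrt(n_genes)
  x <- with_seed(seed, {
    if (noise == "normal") {
      matrix(stats::rnorm(n_genes * n_cells), n_genes, n_cells)
    } else {
      matrix(stats::rpois(n_genes * n_cells, 1) - 1, n_genes, n_cells)
    }
  })
  m <- x + sqrt(n_genes) * theta * tcrossprod(u, v)
  dimnames(m) <- list(paste0("gene", seq_len(n_genes)),
                      paste0("cell", seq_len(n_cells)))
  structure(
    list(
      matrix = m,
      labels = tibble::tibble(
        cell_id = colnames(m),
        cluster = rep(c("pos", "neg"), c(pos_cells, n_cells - pos_cells))
      ),
      true_theta = theta, u = u, v = v,
      generator = paste0("planted_rank_one/", noise)
    ),
    class = "phiclust_sim"
  )
}

#' Add a planted rank-one signal to an existing processed matrix
#'
#' Cell vector: two-block `+/- 1/sqrt(n_cells)` with a third of the cells
#' positive by default; gene vector: standard normal draws normalized to
#' unit length. Adds `sqrt(n_genes) * theta * u v'`, producing one extra
#' outlying singular value near the forward map of `theta`.
#'
#' @param x Processed (standardized) matrix, genes x cells.
#' @param theta Signal singular value; 0 returns `x` unchanged.
#' @param pos_cells Positive block size (default `round(n_cells / 3)`).
#' @param seed Integer seed (gene vector draw).
#' @return List: `matrix`, `u`, `v`, `true_theta`.
#' @export
add_planted_signal <- function(x, theta, pos_cells = NULL, seed = 1L) {
  n_genes <- nrow(x); n_cells <- ncol(x)
  pos_cells <- pos_cells %||% round(n_cells / 3)
  v <- c(rep(1, pos_cells), rep(-1, n_cells - pos_cells)) / sqrt(n_cells)
  u <- with_seed(seed, stats::rnorm(n_genes))
  u <- u / sqrt(sum(u^2))
  list(
    matrix = x + sqrt(n_genes) * theta * tcrossprod(u, v),
    u = u, v = v, true_theta = theta
  )
}

#' Gamma-Poisson multi-group count simulator
#'
#' Generative stand-in for Splatter-style group simulations: gene base
#' means are Gamma(shape, rate); per group each gene is differentially
#' expressed with probability `de_prob`, its mean multiplied by a
#' log-normal factor `exp(N(de_loc, de_scale^2))`, inverted with
#' probability 1/2; group means are renormalized to proportions; per-cell
#' library sizes are log-normal; counts are Poisson(library x proportion).
#' No BCV trend or dropout model: the downstream claims are at the
#' random-matrix level and only need group-structured overdispersed counts
#' whose preprocessed bulk is MP-consistent.
#'
#' @param n_genes,n_cells Dimensions of the count matrix.
#' @param n_groups Number of groups.
#' @param group_prob Group proportions (sum to 1; default equal).
#' @param de_prob Per-gene probability of differential expression per group.
#' @param de_loc,de_scale Log-normal DE factor parameters. The default
#'   `de_loc` is the package's fixture value for the DE-factor strength.
#' @param mean_shape,mean_rate Gamma parameters of the gene base means.
#' @param lib_loc,lib_scale Log-normal library-size parameters.
#' @param seed Integer seed.
#' @return A `phiclust_sim` list: integer `counts`, `labels` tibble,
#'   `group_means` (genes x groups proportion matrix), `de_genes` (list of
#'   per-group DE indices), `generator`.
#' @export
simulate_groups <- function(n_genes = 2000L, n_cells = 500L, n_groups = 2L,
                            group_prob = rep(1 / n_groups, n_groups),
                            de_prob = 0.1, de_loc = 0.6, de_scale = 0.4,
                            mean_shape = 0.6, mean_rate = 0.3,
                            lib_loc = log(5000), lib_scale = 0.2,
                            seed = 1L) {
  stopifnot(length(group_prob) == n_groups,
            abs(sum(group_prob) - 1) < 1e-8,
            all(group_prob > 0), de_prob >= 0, de_prob <= 1)
  with_seed(seed, {
    base <- stats::rgamma(n_genes, shape = mean_shape, rate = mean_rate)
    de_genes <- vector("list", n_groups)
    group_means <- matrix(base, n_genes, n_groups)
    for (k in seq_len(n_groups)) {
      de <- which(stats::runif(n_genes) < de_prob)
      de_genes[[k]] <- de
      if (length(de)) {
        fac <- exp(stats::rnorm(length(de), de_loc, de_scale))
        inv <- stats::runif(length(de)) < 0.5
        fac[inv] <- 1 / fac[inv]
        group_means[de, k] <- group_means[de, k] * fac
      }
    }
    prop <- sweep(group_means, 2, colSums(group_means), `/`)
    grp <- sample(rep(seq_len(n_groups), round(group_prob * n_cells))[seq_len(n_cells)])
    libs <- exp(stats::rnorm(n_cells, lib_loc, lib_scale))
    counts <- matrix(0L, n_genes, n_cells)
    for (j in seq_len(n_cells)) {
      counts[, j] <- stats::rpois(n_genes, libs[j] * prop[, grp[j]])
    }
    dimnames(counts) <- list(paste0("gene", seq_len(n_genes)),
                             paste0("cell", seq_len(n_cells)))
    structure(
      list(
        counts = counts,
        labels = tibble::tibble(cell_id = colnames(counts),
                                cluster = paste0("group", grp)),
        group_means = prop, de_genes = de_genes,
        generator = "splatter_lite"
      ),
      class = "phiclust_sim"
    )
  })
}

#' Weighted mixture of two cleaned cluster profiles
#'
#' Emulates controlled cluster similarity: each source matrix is "cleaned"
#' by moving above-threshold singular values down to the bulk upper edge
#' and restoring the transcriptome mode above the bulk (fixed at twice the
#' upper edge), then two synthetic clusters are built as weighted averages
#' of source cells (drawn without replacement, so each source needs at
#' least `2 * n_cells_per_cluster` cells): cluster 1 mixes `alpha` of A with
#' `1 - alpha` of B, cluster 2 flips the weights. `alpha = 0.5` makes both
#' clusters identically distributed (phiclust ~ 0); `alpha` near 0 or 1
#' maximally different.
#'
#' @param source_a,source_b Processed (standardized) matrices sharing the
#'   gene axis.
#' @param alpha Mixing weight in `[0, 1]`.
#' @param n_cells_per_cluster Cells per synthetic cluster (default 150).
#' @param seed Integer seed.
#' @return A `phiclust_sim` list: `matrix` (genes x 2 * n_cells_per_cluster),
#'   `labels` tibble (`mix1` / `mix2`), `alpha`, `generator`.
#' @export
simulate_weighted_mixture <- function(source_a, source_b, alpha,
                                      n_cells_per_cluster = 150L, seed = 1L) {
  if (nrow(source_a) != nrow(source_b)) {
    stop_phiclust("source matrices must share the gene axis")
  }
  if (alpha < 0 || alpha > 1) stop_phiclust("`alpha` must lie in [0, 1]")
  a <- clean_cluster_matrix(source_a)
  b <- clean_cluster_matrix(source_b)
  n <- n_cells_per_cluster
  if (ncol(a) < 2 * n || ncol(b) < 2 * n) {
    stop_phiclust("each source needs at least 2 * n_cells_per_cluster cells ",
                  "(cells are drawn without replacement so the synthetic ",
                  "cells stay independent)")
  }
  with_seed(seed, {
    ia <- sample(ncol(a), 2 * n)
    ib <- sample(ncol(b), 2 * n)
    m1 <- alpha * a[, ia[1:n]] + (1 - alpha) * b[, ib[1:n]]
    m2 <- (1 - alpha) * a[, ia[(n + 1):(2 * n)]] + alpha * b[, ib[(n + 1):(2 * n)]]
    m <- cbind(m1, m2)
    dimnames(m) <- list(rownames(source_a) %||% paste0("gene", seq_len(nrow(m))),
                        paste0("cell", seq_len(2 * n)))
    structure(
      list(
        matrix = m,
        labels = tibble::tibble(cell_id = colnames(m),
                                cluster = rep(c("mix1", "mix2"), each = n)),
        alpha = alpha, generator = "weighted_mixture"
      ),
      class = "phiclust_sim"
    )
  })
}

# Remove deterministic structure from a processed cluster matrix: singular
# values above the TW threshold are set to the bulk upper edge; the
# transcriptome mode (smallest singular value) is restored above the bulk
# at twice the upper edge, mimicking the spectrum of an unscaled matrix.
clean_cluster_matrix <- function(x) {
  s <- scaled_svd(x)
  mp <- mp_model(s$n_major, round(s$c * s$n_major))
  g <- s$gamma
  g[g^2 > mp$tw_lambda_star] <- mp$gamma_plus
  g[which.min(s$gamma)] <- 2 * mp$gamma_plus
  s$gamma <- g
  reconstruct_svd(s)
}

#' Smooth differentiation path
#'
#' A rank-one expression gradient along a latent cell ordering: noise plus
#' `sqrt(n_genes) * strength * u w'`, where `w` is the centered, unit-norm
#' latent ordering (recorded as `pseudotime`) and `u` a random unit gene
#' vector. Cells are shuffled so column order carries no information.
#'
#' @param n_genes,n_cells Dimensions.
#' @param gradient_strength Signal singular value of the gradient (>= 0).
#' @param seed Integer seed.
#' @return A `phiclust_sim` list: `matrix`, `pseudotime` tibble
#'   (`cell_id`, `pseudotime`), `true_theta`, `generator`.
#' @export
simulate_differentiation_path <- function(n_genes = 1500L, n_cells = 400L,
                                          gradient_strength = 3, seed = 1L) {
  stopifnot(gradient_strength >= 0)
  with_seed(seed, {
    t_latent <- sample(seq(0, 1, length.out = n_cells))
    w <- t_latent - mean(t_latent)
    w <- w / sqrt(sum(w^2))
    u <- stats::rnorm(n_genes)
    u <- u / sqrt(sum(u^2))
    m <- matrix(stats::rnorm(n_genes * n_cells), n_genes, n_cells) +
      sqrt(n_genes) * gradient_strength * tcrossprod(u, w)
    dimnames(m) <- list(paste0("gene", seq_len(n_genes)),
                        paste0("cell", seq_len(n_cells)))
    structure(
      list(
        matrix = m,
        pseudotime = tibble::tibble(cell_id = colnames(m),
                                    pseudotime = t_latent),
        true_theta = gradient_strength,
        generator = "differentiation_path"
      ),
      class = "phiclust_sim"
    )
  })
}

#' Multiplicative-noise planted signal
#'
#' `X~ = (I + P)^(1/2) X` with a rank-one square signal `P` acting in gene
#' space and `X` i.i.d. standard normal. `theta` is specified in the units
#' of the scaled spectrum (the ones [theta_multiplicative()] recovers), so
#' the planted population spike is `theta / c`; for large `theta` the
#' leading scaled eigenvalue approaches `theta`. The bulk of the scaled
#' spectrum still follows the MP law.
#'
#' @param n_genes,n_cells Dimensions.
#' @param theta Signal eigenvalue (>= 0).
#' @param seed Integer seed.
#' @return A `phiclust_sim` list: `matrix`, `true_theta`, `u`, `generator`.
#' @export
simulate_multiplicative <- function(n_genes = 350L, n_cells = 201L,
                                    theta = 5, seed = 1L) {
  stopifnot(theta >= 0)
  with_seed(seed, {
    u <- stats::rnorm(n_genes)
    u <- u / sqrt(sum(u^2))
    x <- matrix(stats::rnorm(n_genes * n_cells), n_genes, n_cells)
    # population spike in covariance units; (I + s u u')^(1/2) =
    # I + (sqrt(1 + s) - 1) u u'
    s_pop <- theta * n_genes / n_cells
    m <- x + (sqrt(1 + s_pop) - 1) * tcrossprod(u, crossprod(x, u))
    dimnames(m) <- list(paste0("gene", seq_len(n_genes)),
                        paste0("cell", seq_len(n_cells)))
    structure(
      list(matrix = m, true_theta = theta, u = u,
           generator = "multiplicative_planted"),
      class = "phiclust_sim"
    )
  })
}

#' @export
print.phiclust_sim <- function(x, ...) {
  m <- x$matrix %||% x$counts
  cat(sprintf("phiclust simulation (%s): %d genes x %d cells\n",
              x$generator, nrow(m), ncol(m)))
  invisible(x)
}
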