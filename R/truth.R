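# Ground-truth validation oracle: the theoretically achievable clustering
# quality. With known labels, an approximate Bayes classifier on the
# outlying singular-vector coordinates gives the minimal misclassification
# rate; its ARI (tARI) is the ceiling no empirical clustering algorithm
# can systematically exceed, and phiclust should track it.

#' Approximate Bayes classification on outlying singular vectors
#'
#' Fits one multivariate Gaussian (maximum-likelihood mean and full
#' covariance; diagonal fallback when a cluster has fewer cells than
#' dimensions + 2) per ground-truth cluster on the coordinates of cells in
#' the singular vectors whose singular values exceed the Tracy-Widom
#' threshold, then assigns each cell to the cluster with the highest fitted
#' density (ties toward the larger cluster). With no outlying vector the
#' classifier is undefined and all cells are assigned to one cluster.
#'
#' @param svd A [scaled_svd()] object of the full (multi-group) matrix.
#' @param mp The matching [mp_model()].
#' @param labels Ground-truth labels (vector in cell order).
#' @return Character vector of predicted labels.
#' @export
bayes_classify <- function(svd, mp, labels) {
  stopifnot(inherits(svd, "scaled_svd"), inherits(mp, "mp_model"))
  labels <- as.character(labels)
  if (length(labels) != nrow(svd$v_cell)) stop_phiclust("label length mismatch")
  if (length(unique(labels)) < 2) stop_phiclust("need >= 2 ground-truth clusters")
  idx <- which(svd$gamma^2 > mp$tw_lambda_star)
  sizes <- sort(table(labels), decreasing = TRUE)
  if (!length(idx)) {
    return(rep(names(sizes)[1], length(labels)))
  }
  coords <- svd$v_cell[, idx, drop = FALSE]
  d <- ncol(coords)
  groups <- names(sizes) # decreasing size = tie-break order
  logdens <- vapply(groups, function(g) {
    xg <- coords[labels == g, , drop = FALSE]
    mu <- colMeans(xg)
    if (nrow(xg) < d + 2) {
      warning("cluster '", g, "' smaller than dimensions + 2; ",
              "using diagonal covariance", call. = FALSE)
      sig <- diag(pmax(apply(xg, 2, stats::var), 1e-12), d)
    } else {
      sig <- stats::cov(xg) * (nrow(xg) - 1) / nrow(xg)
    }
    mvn_logdens(coords, mu, sig)
  }, numeric(nrow(coords)))
  groups[max.col(logdens, ties.method = "first")]
}

mvn_logdens <- function(x, mu, sigma) {
  d <- length(mu)
  ch <- tryCatch(chol(sigma), error = function(e) {
    chol(sigma + diag(1e-10, d))
  })
  z <- forwardsolve(t(ch), t(x) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

#' Adjusted Rand index
#'
#' Permutation-invariant agreement between two labelings (1 = identical
#' partitions, ~0 = chance).
#'
#' @param labels_a,labels_b Label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop_phiclust("label length mismatch")
  mclust::adjustedRandIndex(labels_a, labels_b)
}

#' Mean silhouette on 1-D singular-vector coordinates
#'
#' Standard silhouette with Euclidean distance computed on the first
#' singular vector; used as tSIL when applied to the Bayes classification.
#'
#' @param coords Numeric vector (or 1-column matrix) of coordinates.
#' @param labels Cluster labels.
#' @return Mean silhouette width; NA with a warning for a single cluster.
#' @export
tsil <- function(coords, labels) {
  coords <- as.matrix(coords)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    warning("single predicted cluster; silhouette undefined", call. = FALSE)
    return(NA_real_)
  }
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(coords))
  mean(sil[, "sil_width"])
}

#' Seeded k-means baseline with k-means++ initialization
#'
#' Lloyd's algorithm from `nstart` k-means++ initializations, keeping the
#' solution with the lowest within-cluster sum of squares. Serves as the
#' empirical clustering arm that the tARI must dominate.
#'
#' @param coords Numeric matrix, cells x dimensions.
#' @param k Number of centers (>= 2).
#' @param seed Integer seed.
#' @param nstart Number of restarts (default 10).
#' @return Integer vector of cluster assignments.
#' @export
kmeans_baseline <- function(coords, k = 2L, seed = 1L, nstart = 10L) {
  coords <- as.matrix(coords)
  if (k < 2) stop_phiclust("`k` must be >= 2")
  if (k > nrow(coords)) stop_phiclust("`k` exceeds the number of cells")
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(nstart)) {
      centers <- kmeanspp_init(coords, k)
      fit <- suppressWarnings(
        stats::kmeans(coords, centers = centers, iter.max = 100L,
                      algorithm = "Lloyd")
      )
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    best$cluster
  })
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- x[sample.int(n, 1), , drop = FALSE]
  while (nrow(centers) < k) {
    d2 <- apply(x, 1, function(p) min(colSums((t(centers) - p)^2)))
    prob <- d2 / sum(d2)
    centers <- rbind(centers, x[sample.int(n, 1, prob = prob), , drop = FALSE])
  }
  unname(centers)
}

#' Truth metrics for a simulated data set with known labels
#'
#' Runs the Bayes classifier and baselines on a processed matrix with
#' ground-truth labels and returns tARI, tSIL and the k-means ARI.
#'
#' @param x Processed matrix, genes x cells.
#' @param labels Ground-truth labels in cell order.
#' @param seed Seed for the k-means baseline.
#' @param k Number of clusters for k-means (default: number of true groups).
#' @return A one-row tibble: `tari`, `tsil`, `ari_kmeans`,
#'   `n_components_used`.
#' @export
truth_metrics <- function(x, labels, seed = 1L, k = NULL) {
  s <- scaled_svd(x)
  mp <- mp_model(s$n_major, round(s$c * s$n_major))
  pred <- bayes_classify(s, mp, labels)
  idx <- which(s$gamma^2 > mp$tw_lambda_star)
  tari <- if (length(unique(pred)) < 2) 0 else ari(pred, labels)
  ts <- if (length(unique(pred)) < 2) NA_real_ else tsil(s$v_cell[, 1], pred)
  k <- k %||% length(unique(as.character(labels)))
  ncomp <- min(10L, ncol(s$v_cell))
  km <- kmeans_baseline(s$v_cell[, seq_len(ncomp), drop = FALSE], k = k,
                        seed = seed)
  tibble::tibble(
    tari = tari, tsil = ts, ari_kmeans = ari(km, labels),
    n_components_used = length(idx)
  )
}

#' Validation grid: phiclust versus the theoretically achievable ARI
#'
#' Simulates two-group data over a grid of DE-gene fractions, runs the
#' full phiclust pipeline on each data set treated as a single cluster,
#' computes the truth metrics, and summarizes the collinearity between
#' phiclust and tARI.
#'
#' @param de_probs Grid of DE-gene fractions.
#' @param n_seeds Simulations per grid point.
#' @param n_genes,n_cells Simulation dimensions.
#' @param de_loc DE factor strength (see [simulate_groups()]).
#' @param seed Master seed.
#' @return A list with `grid` (tibble: de_prob, seed, phiclust, tari, tsil,
#'   ari_kmeans) and `pearson_r` (correlation between per-point mean
#'   phiclust and mean tARI across the grid).
#' @export
validate_grid <- function(de_probs = seq(0.01, 0.1, by = 0.01), n_seeds = 5L,
                          n_genes = 1200L, n_cells = 300L, de_loc = 0.6,
                          seed = 1L) {
  rows <- purrr::map(de_probs, function(p) {
    purrr::map(seq_len(n_seeds), function(s) {
      sd_i <- substream(seed, sprintf("grid-%g-%d", p, s))
      sim <- simulate_groups(n_genes = n_genes, n_cells = n_cells,
                             n_groups = 2L, de_prob = p, de_loc = de_loc,
                             seed = sd_i)
      proc <- preprocess_counts(sim$counts)$values
      cfg <- phiclust_config(seed = sd_i)
      fit <- phiclust_one(proc, NULL, cfg)
      tm <- truth_metrics(proc, sim$labels$cluster, seed = sd_i)
      tibble::tibble(
        de_prob = p, seed = s,
        phiclust = fit$cluster$phiclust,
        tari = tm$tari, tsil = tm$tsil, ari_kmeans = tm$ari_kmeans
      )
    })
  })
  grid <- dplyr::bind_rows(purrr::flatten(rows))
  means <- dplyr::summarise(
    dplyr::group_by(grid, de_prob),
    phiclust = mean(phiclust), tari = mean(tari), .groups = "drop"
  )
  r <- if (stats::sd(means$phiclust) > 0 && stats::sd(means$tari) > 0) {
    stats::cor(means$phiclust, means$tari)
  } else {
    NA_real_
  }
  list(grid = grid, pearson_r = r)
}
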