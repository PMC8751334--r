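# broom-style accessors and plots for phiclust fits.

#' Tidy a phiclust fit
#'
#' @param x A `phiclust_fit`.
#' @param ... Unused.
#' @return The per-cluster tibble (one row per cluster).
#' @method tidy phiclust_fit
#' @export
tidy.phiclust_fit <- function(x, ...) {
  x$clusters
}

#' One-line summary of a phiclust fit
#'
#' @param x A `phiclust_fit`.
#' @param ... Unused.
#' @return A one-row tibble: number of clusters, how many carry signal,
#'   the largest phiclust, and the worst adjusted bulk-fit p value.
#' @method glance phiclust_fit
#' @export
glance.phiclust_fit <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$clusters),
    n_clusterable = sum(x$clusters$phiclust > 0),
    max_phiclust = max(x$clusters$phiclust),
    min_bulk_ks_p_adj = min(x$clusters$bulk_ks_p_adj),
    noise_model = x$config$noise_model
  )
}

#' Plot phiclust per cluster
#'
#' Bar chart of phiclust per cluster with asymmetric resampling error bars
#' (when computed).
#'
#' @param object A `phiclust_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phiclust_fit
#' @export
autoplot.phiclust_fit <- function(object, ...) {
  df <- object$clusters
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(cluster_id, -phiclust), y = phiclust
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(phiclust - sigma_minus, 0),
                   ymax = pmin(phiclust + sigma_plus, 1)),
      width = 0.25
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "phiclust") +
    ggplot2::theme_minimal()
}

#' Plot a cluster's singular-value spectrum against the MP law
#'
#' Histogram of the scaled singular values with the MP density, the bulk
#' edges, and the Tracy-Widom threshold; significant components are marked.
#'
#' @param fit A `phiclust_fit`.
#' @param cluster_id Cluster to plot (default: first).
#' @return A ggplot object.
#' @export
plot_spectrum <- function(fit, cluster_id = NULL) {
  stopifnot(inherits(fit, "phiclust_fit"))
  cluster_id <- cluster_id %||% fit$clusters$cluster_id[1]
  s <- fit$svds[[cluster_id]]
  mp <- mp_model(s$n_major, round(s$c * s$n_major), fit$config$alpha_tw)
  grid <- seq(max(mp$gamma_minus, 1e-6), mp$gamma_plus, length.out = 400)
  dens <- tibble::tibble(gamma = grid, density = dmp(grid, s$c))
  sig <- fit$components[fit$components$cluster_id == cluster_id, ]
  ggplot2::ggplot(tibble::tibble(gamma = s$gamma), ggplot2::aes(gamma)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 40, fill = "grey80", color = "grey50") +
    ggplot2::geom_line(data = dens, ggplot2::aes(gamma, density),
                       color = "blue") +
    ggplot2::geom_vline(xintercept = sqrt(mp$tw_lambda_star),
                        color = "red", linetype = 2) +
    ggplot2::geom_point(data = tibble::tibble(gamma = sig$gamma),
                        ggplot2::aes(gamma, 0), shape = 8, color = "red",
                        size = 3) +
    ggplot2::labs(x = "scaled singular value", y = "density",
                  title = paste0("cluster ", cluster_id)) +
    ggplot2::theme_minimal()
}
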