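# The main pipeline: per cluster, preprocess -> scaled SVD -> MP/TW gating
# -> confounder regression -> theta/phi -> phiclust = max phi.

#' Clusterability of cell clusters from random-matrix theory
#'
#' For every cluster in `labels`, runs the full pipeline: preprocessing,
#' scaled SVD, Marchenko-Pastur bulk test, Tracy-Widom outlier detection
#' with a Shapiro-Wilk normality gate, confounder regression on the
#' significant cell-singular vectors, and low-rank perturbation mapping of
#' the corrected singular values to the clusterability angles. phiclust is
#' the largest squared cosine over surviving components (0 when none
#' survive: the within-cluster variability is then consistent with random
#' noise); g-phiclust is the gene-space analogue.
#'
#' @param x Expression matrix, genes x cells. Interpreted per `preprocess`:
#'   `"counts"` (raw counts; normalized, log-transformed, standardized),
#'   `"standardize"` (real-valued; degenerate-gene filter + double
#'   standardization only), or `"none"` (used as-is, e.g. for simulated
#'   matrices that are already in noise units).
#' @param labels Optional data frame with `cell_id`, `cluster` columns, or a
#'   vector of cluster labels in cell order. NULL treats all cells as one
#'   cluster named `"all"`.
#' @param covariates Optional data frame of per-cell nuisance covariates
#'   (see [build_covariates()]); NULL skips confounder regression.
#' @param config A [phiclust_config()].
#' @param preprocess One of `"counts"`, `"standardize"`, `"none"`.
#' @param uncertainty If TRUE, estimate asymmetric error bars by noise
#'   resampling (`config$n_boot` extra SVDs per cluster with significant
#'   components); off by default because of its cost.
#' @return An object of class `phiclust_fit` with tibbles `clusters`
#'   (cluster_id, phiclust, g_phiclust, sigma_plus, sigma_minus, bulk_ks_p,
#'   bulk_ks_p_adj, n_cells, n_genes, c, n_significant, noise_model) and
#'   `components` (per significant component: gamma, gamma_corrected,
#'   theta, phi, phi_gene, sw p values, adjusted R^2), plus the per-cluster
#'   SVDs (for [variance_driving_genes()]) and the config.
#' @examples
#' sim <- simulate_planted_rank_one(theta = 5, seed = 1)
#' fit <- phiclust(sim$matrix, preprocess = "none")
#' fit$clusters$phiclust
#' @export
phiclust <- function(x, labels = NULL, covariates = NULL,
                     config = phiclust_config(),
                     preprocess = c("counts", "standardize", "none"),
                     uncertainty = FALSE) {
  preprocess <- match.arg(preprocess)
  stopifnot(inherits(config, "phiclust_config"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("cell", seq_len(ncol(x)))
  if (is.null(rownames(x))) rownames(x) <- paste0("gene", seq_len(nrow(x)))
  lab <- normalize_labels(labels, colnames(x))
  cluster_ids <- unique(lab$cluster)
  per <- purrr::map(cluster_ids, function(cl) {
    cells <- lab$cell_id[lab$cluster == cl]
    if (length(cells) < 10) {
      stop_phiclust("cluster '", cl, "' has fewer than 10 cells")
    }
    if (length(cells) < config$min_cluster_size_warn) {
      warning("cluster '", cl, "' has ", length(cells), " cells (< ",
              config$min_cluster_size_warn,
              "); the MP bulk fit may be unreliable", call. = FALSE)
    }
    xm <- x[, cells, drop = FALSE]
    mat <- switch(preprocess,
      counts = preprocess_counts(xm)$values,
      standardize = standardize_expression(filter_degenerate(xm)$values),
      none = xm
    )
    cv <- subset_covariates(covariates, cells)
    phiclust_one(mat, cv, config, cluster_id = as.character(cl),
                 uncertainty = uncertainty)
  })
  clusters <- dplyr::bind_rows(purrr::map(per, "cluster"))
  clusters$bulk_ks_p_adj <- stats::p.adjust(clusters$bulk_ks_p, method = "BH")
  components <- dplyr::bind_rows(purrr::map(per, "components"))
  structure(
    list(
      clusters = clusters,
      components = components,
      svds = stats::setNames(purrr::map(per, "svd"), clusters$cluster_id),
      config = config
    ),
    class = "phiclust_fit"
  )
}

normalize_labels <- function(labels, cell_ids) {
  if (is.null(labels)) {
    return(tibble::tibble(cell_id = cell_ids, cluster = "all"))
  }
  if (is.data.frame(labels)) {
    if (!all(c("cell_id", "cluster") %in% names(labels))) {
      stop_phiclust("`labels` needs cell_id and cluster columns")
    }
    unknown <- setdiff(labels$cell_id, cell_ids)
    if (length(unknown)) {
      stop_phiclust("labels contain unknown cell ids: ",
                    paste(utils::head(unknown, 5), collapse = ", "))
    }
    return(tibble::tibble(cell_id = as.character(labels$cell_id),
                          cluster = as.character(labels$cluster)))
  }
  if (length(labels) != length(cell_ids)) {
    stop_phiclust("label vector length must equal the number of cells")
  }
  tibble::tibble(cell_id = cell_ids, cluster = as.character(labels))
}

subset_covariates <- function(covariates, cells) {
  if (is.null(covariates)) return(NULL)
  cov <- as.data.frame(covariates)
  if ("cell_id" %in% names(cov)) {
    cov[cov$cell_id %in% cells, , drop = FALSE]
  } else {
    cov
  }
}

# Core single-cluster computation on an already-processed matrix.
phiclust_one <- function(mat, covariates, config, cluster_id = "all",
                         uncertainty = FALSE) {
  s <- scaled_svd(mat)
  mp <- mp_model(s$n_major, round(s$c * s$n_major), config$alpha_tw)
  ks_p <- ks_bulk_test(
    s, mp, n_mp = config$n_mp_samples,
    seed = substream(config$seed, paste0("mp-sampling-", cluster_id))
  )
  gate <- significant_components(
    s, mp, alpha_sw = config$alpha_sw,
    seed = substream(config$seed, paste0("sw-", cluster_id))
  )
  comp <- compute_components(s, mp, gate, covariates, config)
  phiclust_val <- max_phi(comp$phi, comp$gamma)
  g_phiclust_val <- max_phi(comp$phi_gene, comp$gamma)
  sig <- c(0, 0)
  if (uncertainty) {
    sig <- estimate_uncertainty(
      s, comp[comp$phi > 0, , drop = FALSE], mp, config,
      point_estimate = phiclust_val,
      seed = substream(config$seed, paste0("resampling-", cluster_id))
    )
  }
  cluster <- tibble::tibble(
    cluster_id = cluster_id,
    phiclust = phiclust_val,
    g_phiclust = g_phiclust_val,
    sigma_plus = sig[[1]],
    sigma_minus = sig[[2]],
    bulk_ks_p = ks_p,
    n_cells = s$n_cells,
    n_genes = s$n_genes,
    c = s$c,
    n_significant = sum(comp$phi > 0),
    noise_model = config$noise_model
  )
  if (nrow(comp)) {
    comp$cluster_id <- cluster_id
    comp <- comp[, c("cluster_id", setdiff(names(comp), "cluster_id"))]
  }
  list(cluster = cluster, components = comp, svd = s)
}

# Map gated components through confounder correction and perturbation
# theory. Components whose corrected eigenvalue falls back to or below the
# TW threshold are indistinguishable from noise and get phi = 0.
compute_components <- function(s, mp, gate, covariates, config) {
  empty <- tibble::tibble(
    cluster_id = character(), index = integer(), gamma = numeric(), gamma_corrected = numeric(),
    theta = numeric(), phi = numeric(), phi_gene = numeric(),
    sw_p = numeric(), sw_p_adj = numeric(), adj_r2 = numeric(),
    per_covariate = list()
  )
  sig <- gate[gate$significant, , drop = FALSE]
  if (!nrow(sig)) return(empty)
  reg <- regress_confounders(s, covariates, sig$index)
  gamma_corr <- correct_singular_values(sig$gamma, reg$adj_r2)
  alive <- gamma_corr^2 > mp$tw_lambda_star
  theta <- phi <- phig <- numeric(nrow(sig))
  if (any(alive)) {
    if (config$noise_model == "additive") {
      th <- theta_additive(gamma_corr[alive], s$c)
      pc <- as.numeric(phi_cell(th, s$c))
      pg <- as.numeric(phi_gene(th, s$c))
      if (s$transposed) { tmp <- pc; pc <- pg; pg <- tmp }
    } else {
      th <- theta_multiplicative(gamma_corr[alive]^2, s$c)
      pc <- as.numeric(phi_mult(th, s$c))
      pg <- pc
    }
    theta[alive] <- th
    phi[alive] <- pc
    phig[alive] <- pg
  }
  tibble::tibble(
    index = sig$index, gamma = sig$gamma, gamma_corrected = gamma_corr,
    theta = theta, phi = phi, phi_gene = phig,
    sw_p = sig$sw_p, sw_p_adj = sig$sw_p_adj, adj_r2 = reg$adj_r2,
    per_covariate = reg$per_covariate
  )
}

# max with deterministic tie-break toward the larger gamma (rows are in
# decreasing gamma order, so which.max already resolves ties that way)
max_phi <- function(phi, gamma) {
  if (!length(phi)) return(0)
  max(phi)
}

#' Resampling-based uncertainty of phiclust
#'
#' Approximates the signal matrix as `P^s = sqrt(N) * sum_i theta_i u_i v_i'`
#' over the significant components (singular values replaced by their
#' perturbation-theory estimates theta), adds `n_boot` fresh i.i.d.
#' standard-normal noise matrices, and reruns SVD + gating (no
#' re-preprocessing, no confounder regression) on each draw. Draws where no
#' component survives contribute phiclust = 0, so the spread reflects
#' detection failure near threshold. The asymmetric uncertainty is the
#' standard deviation of resampled values above / below the point estimate.
#'
#' @param s A [scaled_svd()] object.
#' @param components Tibble of surviving components (needs `index`, `theta`).
#' @param mp The [mp_model()] for the cluster.
#' @param config A [phiclust_config()].
#' @param point_estimate The cluster's phiclust.
#' @param seed Seed of the resampling substream.
#' @return `c(sigma_plus, sigma_minus)`; `c(0, 0)` for no components.
#' @export
estimate_uncertainty <- function(s, components, mp, config, point_estimate,
                                 seed = 1L) {
  if (!nrow(components)) return(c(sigma_plus = 0, sigma_minus = 0))
  idx <- components$index
  # build P^s in the internal (major x minor) orientation
  u_major <- if (s$transposed) s$v_cell else s$u_gene
  v_minor <- if (s$transposed) s$u_gene else s$v_cell
  Ps <- sqrt(s$n_major) * u_major[, idx, drop = FALSE] %*%
    (components$theta * t(v_minor[, idx, drop = FALSE]))
  vals <- with_seed(seed, {
    vapply(seq_len(config$n_boot), function(b) {
      m <- Ps + matrix(stats::rnorm(length(Ps)), nrow(Ps), ncol(Ps))
      sb <- scaled_svd(m)
      gate <- significant_components(sb, mp, alpha_sw = config$alpha_sw)
      sig <- gate[gate$significant, , drop = FALSE]
      if (!nrow(sig)) return(0)
      if (config$noise_model == "additive") {
        th <- theta_additive(pmax(sig$gamma, mp$gamma_plus * (1 + 1e-12)), s$c)
        max(as.numeric(phi_cell(th, s$c)))
      } else {
        th <- theta_multiplicative(sig$gamma^2, s$c)
        max(as.numeric(phi_mult(th, s$c)))
      }
    }, numeric(1))
  })
  up <- vals[vals > point_estimate]
  dn <- vals[vals < point_estimate]
  c(
    sigma_plus = if (length(up) > 1) stats::sd(up) else 0,
    sigma_minus = if (length(dn) > 1) stats::sd(dn) else 0
  )
}

#' Genes driving a significant component
#'
#' Genes with large positive (negative) entries in a significant
#' gene-singular vector are concentrated in cells with large positive
#' (negative) entries of the matching cell-singular vector, so ranking by
#' absolute loading points at the genes behind the detected separation.
#'
#' @param fit A `phiclust_fit`.
#' @param cluster_id Cluster to inspect (default: first).
#' @param component_index Index of a significant component of that cluster.
#' @param top_n Number of genes to return (default 20).
#' @return A tibble: `rank`, `gene_id`, `loading`, `sign`, `component_index`.
#' @export
variance_driving_genes <- function(fit, cluster_id = NULL,
                                   component_index = NULL, top_n = 20L) {
  stopifnot(inherits(fit, "phiclust_fit"))
  cluster_id <- cluster_id %||% fit$clusters$cluster_id[1]
  comp <- fit$components[fit$components$cluster_id == cluster_id &
                           fit$components$phi > 0, , drop = FALSE]
  component_index <- component_index %||% comp$index[1]
  if (is.null(component_index) || !component_index %in% comp$index) {
    stop_phiclust("component ", component_index %||% "<none>",
                  " is not a significant component of cluster '", cluster_id, "'")
  }
  if (top_n < 0) stop_phiclust("`top_n` must be >= 0")
  u <- fit$svds[[cluster_id]]$u_gene[, component_index]
  ord <- order(abs(u), decreasing = TRUE)[seq_len(min(top_n, length(u)))]
  tibble::tibble(
    rank = seq_along(ord),
    gene_id = rownames(fit$svds[[cluster_id]]$u_gene)[ord] %||% as.character(ord),
    loading = u[ord],
    sign = ifelse(u[ord] >= 0, "+", "-"),
    component_index = as.integer(component_index)
  )
}

#' @export
print.phiclust_fit <- function(x, ...) {
  cat("phiclust fit:", nrow(x$clusters), "cluster(s),",
      x$config$noise_model, "noise model\n")
  print(x$clusters[, c("cluster_id", "phiclust", "g_phiclust",
                       "n_significant", "bulk_ks_p_adj", "n_cells")])
  invisible(x)
}
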