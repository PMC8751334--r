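# Confounder regression on singular vectors. Singular vectors of the
# measured matrix carry normally distributed noise, so ordinary least
# squares of a relevant cell-singular vector on nuisance covariates is a
# valid decomposition of its variance: the adjusted R^2 is the fraction
# explained by confounders, and the squared singular value (the variance
# carried by the component) is shrunk by (1 - adjusted R^2).

#' Regress singular vectors on nuisance covariates
#'
#' For each requested component, fits OLS of the cell-singular vector on an
#' intercept plus all covariates jointly (collinear columns dropped with a
#' warning) and reports the adjusted R^2, clamped to `[0, 1]`. A
#' per-covariate breakdown from single-covariate regressions is attached
#' for attribution; the correction itself always uses the joint fit.
#'
#' @param svd A [scaled_svd()] object.
#' @param covariates Data frame with `cell_id` plus numeric covariates, or
#'   NULL (returns adjusted R^2 = 0 for all indices). Rows are matched to
#'   `colnames` of the decomposed matrix when present, otherwise taken in
#'   cell order.
#' @param indices Component indices to regress.
#' @return A tibble with `index`, `adj_r2`, and a list-column `per_covariate`
#'   of single-covariate R^2 tibbles.
#' @export
regress_confounders <- function(svd, covariates, indices) {
  stopifnot(inherits(svd, "scaled_svd"))
  zero <- tibble::tibble(
    index = as.integer(indices), adj_r2 = 0,
    per_covariate = replicate(length(indices),
      tibble::tibble(covariate = character(), r2 = numeric()),
      simplify = FALSE
    )
  )
  if (is.null(covariates) || !length(indices)) return(zero)
  design <- covariate_design(svd, covariates)
  if (!ncol(design)) return(zero)
  res <- purrr::map(as.integer(indices), function(i) {
    df <- as.data.frame(design)
    if (".response" %in% names(df)) {
      stop_phiclust("covariate name '.response' is reserved")
    }
    df$.response <- svd$v_cell[, i]
    fit <- stats::lm(.response ~ ., data = df)
    adj <- summary(fit)$adj.r.squared
    y <- svd$v_cell[, i]
    per <- purrr::map_dbl(colnames(design), function(cv) {
      summary(stats::lm(y ~ design[, cv]))$r.squared
    })
    tibble::tibble(
      index = i,
      adj_r2 = min(max(adj, 0), 1),
      per_covariate = list(tibble::tibble(covariate = colnames(design), r2 = per))
    )
  })
  dplyr::bind_rows(res)
}

covariate_design <- function(svd, covariates) {
  cov <- as.data.frame(covariates)
  cells <- rownames(svd$v_cell)
  if ("cell_id" %in% names(cov)) {
    if (!is.null(cells)) {
      missing <- setdiff(cells, cov$cell_id)
      if (length(missing)) {
        stop_phiclust("covariates missing for cell(s): ",
                      paste(utils::head(missing, 5), collapse = ", "))
      }
      cov <- cov[match(cells, cov$cell_id), , drop = FALSE]
    }
    cov$cell_id <- NULL
  }
  cov <- cov[vapply(cov, is.numeric, TRUE)]
  if (nrow(cov) != nrow(svd$v_cell)) {
    stop_phiclust("covariate rows do not align with cells")
  }
  if (anyNA(cov)) stop_phiclust("covariates contain missing values")
  m <- as.matrix(cov)
  const <- apply(m, 2, function(x) stats::sd(x) == 0)
  if (any(const)) {
    warning("dropping zero-variance covariate(s): ",
            paste(colnames(m)[const], collapse = ", "), call. = FALSE)
    m <- m[, !const, drop = FALSE]
  }
  if (ncol(m) > 1) {
    qr_d <- qr(cbind(1, scale(m)))
    if (qr_d$rank < ncol(m) + 1) {
      keep <- (qr_d$pivot[seq_len(qr_d$rank)] - 1)[-1]
      warning("dropping collinear covariate(s): ",
              paste(setdiff(colnames(m), colnames(m)[keep]), collapse = ", "),
              call. = FALSE)
      m <- m[, sort(keep), drop = FALSE]
    }
  }
  m
}

#' Shrink singular values by the confounder-explained variance
#'
#' The squared singular value is the variance carried by a component;
#' multiplying it by `(1 - adjusted R^2)` removes the part explained by
#' nuisance covariates. The square root is the corrected singular value.
#' Negative adjusted R^2 is clamped to 0 before correction.
#'
#' @param gamma Scaled singular value(s).
#' @param adj_r2 Adjusted R^2 value(s) in `[0, 1]`.
#' @return Corrected singular value(s), `gamma * sqrt(1 - adj_r2)`.
#' @export
correct_singular_values <- function(gamma, adj_r2) {
  if (any(adj_r2 < -1e-8 | adj_r2 > 1 + 1e-8)) {
    stop_phiclust("`adj_r2` must lie in [0, 1]")
  }
  gamma * sqrt(1 - pmin(pmax(adj_r2, 0), 1))
}
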