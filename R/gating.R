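# Bulk goodness-of-fit and significance gating of outlying components.

#' Kolmogorov-Smirnov test of the singular-value bulk against the MP law
#'
#' Compares the bulk of the spectrum (eigenvalues at or below the
#' Tracy-Widom threshold, excluding the transcriptome mode, i.e. the
#' smallest singular value, which double standardization drives to ~0)
#' with a reference sample drawn from the MP law. Returns the raw p value;
#' the pipeline adjusts across clusters with Benjamini-Hochberg.
#'
#' @param svd A [scaled_svd()] object.
#' @param mp A [mp_model()] object with matching `c`.
#' @param n_mp Size of the MP reference sample (default 1000).
#' @param seed Seed for the reference sample.
#' @return A single p value.
#' @export
ks_bulk_test <- function(svd, mp, n_mp = 1000L, seed = 1L) {
  stopifnot(inherits(svd, "scaled_svd"), inherits(mp, "mp_model"))
  gamma <- svd$gamma
  bulk <- gamma[gamma^2 <= mp$tw_lambda_star]
  if (length(bulk)) bulk <- bulk[-which.min(bulk)] # transcriptome mode
  if (length(bulk) < 10) stop_phiclust("fewer than 10 bulk singular values")
  ref <- sample_mp(mp$c, n_mp, seed = seed)
  suppressWarnings(stats::ks.test(bulk, ref))$p.value
}

#' Identify significant outlying components
#'
#' A component is significant when its eigenvalue `gamma^2` exceeds the
#' Tracy-Widom threshold *and* its cell-singular vector deviates from
#' normality (Shapiro-Wilk, Benjamini-Hochberg adjusted across the
#' TW-passing set, adjusted p < `alpha_sw`): singular vectors of a pure
#' random matrix are normally distributed, so a normal-looking vector
#' carries no clustering information even if its singular value is large.
#'
#' @param svd A [scaled_svd()] object.
#' @param mp A [mp_model()] object.
#' @param alpha_sw Significance level of the normality gate (default 0.05).
#' @param seed Seed for the subsample used when a vector has more than 5000
#'   entries (Shapiro-Wilk validity cap).
#' @return A tibble with one row per TW-passing component: `index`, `gamma`,
#'   `lambda`, `sw_p`, `sw_p_adj`, `significant`. Zero rows when no
#'   eigenvalue exceeds the threshold.
#' @export
significant_components <- function(svd, mp, alpha_sw = 0.05, seed = 1L) {
  stopifnot(inherits(svd, "scaled_svd"), inherits(mp, "mp_model"))
  if (!is.finite(alpha_sw) || alpha_sw <= 0 || alpha_sw >= 1) {
    stop_phiclust("`alpha_sw` must lie in (0, 1)")
  }
  idx <- which(svd$gamma^2 > mp$tw_lambda_star)
  if (!length(idx)) {
    return(tibble::tibble(
      index = integer(), gamma = numeric(), lambda = numeric(),
      sw_p = numeric(), sw_p_adj = numeric(), significant = logical()
    ))
  }
  sw_p <- vapply(idx, function(i) {
    v <- svd$v_cell[, i]
    if (length(v) > 5000L) {
      v <- with_seed(substream(seed, "sw-subsample"), sample(v, 5000L))
    }
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  sw_p_adj <- stats::p.adjust(sw_p, method = "BH")
  tibble::tibble(
    index = idx,
    gamma = svd$gamma[idx],
    lambda = svd$gamma[idx]^2,
    sw_p = sw_p,
    sw_p_adj = sw_p_adj,
    significant = sw_p_adj < alpha_sw
  )
}
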