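#' Run configuration for the phiclust pipeline
#'
#' Collects the tunable thresholds of the pipeline. `alpha_tw` is the
#' significance of the Tracy-Widom outlier threshold (0.01 by default: an
#' outlier call is a claim of structure, so the gate is conservative);
#' `alpha_sw` the level of the Shapiro-Wilk normality gate on cell-singular
#' vectors (0.05, Benjamini-Hochberg adjusted across TW-passing
#' components); `n_boot` the number of resampled noise matrices for the
#' uncertainty estimate (>= 50 recommended); `n_mp_samples` the size of the
#' MP reference sample for the bulk KS test. Clusters smaller than
#' `min_cluster_size_warn` cells trigger a warning (the MP bulk of very
#' small clusters is noisy). All randomness derives from `seed` through
#' named substreams.
#'
#' @param noise_model `"additive"` (default) or `"multiplicative"`.
#' @param alpha_tw,alpha_sw Significance levels in (0, 1).
#' @param n_boot Resampling count for uncertainty (>= 1).
#' @param n_mp_samples MP reference-sample size for the KS bulk test.
#' @param seed Master integer seed.
#' @param min_cluster_size_warn Warn below this many cells (default 50).
#' @return An object of class `phiclust_config`.
#' @export
phiclust_config <- function(noise_model = c("additive", "multiplicative"),
                            alpha_tw = 0.01, alpha_sw = 0.05,
                            n_boot = 50L, n_mp_samples = 1000L,
                            seed = 1L, min_cluster_size_warn = 50L) {
  noise_model <- match.arg(noise_model)
  for (a in c(alpha_tw, alpha_sw)) {
    if (!is.finite(a) || a <= 0 || a >= 1) {
      stop_phiclust("significance levels must lie in (0, 1)")
    }
  }
  if (n_boot < 1) stop_phiclust("`n_boot` must be >= 1")
  structure(
    list(
      noise_model = noise_model, alpha_tw = alpha_tw, alpha_sw = alpha_sw,
      n_boot = as.integer(n_boot), n_mp_samples = as.integer(n_mp_samples),
      seed = as.integer(seed),
      min_cluster_size_warn = as.integer(min_cluster_size_warn)
    ),
    class = "phiclust_config"
  )
}
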