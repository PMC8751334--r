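# Marchenko-Pastur null model for the scaled singular-value spectrum.
#
# Conventions: the expression matrix has N_genes >= N_cells (enforced by
# transposition upstream), entries standardized to mean 0, variance 1, and
# singular values are divided by sqrt(N_genes). In these units the noise
# bulk converges to the MP law with ratio c = N_cells / N_genes:
# singular-value support [1 - sqrt(c), 1 + sqrt(c)], eigenvalue support
# [b, a] with a, b = (1 +/- sqrt(c))^2.

#' Marchenko-Pastur null model with Tracy-Widom outlier threshold
#'
#' Builds the null model for the spectrum of a standardized pure-noise
#' expression matrix: the MP bulk edges for the given cell-to-gene ratio and
#' the finite-size threshold above which the largest eigenvalue of a random
#' matrix would fall with probability `alpha_tw` (Johnstone's
#' centering/scaling with Tracy-Widom beta = 1 quantiles).
#'
#' @param n_genes,n_cells Matrix dimensions; `n_genes >= n_cells >= 2`.
#' @param alpha_tw Significance level of the outlier threshold (default 0.01).
#' @return An object of class `mp_model`: list with `c`, singular-value
#'   edges `gamma_minus`/`gamma_plus`, eigenvalue edges `b`/`a`, the
#'   eigenvalue outlier threshold `tw_lambda_star`, and `alpha_tw`.
#' @examples
#' mp_model(350, 201)
#' @export
mp_model <- function(n_genes, n_cells, alpha_tw = 0.01) {
  if (n_cells < 2 || n_genes < n_cells) {
    stop_phiclust("need n_genes >= n_cells >= 2 (transpose upstream if needed)")
  }
  if (!is.finite(alpha_tw) || alpha_tw <= 0 || alpha_tw >= 1) {
    stop_phiclust("`alpha_tw` must lie in (0, 1)")
  }
  c_ratio <- n_cells / n_genes
  # Johnstone centering/scaling for the largest eigenvalue of X'X, X an
  # n_genes x n_cells standard Gaussian matrix, rescaled by 1/n_genes to
  # match the scaled spectrum.
  mu <- (sqrt(n_genes - 1) + sqrt(n_cells))^2 / n_genes
  sg <- (sqrt(n_genes - 1) + sqrt(n_cells)) *
    (1 / sqrt(n_genes - 1) + 1 / sqrt(n_cells))^(1 / 3) / n_genes
  structure(
    list(
      c = c_ratio,
      gamma_minus = 1 - sqrt(c_ratio),
      gamma_plus = 1 + sqrt(c_ratio),
      b = (1 - sqrt(c_ratio))^2,
      a = (1 + sqrt(c_ratio))^2,
      tw_lambda_star = mu + sg * qtw1(1 - alpha_tw),
      alpha_tw = alpha_tw,
      n_genes = n_genes,
      n_cells = n_cells
    ),
    class = "mp_model"
  )
}

#' @export
print.mp_model <- function(x, ...) {
  cat(sprintf(
    "MP null model: c = %.4f, gamma in [%.4f, %.4f], lambda in [%.4f, %.4f]\n",
    x$c, x$gamma_minus, x$gamma_plus, x$b, x$a
  ))
  cat(sprintf(
    "TW outlier threshold (alpha = %g): lambda* = %.4f\n",
    x$alpha_tw, x$tw_lambda_star
  ))
  invisible(x)
}

#' Marchenko-Pastur singular-value density
#'
#' Density of the MP law for scaled singular values with ratio `c`:
#' `sqrt((a - x^2)(x^2 - b)) / (pi * c * x)` on `[1 - sqrt(c), 1 + sqrt(c)]`.
#'
#' @param x Numeric vector of scaled singular values.
#' @param c_ratio Cell-to-gene ratio in (0, 1].
#' @return Density values (0 outside the support).
#' @export
dmp <- function(x, c_ratio) {
  check_c_ratio(c_ratio)
  a <- (1 + sqrt(c_ratio))^2
  b <- (1 - sqrt(c_ratio))^2
  out <- numeric(length(x))
  in_support <- is.finite(x) & x^2 > b & x^2 < a & x > 0
  xi <- x[in_support]
  out[in_support] <- sqrt((a - xi^2) * (xi^2 - b)) / (pi * c_ratio * xi)
  out
}

check_c_ratio <- function(c_ratio) {
  if (!is.finite(c_ratio) || c_ratio <= 0 || c_ratio > 1) {
    stop_phiclust("`c_ratio` must lie in (0, 1]")
  }
}

# Cached inverse-CDF interpolants of the MP singular-value law, keyed by c.
mp_cdf_cache <- new.env(parent = emptyenv())

mp_inverse_cdf <- function(c_ratio) {
  key <- sprintf("%.12g", c_ratio)
  if (!is.null(mp_cdf_cache[[key]])) {
    return(mp_cdf_cache[[key]])
  }
  lo <- 1 - sqrt(c_ratio)
  hi <- 1 + sqrt(c_ratio)
  # trapezoidal CDF on a fine grid; the density vanishes like a square root
  # at both edges, so plain trapezoids converge fast
  grid <- seq(lo, hi, length.out = 4096L)
  dens <- dmp(grid, c_ratio)
  cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(grid)))
  cdf <- cdf / cdf[length(cdf)]
  keep <- c(TRUE, diff(cdf) > 0)
  fun <- stats::approxfun(cdf[keep], grid[keep], rule = 2)
  mp_cdf_cache[[key]] <- fun
  fun
}

#' Sample from the Marchenko-Pastur singular-value law
#'
#' Draws i.i.d. scaled singular values by inverse-CDF sampling on a
#' numerically integrated MP density; used as the reference sample for the
#' bulk Kolmogorov-Smirnov test.
#'
#' @param c_ratio Cell-to-gene ratio in (0, 1].
#' @param n Number of draws.
#' @param seed Integer seed (deterministic output; caller RNG untouched).
#' @return Numeric vector of length `n` inside the MP support.
#' @examples
#' range(sample_mp(0.5, 1000, seed = 1))
#' @export
sample_mp <- function(c_ratio, n, seed = 1L) {
  check_c_ratio(c_ratio)
  if (n < 1) stop_phiclust("`n` must be >= 1")
  qf <- mp_inverse_cdf(c_ratio)
  with_seed(seed, qf(stats::runif(n)))
}
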