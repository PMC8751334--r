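# Low-rank perturbation theory: map outlying singular values of the
# measured matrix to the signal strength theta and to the squared cosine
# between measured and noise-free singular vectors.
#
# Additive model X~ = X + P with X i.i.d. noise (scaled spectrum):
#   forward map   gamma^2 = (theta^2 + 1)(theta^2 + c) / theta^2
#   detectability theta > c^(1/4) (BBP transition); at theta = c^(1/4)
#   the angle formulas vanish algebraically.

#' Signal singular value from an outlying measured singular value (additive noise)
#'
#' Inverts the forward map `gamma^2 = (theta^2 + 1)(theta^2 + c) / theta^2`
#' to recover the singular value `theta` of the noise-free signal matrix
#' from a measured scaled singular value `gamma` above the bulk edge.
#'
#' @param gamma Scaled singular value(s), strictly above `1 + sqrt(c)`.
#' @param c_ratio Cell-to-gene ratio in (0, 1].
#' @return `theta` (> `c_ratio^(1/4)`), vectorized over `gamma`.
#' @examples
#' theta_additive(2.391204, 201 / 350)  # ~2
#' @export
theta_additive <- function(gamma, c_ratio) {
  check_c_ratio(c_ratio)
  if (any(gamma <= 1 + sqrt(c_ratio))) {
    stop_phiclust("`gamma` must exceed the bulk edge 1 + sqrt(c); value(s) ",
                  "inside the bulk carry no recoverable signal")
  }
  g2 <- gamma^2
  disc <- (g2 - (c_ratio + 1))^2 - 4 * c_ratio
  # conjugate form of 2c / (g2 - (c+1) - sqrt(disc)); identical by the
  # product of roots, stable for large gamma
  theta <- sqrt((g2 - (c_ratio + 1) + sqrt(disc)) / 2)
  # verify the forward identity (guards against catastrophic cancellation)
  back <- (theta^2 + 1) * (theta^2 + c_ratio) / theta^2
  if (any(abs(back - g2) > 1e-10 * pmax(1, g2))) {
    stop_phiclust("forward identity gamma^2 = (theta^2+1)(theta^2+c)/theta^2 ",
                  "not satisfied to 1e-10")
  }
  theta
}

#' Forward map: measured singular value produced by a planted signal
#' @param theta Signal singular value(s), >= `c_ratio^(1/4)`.
#' @param c_ratio Cell-to-gene ratio.
#' @return Expected scaled singular value `gamma` of the measured matrix.
#' @rdname theta_additive
#' @export
gamma_additive <- function(theta, c_ratio) {
  check_c_ratio(c_ratio)
  sqrt((theta^2 + 1) * (theta^2 + c_ratio) / theta^2)
}

#' Clusterability angle of a cell-singular vector (additive noise)
#'
#' Squared cosine of the angle between the measured and noise-free
#' cell-singular vectors: `phi = 1 - c(1 + theta^2) / (theta^2 (theta^2 + c))`.
#' Below the detectability threshold `theta < c^(1/4)` the measured vector
#' is asymptotically orthogonal to the signal and the value is 0 (flagged
#' with attribute `sub_threshold`).
#'
#' @param theta Signal singular value(s).
#' @param c_ratio Cell-to-gene ratio in (0, 1].
#' @return Value(s) in `[0, 1)`, monotone increasing in `theta`.
#' @examples
#' phi_cell(2, 201 / 350)  # 0.8431
#' @export
phi_cell <- function(theta, c_ratio) {
  check_c_ratio(c_ratio)
  phi_from(theta, c_ratio, function(t2) {
    1 - c_ratio * (1 + t2) / (t2 * (t2 + c_ratio))
  })
}

#' Clusterability angle of a gene-singular vector (additive noise)
#'
#' Gene-space conjugate of [phi_cell()]:
#' `phi_g = 1 - (c + theta^2) / (theta^2 (theta^2 + 1))`.
#'
#' @inheritParams phi_cell
#' @return Value(s) in `[0, 1)`.
#' @examples
#' phi_gene(2, 201 / 350)  # 0.7713
#' @export
phi_gene <- function(theta, c_ratio) {
  check_c_ratio(c_ratio)
  phi_from(theta, c_ratio, function(t2) {
    1 - (c_ratio + t2) / (t2 * (t2 + 1))
  })
}

phi_from <- function(theta, c_ratio, formula) {
  if (any(!is.finite(theta) | theta < 0)) stop_phiclust("`theta` must be >= 0")
  out <- numeric(length(theta))
  above <- theta >= c_ratio^0.25
  out[above] <- pmax(0, formula(theta[above]^2))
  attr(out, "sub_threshold") <- !above
  out
}

#' Signal eigenvalue and angle under multiplicative noise
#'
#' Under the multiplicative model `X~ = (I + P)^(1/2) X` (square rank-one
#' signal `P` acting in gene space), the signal eigenvalue is recovered
#' from an outlying eigenvalue `lambda > a = (1 + sqrt(c))^2` of the scaled
#' spectrum as `theta = 2c / (lambda - c - 1 - sqrt((lambda - a)(lambda - b)))`,
#' and the squared cosine is
#' `phi = (1/theta) (theta^2 - c) / (theta (c + 1) + 2c)`.
#' Note `phi_mult` tends to `1 / (c + 1)` (not 1) as `theta` grows; the
#' formula is implemented as printed, without renormalization.
#'
#' @param lambda Outlying scaled eigenvalue(s), strictly above `a`.
#' @param c_ratio Cell-to-gene ratio in (0, 1].
#' @return `theta_multiplicative()`: the signal eigenvalue(s);
#'   `phi_mult()`: values in `[0, 1/(c+1))`, 0 below `theta^2 = c`.
#' @examples
#' th <- theta_multiplicative(9, 1)  # 6.8541
#' phi_mult(th, 1)                   # 0.4271
#' @export
theta_multiplicative <- function(lambda, c_ratio) {
  check_c_ratio(c_ratio)
  a <- (1 + sqrt(c_ratio))^2
  b <- (1 - sqrt(c_ratio))^2
  if (any(lambda <= a)) {
    stop_phiclust("`lambda` must exceed the bulk edge a = (1 + sqrt(c))^2")
  }
  2 * c_ratio / (lambda - c_ratio - 1 - sqrt((lambda - a) * (lambda - b)))
}

#' @param theta Signal eigenvalue(s) from [theta_multiplicative()].
#' @rdname theta_multiplicative
#' @export
phi_mult <- function(theta, c_ratio) {
  check_c_ratio(c_ratio)
  if (any(!is.finite(theta) | theta < 0)) stop_phiclust("`theta` must be >= 0")
  out <- numeric(length(theta))
  above <- theta^2 >= c_ratio
  t <- theta[above]
  out[above] <- pmax(0, (1 / t) * (t^2 - c_ratio) / (t * (c_ratio + 1) + 2 * c_ratio))
  attr(out, "sub_threshold") <- !above
  out
}

#' Forward map for the multiplicative model
#' @rdname theta_multiplicative
#' @export
lambda_multiplicative <- function(theta, c_ratio) {
  check_c_ratio(c_ratio)
  theta / (4 * c_ratio) *
    ((c_ratio + 1 + 2 * c_ratio / theta)^2 - (1 - c_ratio)^2)
}
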