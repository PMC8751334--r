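# Tracy-Widom (beta = 1) distribution, tabulated.
#
# The CDF F1(s) was computed once from the Painleve II (Hastings-McLeod)
# representation: q'' = s q + 2 q^3 with q(s) ~ Ai(s) as s -> +Inf,
#   F2(s) = exp(-int_s^Inf (x - s) q(x)^2 dx),
#   F1(s) = sqrt(F2(s)) * exp(-1/2 int_s^Inf q(x) dx),
# on a grid s = -7.0, -6.9, ..., 6.0 and frozen here. Spot checks against
# published values: q(0.99) = 2.0234, q(0.95) = 0.9793, mean = -1.2065,
# sd = 1.268. Quantiles/probabilities in between come from monotone
# (Hyman-filtered) spline interpolation.

.tw1_s <- seq(-7, 6, by = 0.1)
.tw1_F <- c(
  4.029768115393e-09, 8.981956087940e-09, 1.893715398646e-08, 3.835103514430e-08,
    7.524690832211e-08, 1.437843983146e-07, 2.684719013791e-07, 4.909358241580e-07,
    8.805806544827e-07, 1.551040925326e-06, 2.685065258072e-06, 4.571402564742e-06,
    7.658384886195e-06, 1.263019981976e-05, 2.051326311182e-05, 3.282153913029e-05,
    5.175096111962e-05, 8.043406533944e-05, 1.232663111249e-04, 1.863150099237e-04,
    2.778200115556e-04, 4.087919959721e-04, 5.937091600186e-04, 8.513061557509e-04,
    1.205440385859e-03, 1.686010466187e-03, 2.329890345637e-03, 3.181831002154e-03,
    4.295270807013e-03, 5.732986728226e-03, 7.567512754072e-03, 9.881250429695e-03,
    1.276620018733e-02, 1.632325185329e-02, 2.066098851555e-02, 2.589397947828e-02,
    3.214056438297e-02, 3.952016026533e-02, 4.815015441225e-02, 5.814247614755e-02,
    6.959996776011e-02, 8.261269644310e-02, 9.725436340909e-02, 1.135789718569e-01,
    1.316179114238e-01, 1.513776031221e-01, 1.728378262424e-01, 1.959508187021e-01,
    2.206412067713e-01, 2.468067813720e-01, 2.743200987230e-01, 3.030308455055e-01,
    3.327688752012e-01, 3.633477947009e-01, 3.945689600542e-01, 4.262257281194e-01,
    4.581078070777e-01, 4.900055529295e-01, 5.217140703594e-01, 5.530369935264e-01,
    5.837898439391e-01, 6.138028870560e-01, 6.429234349968e-01, 6.710175683283e-01,
    6.979712739866e-01, 7.236910180063e-01, 7.481037900699e-01, 7.711566715111e-01,
    7.928159890916e-01, 8.130661236694e-01, 8.319080460139e-01, 8.493576519085e-01,
    8.654439657868e-01, 8.802072770527e-01, 8.936972664824e-01, 9.059711722718e-01,
    9.170920368725e-01, 9.271270671963e-01, 9.361461324519e-01, 9.442204160708e-01,
    9.514212311297e-01, 9.578190024960e-01, 9.634824137077e-01, 9.684777123566e-01,
    9.728681644532e-01, 9.767136458565e-01, 9.800703572620e-01, 9.829906483580e-01,
    9.855229364845e-01, 9.877117053370e-01, 9.895975698617e-01, 9.912173943735e-01,
    9.926044520238e-01, 9.937886149565e-01, 9.947965657730e-01, 9.956520222033e-01,
    9.963759681362e-01, 9.969868853407e-01, 9.975009813050e-01, 9.979324096138e-01,
    9.982934801635e-01, 9.985948572841e-01, 9.988457444931e-01, 9.990540551601e-01,
    9.992265688108e-01, 9.993690731634e-01, 9.994864922745e-01, 9.995830013810e-01,
    9.996621291814e-01, 9.997268483951e-01, 9.997796555034e-01, 9.998226405967e-01,
    9.998575482515e-01, 9.998858303373e-01, 9.999086916154e-01, 9.999271289411e-01,
    9.999419648264e-01, 9.999538760564e-01, 9.999634179945e-01, 9.999710451466e-01,
    9.999771284963e-01, 9.999819700668e-01, 9.999858151091e-01, 9.999888622705e-01,
    9.999912720494e-01, 9.999931738017e-01, 9.999946715311e-01, 9.999958486562e-01,
    9.999967719267e-01, 9.999974946290e-01, 9.999980592028e-01)

.tw1_q_fun <- NULL
.tw1_p_fun <- NULL

tw1_funs <- local({
  env <- new.env()
  function() {
    if (is.null(env$p)) {
      env$p <- stats::splinefun(.tw1_s, .tw1_F, method = "hyman")
      env$q <- stats::splinefun(.tw1_F, .tw1_s, method = "hyman")
    }
    env
  }
})

#' Tracy-Widom (beta = 1) distribution function
#'
#' CDF of the fluctuation law of the largest eigenvalue of a real Wishart
#' matrix around the Marchenko-Pastur upper edge, used to set the outlier
#' threshold for singular values.
#'
#' @param s Numeric vector of quantiles (centered/scaled eigenvalue units).
#' @return `ptw1()`: probabilities; `qtw1()`: quantiles.
#' @examples
#' ptw1(qtw1(0.99))
#' @export
ptw1 <- function(s) {
  f <- tw1_funs()
  p <- f$p(pmin(pmax(s, min(.tw1_s)), max(.tw1_s)))
  p[s < min(.tw1_s)] <- 0
  p[s > max(.tw1_s)] <- 1
  pmin(pmax(p, 0), 1)
}

#' @param p Numeric vector of probabilities in (0, 1).
#' @rdname ptw1
#' @export
qtw1 <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p >= 1)) {
    stop_phiclust("`p` must lie strictly inside (0, 1)")
  }
  f <- tw1_funs()
  f$q(pmin(pmax(p, min(.tw1_F)), max(.tw1_F)))
}
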