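# Prior specification: diffuse Normals for regression coefficients,
# half-Cauchy(0, 5) for the residual SD, inverse-Wishart(I, K) for the
# random-effects covariance, Gamma(eta, eta) for the individual hazard
# multipliers (mean 1, variance 1/eta).

#' Default prior specification
#'
#' @param K random-effect dimension (canonical model: 2).
#' @param normal_sd common SD of the zero-mean Normal priors on beta, gamma
#'   and alpha; the default 100 makes them diffuse on the scale of the
#'   prothrombin-style data.
#' @param eta concentration of the Gamma(eta, eta) prior on the individual
#'   multiplicative fixed effects; E(w) = 1 and Var(w) = 1/eta.  The default
#'   1.5 gives prior variance 1/1.5 ~ 0.67.
#' @param cauchy_scale scale of the half-Cauchy prior on sigma.
#' @return An object of class \code{"prior_spec"}.
#' @export
default_priors <- function(K = 2, normal_sd = 100, eta = 1.5,
                           cauchy_scale = 5) {
  if (normal_sd <= 0) stop("`normal_sd` must be > 0")
  if (eta <= 0) stop("`eta` must be > 0")
  if (cauchy_scale <= 0) stop("`cauchy_scale` must be > 0")
  structure(
    list(normal_sd = normal_sd,
         cauchy_scale = cauchy_scale,
         wishart_V = diag(K),
         wishart_df = K,
         eta = eta),
    class = "prior_spec"
  )
}

# log density of the half-Cauchy(0, scale) on x > 0
log_half_cauchy <- function(x, scale) {
  ifelse(x > 0, log(2) - log(pi * scale) - log1p((x / scale)^2), -Inf)
}

# log inverse-Wishart(V, df) density of a K x K covariance, normalised
log_inv_wishart <- function(Sigma, V, df) {
  K <- ncol(V)
  lgamma_K <- (K * (K - 1) / 4) * log(pi) +
    sum(lgamma((df + 1 - seq_len(K)) / 2))
  Sinv <- solve(Sigma)
  (df / 2) * determinant(V, logarithm = TRUE)$modulus[1] -
    (df * K / 2) * log(2) - lgamma_K -
    ((df + K + 1) / 2) * determinant(Sigma, logarithm = TRUE)$modulus[1] -
    0.5 * sum(diag(V %*% Sinv))
}
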