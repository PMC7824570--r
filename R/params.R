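#' Joint-model parameter set
#'
#' Bundles the full parameter vector of the canonical joint model: a linear
#' mixed-effects longitudinal submodel with random intercept and slope, and a
#' proportional-hazards survival submodel with exponential baseline and
#' current-value association,
#' \deqn{y_i(t) = (\beta_0 + b_{0i}) + (\beta_1 + b_{1i}) t + \beta_2 x_i +
#'   \epsilon_i(t), \quad
#'   h_i(t) = \exp\{\gamma_0 + \gamma_1 x_i + \alpha \mu_i(t)\}.}
#'
#' @param beta length-3 fixed-effects vector (intercept, time slope, group
#'   contrast) of the longitudinal submodel.
#' @param Sigma 2x2 symmetric positive-definite covariance of the random
#'   intercept and slope.
#' @param sigma residual standard deviation of the longitudinal outcome,
#'   strictly positive.
#' @param gamma length-2 survival coefficients: \code{gamma[1]} is the
#'   baseline log-hazard (the exponential baseline is
#'   \eqn{h_0(t)=\exp(\gamma_0)}), \code{gamma[2]} the group coefficient.
#' @param alpha association scalar multiplying the current trajectory value
#'   in the log-hazard.
#' @param eta optional Gamma concentration for the individual multiplicative
#'   fixed effects \eqn{w_i \sim \mathrm{Gamma}(\eta, \eta)}; strictly
#'   positive when supplied (bias-corrected two-stage model only).
#' @param w optional vector of positive individual hazard multipliers.
#'
#' @return An object of class \code{"joint_params"}.
#' @seealso [prothro_params()] for the default simulation truth.
#' @export
joint_params <- function(beta, Sigma, sigma, gamma, alpha, eta = NULL,
                         w = NULL) {
  beta <- as.numeric(beta)
  gamma <- as.numeric(gamma)
  Sigma <- as.matrix(Sigma)
  if (length(beta) != 3L) {
    stop("`beta` must have length 3 (intercept, slope, group contrast)")
  }
  if (length(gamma) != 2L) {
    stop("`gamma` must have length 2 (baseline log-hazard, group coefficient)")
  }
  if (!all(is.finite(beta)) || !all(is.finite(gamma)) || !is.finite(alpha)) {
    stop("parameters must be finite")
  }
  if (!identical(dim(Sigma), c(2L, 2L))) {
    stop("`Sigma` must be a 2x2 matrix")
  }
  if (max(abs(Sigma - t(Sigma))) > 1e-12) stop("`Sigma` must be symmetric")
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("`Sigma` must be positive-definite")
  if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be > 0")
  if (!is.null(eta) && (!is.finite(eta) || eta <= 0)) {
    stop("`eta` must be > 0 when supplied")
  }
  if (!is.null(w) && any(w <= 0)) stop("all `w` must be > 0")
  structure(
    list(beta = beta, Sigma = Sigma, sigma = sigma, gamma = gamma,
         alpha = as.numeric(alpha), eta = eta, w = w),
    class = "joint_params"
  )
}

#' @export
print.joint_params <- function(x, ...) {
  cat("Joint model parameters\n")
  cat(sprintf("  beta  = (%.4g, %.4g, %.4g)   sigma = %.4g\n",
              x$beta[1], x$beta[2], x$beta[3], x$sigma))
  cat(sprintf("  Sigma = [%.4g %.4g; %.4g %.4g]\n",
              x$Sigma[1, 1], x$Sigma[1, 2], x$Sigma[2, 1], x$Sigma[2, 2]))
  cat(sprintf("  gamma = (%.4g, %.4g)   alpha = %.4g\n",
              x$gamma[1], x$gamma[2], x$alpha))
  if (!is.null(x$eta)) cat(sprintf("  eta   = %.4g\n", x$eta))
  invisible(x)
}

#' Default simulation truth from the prothrombin trial
#'
#' Parameter values obtained by fitting the canonical joint model to the
#' prothro liver-cirrhosis trial (prothrombin index on the log scale,
#' prednisone treatment as the binary group indicator).  These values serve
#' as the built-in "true parameter values" that drive the simulator and the
#' simulation-study harness.
#'
#' @return A [joint_params()] object with
#'   \eqn{\beta = (4.274, -0.004, -0.097)}, \eqn{\sigma = 0.262},
#'   \eqn{\Sigma_{11} = 0.094}, \eqn{\Sigma_{22} = 0.005},
#'   \eqn{\Sigma_{12} = -0.001}, \eqn{\gamma = (8.671, -0.172)} and
#'   \eqn{\alpha = -2.447}.
#' @export
prothro_params <- function() {
  joint_params(
    beta = c(4.274, -0.004, -0.097),
    Sigma = matrix(c(0.094, -0.001, -0.001, 0.005), 2, 2),
    sigma = 0.262,
    gamma = c(8.671, -0.172),
    alpha = -2.447
  )
}
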