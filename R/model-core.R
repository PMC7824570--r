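# Computational core of the canonical joint model: subject trajectory,
# exp-linear hazard with closed-form cumulative hazard and survival function,
# inverse-transform event-time solution, and the per-subject log-likelihood
# contributions used by every fitter.
#
# Because the trajectory is linear in time and the baseline hazard is
# constant, each subject's hazard collapses to w * exp(c + d * t) with
#   c = gamma0 + gamma1 * x + alpha * (beta0 + b0 + beta2 * x)
#   d = alpha * (beta1 + b1)
# which integrates in closed form; all survival quantities below exploit
# this.

# |d| below this is handled through the d -> 0 limit: expm1(d*t)/d suffers
# cancellation for smaller slopes without changing any value by > 1e-8 rel.
.SMALL_SLOPE <- 1e-10

#' Subject-specific longitudinal trajectory
#'
#' Error-free mean of the longitudinal outcome,
#' \eqn{\mu_i(t) = (\beta_0 + b_0) + (\beta_1 + b_1) t + \beta_2 x}.
#'
#' @param beta length-3 fixed-effects vector.
#' @param b length-2 random-effects vector (intercept, slope deviations).
#' @param x binary group indicator (0/1).
#' @param t time (vectorised), must be >= 0.
#' @return Numeric vector of trajectory values, one per element of \code{t}.
#' @export
trajectory <- function(beta, b, x, t) {
  if (length(beta) != 3L) stop("`beta` must have length 3")
  if (length(b) != 2L) stop("`b` must have length 2")
  if (any(t < 0)) stop("`t` must be nonnegative")
  (beta[1] + b[1]) + (beta[2] + b[2]) * t + beta[3] * x
}

#' Log-linear hazard coefficients for one or more subjects
#'
#' Collapses the joint-model hazard
#' \eqn{h_i(t) = w \exp\{\gamma_0 + \gamma_1 x + \alpha \mu_i(t)\}} into the
#' exp-linear form \eqn{w e^{c + d t}}.  Vectorised over subjects: \code{b}
#' may be an n x 2 matrix and \code{x} a length-n vector.
#'
#' @param beta length-3 longitudinal fixed effects.
#' @param b length-2 vector or n x 2 matrix of random effects.
#' @param gamma length-2 survival coefficients.
#' @param alpha association scalar.
#' @param x binary group indicator(s).
#' @param w positive hazard multiplier(s); defaults to 1 (no perturbation).
#' @return A data.frame with columns \code{c}, \code{d}, \code{w} (class
#'   \code{"linear_hazard"}).
#' @export
linear_hazard <- function(beta, b, gamma, alpha, x, w = 1) {
  if (length(beta) != 3L) stop("`beta` must have length 3")
  if (length(gamma) != 2L) stop("`gamma` must have length 2")
  if (is.matrix(b)) {
    if (ncol(b) != 2L) stop("`b` must have 2 columns")
    b0 <- b[, 1]; b1 <- b[, 2]
  } else {
    if (length(b) != 2L) stop("`b` must have length 2")
    b0 <- b[1]; b1 <- b[2]
  }
  if (any(w <= 0)) stop("`w` must be > 0")
  out <- data.frame(
    c = gamma[1] + gamma[2] * x + alpha * (beta[1] + b0 + beta[3] * x),
    d = alpha * (beta[2] + b1),
    w = rep_len(w, length(b0))
  )
  class(out) <- c("linear_hazard", "data.frame")
  out
}

#' Closed-form cumulative hazard of an exp-linear hazard
#'
#' \eqn{H(t) = \int_0^t w e^{c + d s} ds = w e^c (e^{dt} - 1)/d}, with the
#' limit \eqn{w e^c t} as \eqn{d \to 0}.  All arguments recycle.
#'
#' @param c log-hazard intercept.
#' @param d log-hazard slope per unit time.
#' @param w positive multiplier.
#' @param t time, >= 0.
#' @return Nonnegative cumulative hazard, nondecreasing in \code{t}.
#' @export
cum_hazard <- function(c, d, w = 1, t) {
  if (any(t < 0)) stop("`t` must be nonnegative")
  n <- max(length(c), length(d), length(w), length(t))
  c <- rep_len(c, n); d <- rep_len(d, n)
  w <- rep_len(w, n); t <- rep_len(t, n)
  out <- numeric(n)
  small <- abs(d) < .SMALL_SLOPE
  out[small] <- w[small] * exp(c[small]) * t[small]
  if (any(!small)) {
    i <- !small
    out[i] <- w[i] * exp(c[i]) * expm1(d[i] * t[i]) / d[i]
  }
  out
}

#' Survival function of an exp-linear hazard
#'
#' \eqn{S(t) = \exp\{-H(t)\}}; equals 1 at \eqn{t = 0} and is nonincreasing.
#'
#' @inheritParams cum_hazard
#' @return Survival probabilities in (0, 1].
#' @export
surv_prob <- function(c, d, w = 1, t) {
  exp(-cum_hazard(c, d, w, t))
}

#' Inverse-transform event time
#'
#' Solves \eqn{S(T) = u} for an exp-linear hazard in closed form:
#' \eqn{T = \log\{1 - d \log(u) e^{-c} / w\}/d}, with the exponential
#' quantile \eqn{-\log(u)/(w e^c)} at the \eqn{d \to 0} limit.  When
#' \eqn{d < 0} the total hazard \eqn{H(\infty) = w e^c / (-d)} is finite; a
#' draw with \eqn{-\log u \ge H(\infty)} never experiences the event and
#' \code{Inf} is returned (to be resolved by censoring).
#'
#' @inheritParams cum_hazard
#' @param u uniform(0,1) draw(s), strictly inside the unit interval.
#' @return Event times in (0, Inf]; vectorised, arguments recycle.
#' @export
sample_event_time <- function(c, d, w = 1, u) {
  if (any(u <= 0) || any(u >= 1)) stop("`u` must lie strictly in (0, 1)")
  n <- max(length(c), length(d), length(w), length(u))
  c <- rep_len(c, n); d <- rep_len(d, n)
  w <- rep_len(w, n); u <- rep_len(u, n)
  out <- numeric(n)
  small <- abs(d) < .SMALL_SLOPE
  out[small] <- -log(u[small]) / (w[small] * exp(c[small]))
  if (any(!small)) {
    i <- !small
    arg <- -d[i] * log(u[i]) * exp(-c[i]) / w[i]
    ti <- rep(Inf, sum(i))
    ok <- arg > -1
    ti[ok] <- log1p(arg[ok]) / d[i][ok]
    out[i] <- ti
  }
  out
}

#' Survival log-likelihood contribution
#'
#' Standard right-censored contribution for an exp-linear hazard:
#' \eqn{\delta (\log w + c + dT) - H(T)}.  Vectorised over subjects.
#'
#' @inheritParams cum_hazard
#' @param T observed time(s), > 0.
#' @param delta event indicator(s) in \{0, 1\}.
#' @return Log-likelihood contribution(s).
#' @export
log_lik_survival <- function(c, d, w = 1, T, delta) {
  if (any(T <= 0)) stop("observed times must be > 0")
  if (!all(delta %in% c(0, 1))) stop("`delta` must be 0 or 1")
  delta * (log(w) + c + d * T) - cum_hazard(c, d, w, T)
}

#' Longitudinal log-likelihood contribution
#'
#' Sum of independent Gaussian log-densities of the measurements around the
#' subject trajectory.
#'
#' @param y outcome vector.
#' @param times measurement times aligned with \code{y}.
#' @param beta,b,x trajectory arguments as in [trajectory()].
#' @param sigma residual SD, > 0.
#' @return Scalar log-likelihood.
#' @export
log_lik_longitudinal <- function(y, times, beta, b, x, sigma) {
  if (sigma <= 0) stop("`sigma` must be > 0")
  if (length(y) != length(times)) stop("`y` and `times` lengths differ")
  mu <- trajectory(beta, b, x, times)
  sum(stats::dnorm(y, mean = mu, sd = sigma, log = TRUE))
}
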