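# Stage-2 fitters for the two-stage strategies.  The survival submodel has
# an exp-linear hazard per subject once the stage-1 plug-in trajectory
# coefficients (intercept a_i, slope s_i) are fixed:
#   h_i(t) = w_i * exp(gamma0 + gamma1 x_i + alpha a_i + alpha s_i t).
# (gamma0, gamma1, alpha) are sampled by random-walk Metropolis with a
# proposal calibrated from the Laplace approximation at the posterior mode;
# in the bias-corrected variant the multipliers w_i are conjugate:
#   w_i | rest ~ Gamma(eta + delta_i, eta + H_i(T_i; w = 1)).

# log posterior kernel of (gamma0, gamma1, alpha) given plug-ins and w
surv_logpost <- function(par, a, s, x, T, delta, w, normal_sd) {
  cc <- par[1] + par[2] * x + par[3] * a
  d <- par[3] * s
  sum(log_lik_survival(cc, d, w, T, delta)) +
    sum(stats::dnorm(par, 0, normal_sd, log = TRUE))
}

# posterior mode and proposal Cholesky factor from the Laplace approximation
surv_laplace <- function(a, s, x, T, delta, w, normal_sd) {
  neg <- function(par) -surv_logpost(par, a, s, x, T, delta, w, normal_sd)
  init <- c(log(max(sum(delta), 1) / sum(T)), 0, 0)
  opt <- stats::optim(init, neg, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500))
  H <- opt$hessian
  V <- tryCatch(solve(H), error = function(e) diag(0.01, 3))
  ev <- eigen(V, symmetric = TRUE)
  ev$values <- pmax(ev$values, 1e-10)
  V <- ev$vectors %*% diag(ev$values) %*% t(ev$vectors)
  list(mode = opt$par, chol = chol(V) * 2.38 / sqrt(3))
}

mh_step <- function(par, lp, prop_chol, log_target) {
  prop <- par + as.vector(stats::rnorm(3) %*% prop_chol)
  lp_prop <- log_target(prop)
  if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
    list(par = prop, lp = lp_prop, acc = TRUE)
  } else {
    list(par = par, lp = lp, acc = FALSE)
  }
}

surv_mh_chain <- function(a, s, x, T, delta, priors, n_iter, warmup,
                          chain_seed, eta = NULL) {
  set.seed(chain_seed)
  n <- length(T)
  nts <- !is.null(eta)
  w <- rep(1, n)
  lap <- surv_laplace(a, s, x, T, delta, w, priors$normal_sd)
  par <- lap$mode
  target <- function(p) surv_logpost(p, a, s, x, T, delta, w,
                                     priors$normal_sd)
  lp <- target(par)
  n_keep <- n_iter - warmup
  out <- list(par = matrix(NA_real_, n_keep, 3), acc = 0)
  w_sum <- numeric(n)
  for (it in seq_len(n_iter)) {
    if (nts) {
      cc <- par[1] + par[2] * x + par[3] * a
      d <- par[3] * s
      H0 <- cum_hazard(cc, d, 1, T)
      w <- stats::rgamma(n, shape = eta + delta, rate = eta + H0)
      lp <- target(par)  # refresh after w move
    }
    st <- mh_step(par, lp, lap$chol, target)
    par <- st$par; lp <- st$lp
    if (it > warmup) {
      k <- it - warmup
      out$par[k, ] <- par
      out$acc <- out$acc + st$acc
      if (nts) w_sum <- w_sum + w
    }
  }
  out$acc <- out$acc / n_keep
  if (nts) out$w_mean <- w_sum / n_keep
  out
}

collect_surv_fit <- function(chains, mcmc, method, extra = list()) {
  draws <- list(
    gamma0 = sapply(chains, function(ch) ch$par[, 1]),
    gamma1 = sapply(chains, function(ch) ch$par[, 2]),
    alpha = sapply(chains, function(ch) ch$par[, 3])
  )
  summary <- summarize_draws(draws)
  extra$accept <- mean(vapply(chains, `[[`, numeric(1), "acc"))
  new_fit(summary, draws, mcmc, method, extra = extra)
}

#' Standard two-stage survival fit (STS)
#'
#' Fits the proportional-hazards submodel with the stage-1 posterior-mean
#' trajectory treated as a fixed endogenous time-varying covariate.  The
#' plug-in deliberately discards stage-1 uncertainty; the resulting
#' association estimate is attenuated, which the bias-corrected variant
#' [fit_survival_nts()] addresses.
#'
#' @param data a \code{joint_data} object.
#' @param stage1 the \code{stage1} element of a [fit_longitudinal()] fit
#'   on the same data (or a compatible list with \code{intercept} and
#'   \code{slope} vectors).
#' @param priors a [default_priors()] specification.
#' @param mcmc an [mcmc_config()]; the conventional stage-2 size is 1000
#'   iterations per chain with 500 warmup.
#' @return A \code{jm_fit} over (gamma0, gamma1, alpha).
#' @export
fit_survival_sts <- function(data, stage1, priors = default_priors(),
                             mcmc = mcmc_config(iter = 1000, warmup = 500)) {
  surv <- data$survival
  if (length(stage1$intercept) != nrow(surv)) {
    stop("stage-1 estimates are not aligned with the dataset")
  }
  chains <- lapply(seq_len(mcmc$chains), function(ch) {
    surv_mh_chain(stage1$intercept, stage1$slope, surv$x, surv$T,
                  surv$delta, priors, mcmc$iter, mcmc$warmup,
                  derive_seed(mcmc$seed, 201L, ch))
  })
  collect_surv_fit(chains, mcmc, "STS")
}

#' Bias-corrected two-stage survival fit (NTS)
#'
#' As [fit_survival_sts()], but the hazard of each subject carries an
#' individual multiplicative fixed effect \eqn{w_i} with informative
#' \eqn{\mathrm{Gamma}(\eta, \eta)} prior (mean 1, variance \eqn{1/\eta}).
#' The small perturbation absorbs the bias introduced by ignoring stage-1
#' uncertainty.  \eqn{\eta} is a known constant and is never sampled; as
#' \eqn{\eta \to \infty} the fit reduces to the standard two-stage one.
#'
#' @inheritParams fit_survival_sts
#' @return A \code{jm_fit} over (gamma0, gamma1, alpha) with extra elements
#'   \code{w_hat} (posterior means of the multipliers) and \code{eta}.
#' @export
fit_survival_nts <- function(data, stage1, priors = default_priors(),
                             mcmc = mcmc_config(iter = 1000, warmup = 500)) {
  surv <- data$survival
  if (length(stage1$intercept) != nrow(surv)) {
    stop("stage-1 estimates are not aligned with the dataset")
  }
  chains <- lapply(seq_len(mcmc$chains), function(ch) {
    surv_mh_chain(stage1$intercept, stage1$slope, surv$x, surv$T,
                  surv$delta, priors, mcmc$iter, mcmc$warmup,
                  derive_seed(mcmc$seed, 301L, ch), eta = priors$eta)
  })
  w_hat <- Reduce(`+`, lapply(chains, `[[`, "w_mean")) / length(chains)
  collect_surv_fit(chains, mcmc, "NTS",
                   extra = list(w_hat = w_hat, eta = priors$eta))
}
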