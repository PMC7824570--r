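# Joint-specification fitter: simultaneous posterior over the longitudinal
# and survival parameters under the shared-parameter factorisation.  The
# sampler is Metropolis-within-Gibbs:
#   * b_i: independence proposal from the exact longitudinal conditional,
#     accepted on the subject's survival-likelihood ratio (vectorised over
#     subjects, which are conditionally independent);
#   * beta: independence proposal from the longitudinal conditional given b,
#     accepted on the total survival-likelihood ratio;
#   * Sigma: exact conjugate inverse-Wishart draw;
#   * sigma: Metropolis on the log scale (half-Cauchy prior);
#   * (gamma0, gamma1, alpha): random-walk Metropolis with a Laplace
#     proposal recalibrated at the start of sampling.

# total survival log-likelihood given all current parameters
js_surv_ll <- function(ss, beta, b, gamma, alpha) {
  a <- beta[1] + b[, 1] + beta[3] * ss$x
  s <- beta[2] + b[, 2]
  cc <- gamma[1] + gamma[2] * ss$x + alpha * a
  d <- alpha * s
  log_lik_survival(cc, d, 1, ss$T, ss$delta)
}

js_chain <- function(ss, priors, n_iter, warmup, chain_seed) {
  set.seed(chain_seed)
  n <- ss$n
  XtX <- pooled_xtx(ss)
  prior_prec <- 1 / priors$normal_sd^2
  # warm start: a short longitudinal-only Gibbs run to land in the typical
  # set, then a Laplace calibration of the survival block at the plug-ins
  init <- gibbs_long_chain(ss, priors, 300, 150,
                           derive_seed(chain_seed, 1L))
  beta <- colMeans(init$beta)
  sigma <- mean(init$sigma)
  Sg <- colMeans(init$Sigma)
  Sigma <- matrix(c(Sg[1], Sg[2], Sg[2], Sg[3]), 2, 2)
  b <- init$b_mean
  a0 <- beta[1] + b[, 1] + beta[3] * ss$x
  s0 <- beta[2] + b[, 2]
  lap <- surv_laplace(a0, s0, ss$x, ss$T, ss$delta, rep(1, n),
                      priors$normal_sd)
  gamma <- lap$mode[1:2]
  alpha <- lap$mode[3]
  surv_ll <- js_surv_ll(ss, beta, b, gamma, alpha)
  n_keep <- n_iter - warmup
  out <- list(beta = matrix(NA_real_, n_keep, 3), sigma = numeric(n_keep),
              Sigma = matrix(NA_real_, n_keep, 3),
              gamma = matrix(NA_real_, n_keep, 2), alpha = numeric(n_keep),
              acc_b = 0, acc_beta = 0, acc_surv = 0)
  b_sum <- matrix(0, n, 2)
  ls_scale <- 0.05
  for (it in seq_len(n_iter)) {
    # --- b: independence MH from the longitudinal conditional ---
    Sigma_inv <- solve(Sigma)
    b_prop <- draw_b(ss, beta, sigma, Sigma_inv,
                     stats::rnorm(n), stats::rnorm(n))
    ll_prop <- js_surv_ll(ss, beta, b_prop, gamma, alpha)
    acc <- log(stats::runif(n)) < (ll_prop - surv_ll)
    acc[!is.finite(ll_prop)] <- FALSE
    b[acc, ] <- b_prop[acc, ]
    surv_ll[acc] <- ll_prop[acc]
    # --- beta: independence MH from the longitudinal conditional ---
    cond <- beta_conditional(ss, XtX, b, sigma, prior_prec)
    beta_prop <- draw_beta(cond, stats::rnorm(3))
    ll_prop <- js_surv_ll(ss, beta_prop, b, gamma, alpha)
    acc_beta <- is.finite(sum(ll_prop)) &&
      log(stats::runif(1)) < (sum(ll_prop) - sum(surv_ll))
    if (acc_beta) { beta <- beta_prop; surv_ll <- ll_prop }
    # --- Sigma: conjugate ---
    Sigma <- draw_Sigma(b, priors$wishart_V, priors$wishart_df)
    # --- sigma: Metropolis on the log scale ---
    a_i <- beta[1] + b[, 1] + beta[3] * ss$x
    s_i <- beta[2] + b[, 2]
    rss <- rss_from_stats(ss, a_i, s_i)
    ls <- log(sigma)
    ls_prop <- ls + ls_scale * stats::rnorm(1)
    log_r <- log_sigma_target(ls_prop, ss$N, rss, priors$cauchy_scale) -
      log_sigma_target(ls, ss$N, rss, priors$cauchy_scale)
    acc_s <- is.finite(log_r) && log(stats::runif(1)) < log_r
    if (acc_s) sigma <- exp(ls_prop)
    # --- (gamma, alpha): random-walk MH ---
    par <- c(gamma, alpha)
    target <- function(p) {
      cc <- p[1] + p[2] * ss$x + p[3] * a_i
      d <- p[3] * s_i
      sum(log_lik_survival(cc, d, 1, ss$T, ss$delta)) +
        sum(stats::dnorm(p, 0, priors$normal_sd, log = TRUE))
    }
    st <- mh_step(par, target(par), lap$chol, target)
    if (st$acc) {
      gamma <- st$par[1:2]; alpha <- st$par[3]
      surv_ll <- js_surv_ll(ss, beta, b, gamma, alpha)
    }
    if (it <= warmup) {
      ls_scale <- ls_scale * exp((as.numeric(acc_s) - 0.44) / sqrt(it))
    } else {
      k <- it - warmup
      out$beta[k, ] <- beta
      out$sigma[k] <- sigma
      out$Sigma[k, ] <- c(Sigma[1, 1], Sigma[1, 2], Sigma[2, 2])
      out$gamma[k, ] <- gamma
      out$alpha[k] <- alpha
      b_sum <- b_sum + b
      out$acc_b <- out$acc_b + mean(acc)
      out$acc_beta <- out$acc_beta + acc_beta
      out$acc_surv <- out$acc_surv + st$acc
    }
  }
  out$b_mean <- b_sum / n_keep
  out$acc_b <- out$acc_b / n_keep
  out$acc_beta <- out$acc_beta / n_keep
  out$acc_surv <- out$acc_surv / n_keep
  out
}

#' Joint-specification fit (JS)
#'
#' Simultaneous Bayesian fit of the longitudinal and survival submodels
#' under the shared-parameter factorisation: the two outcomes are
#' conditionally independent given the subject random effects, which enter
#' the hazard through the current trajectory value.  The survival
#' likelihood uses the closed-form cumulative hazard with the sampled
#' random effects (no plug-in).
#'
#' @param data a \code{joint_data} object.
#' @param priors a [default_priors()] specification.
#' @param mcmc an [mcmc_config()]; the conventional size is 2000 iterations
#'   per chain with 1000 warmup.
#' @return A \code{jm_fit} over (beta, sigma, Sigma, gamma, alpha) with an
#'   extra \code{b_hat} element (posterior means of the random effects) and
#'   \code{accept} acceptance-rate diagnostics.
#' @export
fit_joint_js <- function(data, priors = default_priors(),
                         mcmc = mcmc_config()) {
  ss <- suff_stats(data)
  chains <- lapply(seq_len(mcmc$chains), function(ch) {
    js_chain(ss, priors, mcmc$iter, mcmc$warmup,
             derive_seed(mcmc$seed, 401L, ch))
  })
  draws <- list(
    beta0 = sapply(chains, function(ch) ch$beta[, 1]),
    beta1 = sapply(chains, function(ch) ch$beta[, 2]),
    beta2 = sapply(chains, function(ch) ch$beta[, 3]),
    sigma = sapply(chains, function(ch) ch$sigma),
    Sigma11 = sapply(chains, function(ch) ch$Sigma[, 1]),
    Sigma12 = sapply(chains, function(ch) ch$Sigma[, 2]),
    Sigma22 = sapply(chains, function(ch) ch$Sigma[, 3]),
    gamma0 = sapply(chains, function(ch) ch$gamma[, 1]),
    gamma1 = sapply(chains, function(ch) ch$gamma[, 2]),
    alpha = sapply(chains, function(ch) ch$alpha)
  )
  summary <- summarize_draws(draws)
  b_hat <- Reduce(`+`, lapply(chains, `[[`, "b_mean")) / length(chains)
  accept <- c(b = mean(sapply(chains, `[[`, "acc_b")),
              beta = mean(sapply(chains, `[[`, "acc_beta")),
              surv = mean(sapply(chains, `[[`, "acc_surv")))
  new_fit(summary, draws, mcmc, "JS",
          extra = list(b_hat = b_hat, accept = accept))
}

#' Log joint density of the shared-parameter model
#'
#' Evaluates the (unnormalised only through the half-Cauchy and
#' inverse-Wishart constants, which are included) log joint density
#' \eqn{\log f(y, s, b, \theta)}: longitudinal likelihood + survival
#' likelihood + random-effects density + log priors.  This is the target
#' distribution of [fit_joint_js()] and is exposed for verification.
#'
#' @param data a \code{joint_data} object.
#' @param beta,b,sigma,Sigma,gamma,alpha a full parameter state; \code{b}
#'   is n x 2.
#' @param priors a [default_priors()] specification.
#' @return Scalar log density.
#' @export
js_log_density <- function(data, beta, b, sigma, Sigma, gamma, alpha,
                           priors = default_priors()) {
  surv <- data$survival
  long <- data$longitudinal
  idx <- match(long$id, surv$id)
  mu <- (beta[1] + b[idx, 1]) + (beta[2] + b[idx, 2]) * long$time +
    beta[3] * long$x
  ll_long <- sum(stats::dnorm(long$y, mu, sigma, log = TRUE))
  lh <- linear_hazard(beta, b, gamma, alpha, surv$x)
  ll_surv <- sum(log_lik_survival(lh$c, lh$d, lh$w, surv$T, surv$delta))
  Sinv <- solve(Sigma)
  logdet <- determinant(Sigma, logarithm = TRUE)$modulus[1]
  qf <- rowSums((b %*% Sinv) * b)
  ll_b <- sum(-log(2 * pi) - 0.5 * logdet - 0.5 * qf)
  lp <- sum(stats::dnorm(c(beta, gamma, alpha), 0, priors$normal_sd,
                         log = TRUE)) +
    log_half_cauchy(sigma, priors$cauchy_scale) +
    log_inv_wishart(Sigma, priors$wishart_V, priors$wishart_df)
  ll_long + ll_surv + ll_b + lp
}
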