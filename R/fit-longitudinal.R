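# Stage-1 fitter: blocked Gibbs sampler for the linear mixed-effects
# longitudinal submodel with random intercept and slope.  Conjugate updates
# for beta, b and Sigma; Metropolis update on log(sigma) for the
# half-Cauchy residual-SD prior.  All per-subject computations run on
# sufficient statistics (n_i, sum t, sum t^2, sum y, sum ty, sum y^2), so
# one iteration is O(n) regardless of the number of measurements.

# Per-subject sufficient statistics aligned with the survival table order.
suff_stats <- function(data) {
  stopifnot(inherits(data, "joint_data"))
  long <- data$longitudinal
  surv <- data$survival
  idx <- match(long$id, surv$id)
  if (anyNA(idx)) stop("longitudinal ids missing from survival table")
  n <- nrow(surv)
  agg <- function(v) {
    out <- numeric(n)
    s <- rowsum(v, idx)
    out[as.integer(rownames(s))] <- s
    out
  }
  t <- long$time; y <- long$y
  list(
    n = n,
    n_i = agg(rep(1, length(t))),
    St = agg(t), Stt = agg(t * t),
    Sy = agg(y), Sty = agg(t * y), Syy = agg(y * y),
    x = surv$x, T = surv$T, delta = surv$delta,
    N = length(y)
  )
}

# pooled design cross-products for the fixed-effects update
pooled_xtx <- function(ss) {
  Sn <- sum(ss$n_i); St <- sum(ss$St); Stt <- sum(ss$Stt)
  Snx <- sum(ss$x * ss$n_i); Stx <- sum(ss$x * ss$St)
  matrix(c(Sn, St, Snx,
           St, Stt, Stx,
           Snx, Stx, Snx), 3, 3)
}

# residual sum of squares given subject intercepts a and slopes s
rss_from_stats <- function(ss, a, s) {
  sum(ss$Syy - 2 * a * ss$Sy - 2 * s * ss$Sty +
        a^2 * ss$n_i + 2 * a * s * ss$St + s^2 * ss$Stt)
}

# one conjugate draw of b (n x 2) given beta, sigma, Sigma
draw_b <- function(ss, beta, sigma, Sigma_inv, z1, z2) {
  s2 <- sigma^2
  p11 <- ss$n_i / s2 + Sigma_inv[1, 1]
  p12 <- ss$St / s2 + Sigma_inv[1, 2]
  p22 <- ss$Stt / s2 + Sigma_inv[2, 2]
  m1 <- (ss$Sy - beta[1] * ss$n_i - beta[2] * ss$St -
           beta[3] * ss$x * ss$n_i) / s2
  m2 <- (ss$Sty - beta[1] * ss$St - beta[2] * ss$Stt -
           beta[3] * ss$x * ss$St) / s2
  det <- p11 * p22 - p12^2
  V11 <- p22 / det; V12 <- -p12 / det; V22 <- p11 / det
  mu1 <- V11 * m1 + V12 * m2
  mu2 <- V12 * m1 + V22 * m2
  L11 <- sqrt(V11); L21 <- V12 / L11; L22 <- sqrt(pmax(V22 - L21^2, 0))
  cbind(mu1 + L11 * z1, mu2 + L21 * z1 + L22 * z2)
}

# conditional Normal parameters for beta given b and sigma
beta_conditional <- function(ss, XtX, b, sigma, prior_prec) {
  s2 <- sigma^2
  r1 <- sum(ss$Sy) - sum(b[, 1] * ss$n_i + b[, 2] * ss$St)
  r2 <- sum(ss$Sty) - sum(b[, 1] * ss$St + b[, 2] * ss$Stt)
  r3 <- sum(ss$x * (ss$Sy - b[, 1] * ss$n_i - b[, 2] * ss$St))
  A <- XtX / s2 + diag(prior_prec, 3)
  list(A = A, rhs = c(r1, r2, r3) / s2)
}

draw_beta <- function(cond, z) {
  R <- chol(cond$A)
  mean <- backsolve(R, forwardsolve(t(R), cond$rhs))
  mean + backsolve(R, z)
}

draw_Sigma <- function(b, V0, df0) {
  Sb <- crossprod(b)
  W <- stats::rWishart(1, df = df0 + nrow(b), Sigma = solve(V0 + Sb))[, , 1]
  solve(W)
}

# log posterior kernel of log(sigma) given residual sum of squares
log_sigma_target <- function(ls, N, rss, cauchy_scale) {
  sigma <- exp(ls)
  -N * ls - rss / (2 * sigma^2) + log_half_cauchy(sigma, cauchy_scale) + ls
}

gibbs_long_chain <- function(ss, priors, n_iter, warmup, chain_seed,
                             keep_b_draws = FALSE) {
  set.seed(chain_seed)
  XtX <- pooled_xtx(ss)
  n <- ss$n
  # start from the pooled least-squares fit
  Xty <- c(sum(ss$Sy), sum(ss$Sty), sum(ss$x * ss$Sy))
  beta <- as.vector(solve(XtX + diag(1e-8, 3), Xty))
  b <- matrix(0, n, 2)
  sigma <- sqrt(max(rss_from_stats(ss, beta[1] + beta[3] * ss$x,
                                   rep(beta[2], n)) / ss$N, 1e-4))
  Sigma <- diag(c(0.1, 0.01))
  prior_prec <- 1 / priors$normal_sd^2
  n_keep <- n_iter - warmup
  out <- list(beta = matrix(NA_real_, n_keep, 3),
              sigma = numeric(n_keep),
              Sigma = matrix(NA_real_, n_keep, 3))
  b_sum <- matrix(0, n, 2)
  ls_scale <- 0.1
  for (it in seq_len(n_iter)) {
    Sigma_inv <- solve(Sigma)
    b <- draw_b(ss, beta, sigma, Sigma_inv,
                stats::rnorm(n), stats::rnorm(n))
    cond <- beta_conditional(ss, XtX, b, sigma, prior_prec)
    beta <- draw_beta(cond, stats::rnorm(3))
    Sigma <- draw_Sigma(b, priors$wishart_V, priors$wishart_df)
    # Metropolis on log sigma
    a_i <- beta[1] + b[, 1] + beta[3] * ss$x
    s_i <- beta[2] + b[, 2]
    rss <- rss_from_stats(ss, a_i, s_i)
    ls <- log(sigma)
    ls_prop <- ls + ls_scale * stats::rnorm(1)
    log_r <- log_sigma_target(ls_prop, ss$N, rss, priors$cauchy_scale) -
      log_sigma_target(ls, ss$N, rss, priors$cauchy_scale)
    acc <- is.finite(log_r) && log(stats::runif(1)) < log_r
    if (acc) sigma <- exp(ls_prop)
    if (it <= warmup) {
      ls_scale <- ls_scale * exp((as.numeric(acc) - 0.44) / sqrt(it))
    } else {
      k <- it - warmup
      out$beta[k, ] <- beta
      out$sigma[k] <- sigma
      out$Sigma[k, ] <- c(Sigma[1, 1], Sigma[1, 2], Sigma[2, 2])
      b_sum <- b_sum + b
    }
  }
  out$b_mean <- b_sum / n_keep
  out
}

#' Fit the longitudinal submodel (stage 1)
#'
#' Blocked Gibbs sampler for the random-intercept-and-slope mixed model
#' under diffuse Normal priors on the fixed effects, a half-Cauchy prior on
#' the residual SD and an inverse-Wishart prior on the random-effects
#' covariance.  Returns, alongside the posterior summary, the stage-one
#' plug-in estimates: posterior means of the fixed and random effects and
#' the implied per-subject trajectory coefficients.
#'
#' @param data a \code{joint_data} object (simulated or read from files).
#' @param priors a [default_priors()] specification.
#' @param mcmc an [mcmc_config()]; the conventional stage-1 size is 2000
#'   iterations per chain with 1000 warmup.
#' @return A \code{jm_fit} with an extra \code{stage1} element: list with
#'   \code{beta_hat}, \code{b_hat} (n x 2), \code{intercept} and
#'   \code{slope} (per-subject plug-in trajectory coefficients).
#' @export
fit_longitudinal <- function(data, priors = default_priors(),
                             mcmc = mcmc_config()) {
  ss <- suff_stats(data)
  if (any(ss$n_i < 1)) stop("every subject needs at least one measurement")
  chains <- lapply(seq_len(mcmc$chains), function(ch) {
    gibbs_long_chain(ss, priors, mcmc$iter, mcmc$warmup,
                     derive_seed(mcmc$seed, 101L, ch))
  })
  draws <- list(
    beta0 = sapply(chains, function(ch) ch$beta[, 1]),
    beta1 = sapply(chains, function(ch) ch$beta[, 2]),
    beta2 = sapply(chains, function(ch) ch$beta[, 3]),
    sigma = sapply(chains, function(ch) ch$sigma),
    Sigma11 = sapply(chains, function(ch) ch$Sigma[, 1]),
    Sigma12 = sapply(chains, function(ch) ch$Sigma[, 2]),
    Sigma22 = sapply(chains, function(ch) ch$Sigma[, 3])
  )
  summary <- summarize_draws(draws)
  beta_hat <- c(mean(draws$beta0), mean(draws$beta1), mean(draws$beta2))
  b_hat <- Reduce(`+`, lapply(chains, `[[`, "b_mean")) / length(chains)
  stage1 <- list(
    beta_hat = beta_hat,
    b_hat = b_hat,
    intercept = beta_hat[1] + b_hat[, 1] + beta_hat[3] * ss$x,
    slope = beta_hat[2] + b_hat[, 2]
  )
  new_fit(summary, draws, mcmc, "longitudinal",
          extra = list(stage1 = stage1))
}
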