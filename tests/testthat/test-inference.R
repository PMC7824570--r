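test_that("default priors encode the documented specification", {
  pr <- default_priors()
  expect_equal(pr$eta, 1.5)
  expect_equal(1 / pr$eta, 2 / 3, tolerance = 0.01) # Var(w) = 1/eta ~ 0.67
  expect_equal(pr$normal_sd, 100)
  expect_equal(pr$cauchy_scale, 5)
  expect_equal(pr$wishart_V, diag(2))
  expect_equal(pr$wishart_df, 2)
  pr3 <- default_priors(K = 3)
  expect_equal(dim(pr3$wishart_V), c(3L, 3L))
  expect_equal(pr3$wishart_df, 3)
  expect_error(default_priors(normal_sd = -1), "> 0")
  expect_error(default_priors(eta = 0), "> 0")
})

test_that("stage-1 fit recovers parameters in the low-noise limit", {
  p <- prothro_params()
  truth <- joint_params(p$beta, diag(c(1e-8, 1e-8)), 0.001, p$gamma, p$alpha)
  dat <- simulate_joint(sim_config(truth, 200, seed = 111L))
  fit <- fit_longitudinal(dat, mcmc = mcmc_config(iter = 800, warmup = 400,
                                                  seed = 3L))
  sm <- fit$summary
  est <- sm$mean[match(c("beta0", "beta1", "beta2"), sm$parameter)]
  expect_lt(max(abs(est - p$beta)), 0.01)
})

test_that("stage-1 posterior agrees with an independent mixed-model fit", {
  skip_if_not_installed("lme4")
  dat <- sim_small(n = 150, seed = 202L)
  fit <- fit_longitudinal(dat, mcmc = mcmc_config(seed = 4L))
  sm <- fit$summary
  lmer_fit <- lme4::lmer(y ~ time + x + (1 + time | id),
                         data = dat$longitudinal, REML = FALSE)
  fe <- lme4::fixef(lmer_fit)
  se <- sqrt(diag(as.matrix(vcov(lmer_fit))))
  for (k in 1:3) {
    par <- c("beta0", "beta1", "beta2")[k]
    expect_lt(abs(sm$mean[sm$parameter == par] - fe[k]), 3 * se[k])
  }
  expect_lt(abs(sm$mean[sm$parameter == "sigma"] -
                  stats::sigma(lmer_fit)), 0.02)
  # plug-in estimates are aligned and internally consistent
  s1 <- fit$stage1
  expect_equal(length(s1$intercept), nrow(dat$survival))
  expect_equal(s1$intercept,
               s1$beta_hat[1] + s1$b_hat[, 1] +
                 s1$beta_hat[3] * dat$survival$x)
})

test_that("null-association survival fit matches the exponential-rate oracle", {
  p <- prothro_params()
  truth <- joint_params(p$beta, p$Sigma, p$sigma, gamma = c(-1.0, 0),
                        alpha = 0)
  dat <- simulate_joint(sim_config(truth, 250, seed = 121L))
  f1 <- fit_longitudinal(dat, mcmc = mcmc_config(iter = 800, warmup = 400,
                                                 seed = 5L))
  sts <- fit_survival_sts(dat, f1$stage1,
                          mcmc = mcmc_config(iter = 1000, warmup = 500,
                                             seed = 6L))
  sm <- sts$summary
  # crude exponential MLE of the baseline log-rate
  crude <- log(sum(dat$survival$delta) / sum(dat$survival$T))
  g0 <- sm$mean[sm$parameter == "gamma0"]
  a <- sm$mean[sm$parameter == "alpha"]
  # with alpha ~ 0 the linear predictor reduces to gamma0 (+ alpha * mu);
  # compare the implied baseline at the mean plug-in trajectory
  expect_lt(abs(g0 + a * mean(f1$stage1$intercept) - crude),
            3 * sm$sd[sm$parameter == "gamma0"])
  expect_lt(abs(a), 3 * sm$sd[sm$parameter == "alpha"])
})

test_that("survival fits are deterministic under a fixed seed", {
  dat <- sim_small(n = 80, seed = 303L)
  f1 <- fit_longitudinal(dat, mcmc = mcmc_config(iter = 600, warmup = 300,
                                                 seed = 7L))
  mc <- mcmc_config(iter = 600, warmup = 300, seed = 8L)
  a <- fit_survival_sts(dat, f1$stage1, mcmc = mc)
  b <- fit_survival_sts(dat, f1$stage1, mcmc = mc)
  expect_identical(a$summary, b$summary)
  a <- fit_survival_nts(dat, f1$stage1, mcmc = mc)
  b <- fit_survival_nts(dat, f1$stage1, mcmc = mc)
  expect_identical(a$summary, b$summary)
  expect_identical(a$w_hat, b$w_hat)
})

test_that("NTS multipliers stay in a band around their prior mean of one", {
  dat <- sim_small(n = 150, seed = 505L)
  f1 <- fit_longitudinal(dat, mcmc = mcmc_config(seed = 9L))
  nts <- fit_survival_nts(dat, f1$stage1,
                          mcmc = mcmc_config(iter = 1000, warmup = 500,
                                             seed = 10L))
  expect_equal(nts$eta, 1.5)
  expect_gt(mean(nts$w_hat > 0.2 & nts$w_hat < 3), 0.95)
  expect_lt(abs(mean(nts$w_hat) - 1), 0.35)
})

test_that("NTS approaches STS as eta grows", {
  dat <- sim_small(n = 120, seed = 606L)
  f1 <- fit_longitudinal(dat, mcmc = mcmc_config(seed = 11L))
  mc <- mcmc_config(iter = 1000, warmup = 500, seed = 12L)
  sts <- fit_survival_sts(dat, f1$stage1, mcmc = mc)
  dist_to_sts <- function(eta) {
    nts <- fit_survival_nts(dat, f1$stage1,
                            priors = default_priors(eta = eta), mcmc = mc)
    idx <- match(c("gamma1", "alpha"), nts$summary$parameter)
    sum(abs(nts$summary$mean[idx] -
              sts$summary$mean[match(c("gamma1", "alpha"),
                                     sts$summary$parameter)]))
  }
  d_small <- dist_to_sts(1.5)
  d_big <- dist_to_sts(1e4)
  # the perturbation vanishes as Var(w) = 1/eta -> 0
  expect_lt(d_big, d_small)
  expect_lt(d_big, 0.1)
})

test_that("joint fit concentrates the association near zero under a null truth", {
  p <- prothro_params()
  truth <- joint_params(p$beta, p$Sigma, p$sigma, gamma = c(-1.0, -0.2),
                        alpha = 0)
  dat <- simulate_joint(sim_config(truth, 200, seed = 131L))
  js <- fit_joint_js(dat, mcmc = mcmc_config(seed = 13L))
  sm <- js$summary
  a <- sm[sm$parameter == "alpha", ]
  expect_lt(abs(a$mean), 3 * a$sd)
  expect_true(a$q2.5 < 0 & a$q97.5 > 0)
})

test_that("joint fit reduces to the longitudinal fit when events are absent", {
  p <- prothro_params()
  # hazard made negligible: no events, survival likelihood nearly flat
  truth <- joint_params(p$beta, p$Sigma, p$sigma, gamma = c(-30, 0),
                        alpha = 0)
  dat <- simulate_joint(sim_config(truth, 120, seed = 141L))
  expect_equal(sum(dat$survival$delta), 0)
  f1 <- fit_longitudinal(dat, mcmc = mcmc_config(seed = 14L))
  js <- fit_joint_js(dat, mcmc = mcmc_config(seed = 15L))
  for (par in c("beta0", "beta2", "sigma")) {
    m1 <- f1$summary[f1$summary$parameter == par, ]
    m2 <- js$summary[js$summary$parameter == par, ]
    mcse <- sqrt(m1$sd^2 / m1$ess + m2$sd^2 / m2$ess)
    expect_lt(abs(m1$mean - m2$mean), 5 * mcse)
  }
})

test_that("convergence diagnostics are reported for every parameter", {
  dat <- sim_small(n = 60, seed = 707L)
  f1 <- fit_longitudinal(dat, mcmc = mcmc_config(iter = 600, warmup = 300,
                                                 seed = 16L))
  expect_true(all(is.finite(f1$summary$rhat)))
  expect_true(all(is.finite(f1$summary$ess)))
  expect_true(all(f1$summary$sd >= 0))
  expect_type(f1$converged, "logical")
})
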