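# MCMC configuration, convergence diagnostics (split-Rhat, effective sample
# size) and posterior summarisation shared by all fitters.

#' MCMC configuration
#'
#' @param chains number of chains (>= 2 so split-Rhat is meaningful).
#' @param iter total iterations per chain, including warmup.
#' @param warmup iterations discarded per chain, < \code{iter}.
#' @param seed integer seed; per-chain seeds derive from it.
#' @param rhat_threshold convergence bound flagged in fit results.
#' @param min_ess minimum effective sample size flagged in fit results.
#' @return An object of class \code{"mcmc_config"}.
#' @export
mcmc_config <- function(chains = 2, iter = 2000, warmup = 1000, seed = 1L,
                        rhat_threshold = 1.05, min_ess = 100) {
  if (warmup >= iter) stop("`warmup` must be < `iter`")
  if (chains < 2) stop("`chains` must be >= 2 for convergence diagnostics")
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 rhat_threshold = rhat_threshold, min_ess = min_ess),
            class = "mcmc_config")
}

# draws: iterations x chains matrix of one scalar parameter (post-warmup).
split_chains <- function(draws) {
  n <- nrow(draws)
  half <- floor(n / 2)
  cbind(draws[seq_len(half), , drop = FALSE],
        draws[(n - half + 1):n, , drop = FALSE])
}

#' Split-Rhat potential scale reduction factor
#'
#' @param draws iterations x chains matrix of post-warmup draws of one
#'   parameter.
#' @return Scalar Rhat (NA for constant draws).
#' @export
rhat <- function(draws) {
  draws <- as.matrix(draws)
  sp <- split_chains(draws)
  n <- nrow(sp); m <- ncol(sp)
  if (n < 2) return(NA_real_)
  means <- colMeans(sp)
  vars <- apply(sp, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size
#'
#' Autocorrelation-based ESS across split chains, truncating the
#' autocorrelation sum at the first negative paired (Geyer) term.
#'
#' @inheritParams rhat
#' @return Scalar effective sample size.
#' @export
ess <- function(draws) {
  draws <- as.matrix(draws)
  sp <- split_chains(draws)
  n <- nrow(sp); m <- ncol(sp)
  if (n < 4) return(NA_real_)
  means <- colMeans(sp)
  vars <- apply(sp, 2, stats::var)
  W <- mean(vars)
  var_plus <- (n - 1) / n * W + stats::var(means)
  if (!is.finite(var_plus) || var_plus <= 0) return(NA_real_)
  max_lag <- min(n - 1, 500)
  # mean autocovariance across chains at each lag
  acov <- sapply(seq_len(m), function(j) {
    a <- stats::acf(sp[, j], lag.max = max_lag, plot = FALSE,
                    type = "covariance", demean = TRUE)$acf[, 1, 1]
    a
  })
  acov <- rowMeans(acov)
  rho <- 1 - (W - acov[-1]) / var_plus
  # Geyer initial positive sequence on paired sums
  tau <- 1
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (!is.finite(pair) || pair < 0) break
    tau <- tau + 2 * pair
    t <- t + 2
  }
  max(m * n / tau, 1)
}

# draws_list: named list; each element an iterations x chains matrix.
# Returns the standard posterior-summary table.
summarize_draws <- function(draws_list) {
  rows <- lapply(names(draws_list), function(nm) {
    d <- as.matrix(draws_list[[nm]])
    v <- as.vector(d)
    q <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
    data.frame(parameter = nm, mean = mean(v), sd = stats::sd(v),
               q2.5 = q[1], q97.5 = q[2], rhat = rhat(d), ess = ess(d),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Shared result wrapper: flags convergence against the config thresholds.
new_fit <- function(summary, draws, mcmc, method, extra = list()) {
  bad <- !is.na(summary$rhat) & summary$rhat > mcmc$rhat_threshold
  low <- !is.na(summary$ess) & summary$ess < mcmc$min_ess
  out <- c(list(summary = summary, draws = draws, method = method,
                mcmc = mcmc,
                converged = !any(bad),
                flagged = summary$parameter[bad | low]),
           extra)
  class(out) <- "jm_fit"
  out
}

#' @export
print.jm_fit <- function(x, ...) {
  cat(sprintf("Bayesian fit (%s), %d chains x %d post-warmup iterations\n",
              x$method, x$mcmc$chains, x$mcmc$iter - x$mcmc$warmup))
  print(x$summary, row.names = FALSE, digits = 4)
  if (!x$converged) {
    cat("WARNING: convergence flagged for:",
        paste(x$flagged, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Posterior summary table of a fit
#'
#' @param fit a fit returned by [fit_longitudinal()], [fit_survival_sts()],
#'   [fit_survival_nts()] or [fit_joint_js()].
#' @return data.frame with columns parameter, mean, sd, q2.5, q97.5, rhat,
#'   ess.
#' @export
posterior_summary <- function(fit) {
  stopifnot(inherits(fit, "jm_fit"))
  fit$summary
}
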