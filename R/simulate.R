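# Joint-data simulator: covariates and random effects, inverse-transform
# event times from the closed-form survival function, uniform censoring,
# equispaced measurement schedules anchored at 0 and T, Gaussian noise.

# Deterministic 32-bit stream seed derived from a master seed and integer
# tags; keeps every RNG use on its own substream so that, e.g., changing n
# does not shift the censoring draws.
derive_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  h <- 0
  # multiplier kept small so h * 69069 stays exactly representable in a
  # double (< 2^53); a larger multiplier silently drops the low bits
  for (v in tags) {
    h <- (h * 69069 + (as.double(v) %% 2147483647) + 12345) %% 2147483647
    h <- (h * 69069 + 1) %% 2147483647
  }
  as.integer(h)
}

with_stream <- function(seed, expr) {
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' @param truth a [joint_params()] object holding the generating parameters.
#' @param n number of individuals, >= 1.
#' @param m_min minimum number of longitudinal measurements per subject.
#' @param t_max upper bound of the uniform censoring distribution (also the
#'   maximum observational time).
#' @param seed master integer seed; all substreams derive from it.
#' @return An object of class \code{"sim_config"}.
#' @export
sim_config <- function(truth, n, m_min = 3, t_max = 15, seed = 1L) {
  stopifnot(inherits(truth, "joint_params"))
  if (n < 1) stop("`n` must be >= 1")
  if (m_min < 1) stop("`m_min` must be >= 1")
  if (t_max <= 0) stop("`t_max` must be > 0")
  structure(list(truth = truth, n = as.integer(n), m_min = as.integer(m_min),
                 t_max = t_max, seed = as.integer(seed)),
            class = "sim_config")
}

#' Bernoulli(0.5) group indicators
#'
#' @param n number of draws.
#' @param seed integer seed for the draw.
#' @return Integer vector of 0/1 group labels.
#' @export
sample_group <- function(n, seed = 1L) {
  if (n == 0) return(integer(0))
  with_stream(seed, as.integer(stats::runif(n) < 0.5))
}

#' Multivariate normal random effects
#'
#' Rows are i.i.d. N(0, Sigma) draws, generated via the Cholesky factor.
#'
#' @param n number of subjects.
#' @param Sigma positive-definite covariance matrix.
#' @param seed integer seed.
#' @return n x K matrix of random effects.
#' @export
sample_random_effects <- function(n, Sigma, seed = 1L) {
  L <- tryCatch(chol(Sigma),
                error = function(e) stop("`Sigma` is not positive-definite: ",
                                         conditionMessage(e)))
  K <- ncol(Sigma)
  if (n == 0) return(matrix(numeric(0), 0, K))
  z <- with_stream(seed, matrix(stats::rnorm(n * K), n, K))
  z %*% L
}

#' Uniform censoring applied to latent event times
#'
#' Draws \eqn{C \sim U(0, t_{max})} per subject and returns the observed
#' time \eqn{T = \min(T^*, C)} with event indicator
#' \eqn{\delta = I(T^* \le C)}.  Infinite \eqn{T^*} (a subject whose hazard
#' integrates to a finite total) is always resolved to a censored record.
#'
#' @param t_star latent event times in (0, Inf].
#' @param t_max censoring upper bound.
#' @param seed integer seed.
#' @return data.frame with columns \code{T} and \code{delta}.
#' @export
apply_censoring <- function(t_star, t_max, seed = 1L) {
  if (t_max <= 0) stop("`t_max` must be > 0")
  C <- with_stream(seed, stats::runif(length(t_star), 0, t_max))
  data.frame(T = pmin(t_star, C), delta = as.integer(t_star <= C))
}

#' Equispaced measurement schedule
#'
#' A subject observed until time T receives \eqn{m_{min} + \lfloor T
#' \rfloor} measurements, equispaced from 0 to T inclusive.  With
#' \code{m_min = 1} and \code{T < 1} the schedule degenerates to the single
#' baseline time 0.
#'
#' @param T observed time, > 0.
#' @param m_min minimum number of measurements, >= 1.
#' @return Strictly increasing time vector beginning at 0; when it has more
#'   than one element the last is exactly T.
#' @export
measurement_schedule <- function(T, m_min) {
  if (T <= 0) stop("`T` must be > 0")
  if (m_min < 1) stop("`m_min` must be >= 1")
  n_i <- m_min + floor(T)
  if (n_i == 1) return(0)
  seq(0, T, length.out = n_i)
}

#' Simulate a joint longitudinal-survival dataset
#'
#' Full composition of the generating scheme: group indicators and random
#' effects are drawn, latent event times are obtained by inverse-transform
#' sampling from the closed-form survival function of the exp-linear
#' hazard, censoring times are uniform on (0, t_max), and longitudinal
#' measurements are the subject trajectory plus Gaussian noise on an
#' equispaced schedule from 0 to the observed time.
#'
#' @param cfg a [sim_config()] object.
#' @return An object of class \code{"joint_data"}: a list with elements
#'   \code{longitudinal} (data.frame \code{id, time, y, x}),
#'   \code{survival} (data.frame \code{id, T, delta, x}), \code{b} (n x 2
#'   matrix of true random effects), \code{event_rate}, \code{config}.
#' @export
simulate_joint <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  p <- cfg$truth
  n <- cfg$n
  x <- sample_group(n, derive_seed(cfg$seed, 1L))
  b <- sample_random_effects(n, p$Sigma, derive_seed(cfg$seed, 2L))
  lh <- linear_hazard(p$beta, b, p$gamma, p$alpha, x)
  u <- with_stream(derive_seed(cfg$seed, 3L), stats::runif(n))
  t_star <- sample_event_time(lh$c, lh$d, lh$w, u)
  surv <- apply_censoring(t_star, cfg$t_max, derive_seed(cfg$seed, 4L))
  schedules <- lapply(surv$T, measurement_schedule, m_min = cfg$m_min)
  n_obs <- vapply(schedules, length, integer(1))
  eps <- with_stream(derive_seed(cfg$seed, 5L),
                     stats::rnorm(sum(n_obs), 0, p$sigma))
  id <- rep.int(seq_len(n), n_obs)
  time <- unlist(schedules, use.names = FALSE)
  mu <- (p$beta[1] + b[id, 1]) + (p$beta[2] + b[id, 2]) * time +
    p$beta[3] * x[id]
  long <- data.frame(id = id, time = time, y = mu + eps, x = x[id])
  structure(
    list(
      longitudinal = long,
      survival = data.frame(id = seq_len(n), T = surv$T, delta = surv$delta,
                            x = x),
      b = b,
      event_rate = mean(surv$delta),
      config = cfg
    ),
    class = "joint_data"
  )
}

#' @export
print.joint_data <- function(x, ...) {
  cat(sprintf("Joint dataset: %d subjects, %d measurements, event rate %.3f\n",
              nrow(x$survival), nrow(x$longitudinal), x$event_rate))
  invisible(x)
}
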