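# Independent oracles and tiny fixture builders used across the suite.

# adaptive-quadrature cumulative hazard of h(t) = w * exp(c + d t)
quad_cum_hazard <- function(c, d, w, t) {
  if (t == 0) return(0)
  stats::integrate(function(s) w * exp(c + d * s), 0, t,
                   rel.tol = 1e-12, abs.tol = 0)$value
}

# bisection inverse of S(T) = u, independent of the closed form
bisect_event_time <- function(c, d, w, u) {
  target <- -log(u)
  total <- if (d < 0) w * exp(c) / (-d) else Inf
  if (target >= total) return(Inf)
  f <- function(t) quad_cum_hazard(c, d, w, t) - target
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, c(1e-300, upper), tol = 1e-12)$root
}

# hand-summed bivariate normal log density at mean zero
log_dmvnorm2 <- function(b, Sigma) {
  det <- Sigma[1, 1] * Sigma[2, 2] - Sigma[1, 2]^2
  inv <- matrix(c(Sigma[2, 2], -Sigma[1, 2], -Sigma[1, 2], Sigma[1, 1]),
                2, 2) / det
  q <- inv[1, 1] * b[1]^2 + 2 * inv[1, 2] * b[1] * b[2] + inv[2, 2] * b[2]^2
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

# two-subject hand-built dataset for io and likelihood tests
tiny_joint_data <- function() {
  structure(list(
    longitudinal = data.frame(
      id = c(1L, 1L, 1L, 2L, 2L),
      time = c(0, 0.5, 1.0, 0, 0.75),
      y = c(4.1, 4.0, 3.9, 4.5, 4.4),
      x = c(0L, 0L, 0L, 1L, 1L)
    ),
    survival = data.frame(
      id = c(1L, 2L),
      T = c(1.0, 0.75),
      delta = c(1L, 0L),
      x = c(0L, 1L)
    ),
    b = NULL, event_rate = 0.5, config = NULL
  ), class = "joint_data")
}

# standard small simulated dataset shared by inference tests
sim_small <- function(n = 120, seed = 404L, truth = prothro_params()) {
  simulate_joint(sim_config(truth, n, m_min = 3, t_max = 15, seed = seed))
}
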