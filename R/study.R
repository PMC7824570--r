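# Replication harness: factorial simulation study over sample sizes and
# estimation strategies, aggregation into a comparison table, bias metrics,
# and an eta-sensitivity sweep on shared datasets.

#' Simulation-study configuration
#'
#' @param truth generating [joint_params()]; defaults to the prothrombin
#'   trial values.
#' @param n_grid sample sizes to simulate.
#' @param n_datasets replicate datasets per sample size.
#' @param m_min,t_max simulator settings (see [sim_config()]).
#' @param methods subset of \code{c("JS", "STS", "NTS")}.
#' @param eta_grid optional eta values for [eta_sensitivity()].
#' @param master_seed integer; every replicate seed derives from it.
#' @param mcmc_long MCMC size for the joint fit and stage 1.
#' @param mcmc_surv MCMC size for the stage-2 survival fits.
#' @param priors prior specification shared by all fits.
#' @param checkpoint_dir optional directory; per-replicate records are
#'   written there and reloaded on resume.
#' @return An object of class \code{"study_config"}.
#' @export
study_config <- function(truth = prothro_params(),
                         n_grid = c(200, 500, 1000),
                         n_datasets = 100,
                         m_min = 3, t_max = 15,
                         methods = c("JS", "STS", "NTS"),
                         eta_grid = NULL,
                         master_seed = 1L,
                         mcmc_long = mcmc_config(iter = 2000, warmup = 1000),
                         mcmc_surv = mcmc_config(iter = 1000, warmup = 500),
                         priors = default_priors(),
                         checkpoint_dir = NULL) {
  methods <- match.arg(methods, c("JS", "STS", "NTS"), several.ok = TRUE)
  if (n_datasets < 1) stop("`n_datasets` must be >= 1")
  if (length(n_grid) == 0) stop("`n_grid` must be nonempty")
  structure(list(truth = truth, n_grid = n_grid, n_datasets = n_datasets,
                 m_min = m_min, t_max = t_max, methods = methods,
                 eta_grid = eta_grid, master_seed = as.integer(master_seed),
                 mcmc_long = mcmc_long, mcmc_surv = mcmc_surv,
                 priors = priors, checkpoint_dir = checkpoint_dir),
            class = "study_config")
}

#' Seed of one replicate dataset
#'
#' Replicate seeds are hashed from (master seed, sample size, replicate
#' index) rather than drawn sequentially, so any cell is regenerable in
#' isolation.
#'
#' @param master_seed study master seed.
#' @param n sample size of the cell.
#' @param rep replicate index.
#' @return Integer seed.
#' @export
replicate_seed <- function(master_seed, n, rep) {
  derive_seed(master_seed, 7001L, n, rep)
}

# fit all requested methods on one replicate; returns a records data.frame
fit_replicate <- function(dat, cfg, n, rep, seed, eta = NULL) {
  priors <- cfg$priors
  if (!is.null(eta)) priors$eta <- eta
  need_stage1 <- any(c("STS", "NTS") %in% cfg$methods)
  records <- list()
  push <- function(fit, method) {
    sm <- fit$summary
    sm$method <- method
    sm$n <- n
    sm$replicate <- rep
    sm$seed <- seed
    sm$converged <- fit$converged
    records[[length(records) + 1L]] <<- sm
  }
  run_with_retry <- function(f, mcmc, label) {
    fit <- f(mcmc)
    if (!fit$converged) {
      mcmc2 <- mcmc
      mcmc2$iter <- 2L * mcmc$iter
      mcmc2$warmup <- 2L * mcmc$warmup
      mcmc2$seed <- derive_seed(mcmc$seed, 999L)
      fit <- f(mcmc2)
    }
    push(fit, label)
    fit
  }
  stage1 <- NULL
  if (need_stage1) {
    m1 <- cfg$mcmc_long
    m1$seed <- derive_seed(seed, 11L)
    f1 <- run_with_retry(function(m) fit_longitudinal(dat, priors, m),
                         m1, "stage1")
    stage1 <- f1$stage1
  }
  if ("STS" %in% cfg$methods) {
    m <- cfg$mcmc_surv; m$seed <- derive_seed(seed, 12L)
    run_with_retry(function(mm) fit_survival_sts(dat, stage1, priors, mm),
                   m, "STS")
  }
  if ("NTS" %in% cfg$methods) {
    m <- cfg$mcmc_surv; m$seed <- derive_seed(seed, 13L)
    run_with_retry(function(mm) fit_survival_nts(dat, stage1, priors, mm),
                   m, "NTS")
  }
  if ("JS" %in% cfg$methods) {
    m <- cfg$mcmc_long; m$seed <- derive_seed(seed, 14L)
    run_with_retry(function(mm) fit_joint_js(dat, priors, mm), m, "JS")
  }
  do.call(rbind, records)
}

aggregate_records <- function(records) {
  conv <- records[records$converged, , drop = FALSE]
  key <- interaction(conv$method, conv$n, conv$parameter, drop = TRUE)
  agg <- do.call(rbind, lapply(split(conv, key), function(g) {
    data.frame(method = g$method[1], n = g$n[1], parameter = g$parameter[1],
               mean_of_means = mean(g$mean),
               sd_of_means = stats::sd(g$mean),
               mean_post_sd = mean(g$sd),
               n_converged = nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  tot <- unique(records[, c("method", "n", "replicate")])
  counts <- stats::aggregate(replicate ~ method + n, data = tot, FUN = length)
  names(counts)[3] <- "n_total"
  merge(agg, counts, by = c("method", "n"))
}

#' Run a simulation study
#'
#' For every (sample size, replicate) cell a dataset is simulated under a
#' deterministic [replicate_seed()], each requested estimation strategy is
#' fitted (with one automatic retry at doubled MCMC length when convergence
#' is flagged), and per-replicate posterior summaries are aggregated.
#' Non-converged fits after retry are excluded from aggregates but counted.
#'
#' @param cfg a [study_config()].
#' @param eta optional override of the Gamma concentration used by NTS
#'   (used by the sensitivity sweep).
#' @return An object of class \code{"study_report"}: list with
#'   \code{records} (per replicate x method x parameter) and
#'   \code{aggregates} (mean of posterior means, SD of posterior means,
#'   mean posterior SD, convergence counts) plus the configuration.
#' @export
run_study <- function(cfg, eta = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  records <- list()
  for (n in cfg$n_grid) {
    for (rep in seq_len(cfg$n_datasets)) {
      seed <- replicate_seed(cfg$master_seed, n, rep)
      ck <- NULL
      if (!is.null(cfg$checkpoint_dir)) {
        ck <- file.path(cfg$checkpoint_dir,
                        sprintf("cell_n%d_rep%d_eta%s.csv", n, rep,
                                if (is.null(eta)) "default" else
                                  format(eta)))
        if (file.exists(ck)) {
          records[[length(records) + 1L]] <-
            utils::read.csv(ck, stringsAsFactors = FALSE)
          next
        }
      }
      dat <- simulate_joint(sim_config(cfg$truth, n, cfg$m_min, cfg$t_max,
                                       seed))
      rec <- fit_replicate(dat, cfg, n, rep, seed, eta = eta)
      if (!is.null(ck)) {
        dir.create(dirname(ck), recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(rec, ck, row.names = FALSE)
      }
      records[[length(records) + 1L]] <- rec
    }
  }
  records <- do.call(rbind, records)
  structure(list(records = records,
                 aggregates = aggregate_records(records),
                 config = cfg, eta = eta),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Simulation study: %d replicates, n in {%s}, methods %s\n",
              x$config$n_datasets,
              paste(x$config$n_grid, collapse = ", "),
              paste(x$config$methods, collapse = "/")))
  print(summarize_table1(x), digits = 3)
  invisible(x)
}

#' Comparison table of survival-submodel estimates
#'
#' Formats a study report into the conventional comparison layout: rows
#' are posterior mean and mean posterior SD of the group coefficient
#' (gamma1) and the association parameter (alpha); columns are
#' method x sample size.  Missing cells are rendered as NA.
#'
#' @param report a [run_study()] report.
#' @param parameters parameters to tabulate.
#' @return data.frame with columns \code{posterior}, \code{parameter},
#'   \code{truth} and one column per method x n cell.
#' @export
summarize_table1 <- function(report, parameters = c("gamma1", "alpha")) {
  agg <- report$aggregates
  truth <- report$config$truth
  truth_of <- function(p) switch(p,
                                 gamma0 = truth$gamma[1],
                                 gamma1 = truth$gamma[2],
                                 alpha = truth$alpha,
                                 beta0 = truth$beta[1],
                                 beta1 = truth$beta[2],
                                 beta2 = truth$beta[3],
                                 sigma = truth$sigma,
                                 NA_real_)
  methods <- intersect(c("JS", "STS", "NTS"), unique(agg$method))
  ns <- sort(unique(agg$n))
  cells <- expand.grid(n = ns, method = methods,
                       stringsAsFactors = FALSE)[, c("method", "n")]
  col_names <- sprintf("%s_n%d", cells$method, cells$n)
  grab <- function(p, col) {
    vapply(seq_len(nrow(cells)), function(k) {
      row <- agg[agg$method == cells$method[k] & agg$n == cells$n[k] &
                   agg$parameter == p, col]
      if (length(row) == 1) row else NA_real_
    }, numeric(1))
  }
  rows <- list()
  for (p in parameters) {
    rows[[length(rows) + 1L]] <-
      c(list(posterior = "Mean", parameter = p, truth = truth_of(p)),
        as.list(grab(p, "mean_of_means")))
  }
  for (p in parameters) {
    rows[[length(rows) + 1L]] <-
      c(list(posterior = "SD", parameter = p, truth = truth_of(p)),
        as.list(grab(p, "mean_post_sd")))
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(stats::setNames(r, c("posterior", "parameter", "truth",
                                       col_names)),
                  stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Bias metrics of a study report
#'
#' @param report a [run_study()] report.
#' @param truth generating parameters (defaults to the report's own).
#' @return data.frame with bias = mean of posterior means - truth, relative
#'   bias, and the Monte-Carlo standard error of the bias (SD of posterior
#'   means / sqrt(converged replicates)).  Relative bias is NA where the
#'   truth is zero.
#' @export
bias_metrics <- function(report, truth = report$config$truth) {
  agg <- report$aggregates
  tv <- c(beta0 = truth$beta[1], beta1 = truth$beta[2],
          beta2 = truth$beta[3], sigma = truth$sigma,
          Sigma11 = truth$Sigma[1, 1], Sigma12 = truth$Sigma[1, 2],
          Sigma22 = truth$Sigma[2, 2],
          gamma0 = truth$gamma[1], gamma1 = truth$gamma[2],
          alpha = truth$alpha)
  out <- agg[agg$parameter %in% names(tv), ]
  out$truth <- tv[out$parameter]
  out$bias <- out$mean_of_means - out$truth
  out$rel_bias <- ifelse(out$truth == 0, NA_real_,
                         out$bias / abs(out$truth))
  out$mc_se <- out$sd_of_means / sqrt(out$n_converged)
  out[, c("method", "n", "parameter", "truth", "mean_of_means", "bias",
          "rel_bias", "mc_se", "mean_post_sd", "n_converged", "n_total")]
}

#' Sensitivity sweep over the Gamma concentration eta
#'
#' Runs the bias-corrected two-stage strategy once per eta value on SHARED
#' simulated datasets: replicate seeds are identical across eta cells, so
#' differences between reports are attributable to eta alone.
#'
#' @param cfg a [study_config()] with a nonempty \code{eta_grid}; methods
#'   must include \code{"NTS"}.
#' @return Named list of [run_study()] reports, one per eta.
#' @export
eta_sensitivity <- function(cfg) {
  if (is.null(cfg$eta_grid) || length(cfg$eta_grid) == 0) {
    stop("`cfg$eta_grid` must be nonempty")
  }
  if (!"NTS" %in% cfg$methods) stop("`methods` must include NTS")
  sub <- cfg
  sub$methods <- intersect(cfg$methods, c("STS", "NTS"))
  out <- lapply(cfg$eta_grid, function(eta) run_study(sub, eta = eta))
  names(out) <- format(cfg$eta_grid)
  out
}

#' Strip plot of posterior means per method and sample size
#'
#' Mirrors the conventional presentation of simulation results: one panel
#' per parameter, posterior means of every replicate jittered by method and
#' sample size, dashed line at the truth.
#'
#' @param report a [run_study()] report.
#' @param parameters parameters to plot.
#' @return Invisibly, the plotted records.
#' @export
plot_study <- function(report, parameters = c("gamma1", "alpha")) {
  rec <- report$records[report$records$parameter %in% parameters, ]
  truth <- report$config$truth
  old <- graphics::par(mfrow = c(1, length(parameters)))
  on.exit(graphics::par(old))
  for (p in parameters) {
    g <- rec[rec$parameter == p, ]
    grp <- factor(sprintf("%s\nn=%d", g$method, g$n))
    graphics::stripchart(g$mean ~ grp, vertical = TRUE, method = "jitter",
                         pch = 1, ylab = "posterior mean", main = p)
    tv <- switch(p, gamma1 = truth$gamma[2], alpha = truth$alpha,
                 gamma0 = truth$gamma[1], NA_real_)
    if (is.finite(tv)) graphics::abline(h = tv, lty = 2)
  }
  invisible(rec)
}
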