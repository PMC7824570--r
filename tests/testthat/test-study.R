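# Fast study-harness settings shared by this file.
fast_cfg <- function(...) {
  study_config(n_grid = 50, n_datasets = 1, methods = "STS",
               master_seed = 17L,
               mcmc_long = mcmc_config(iter = 400, warmup = 200),
               mcmc_surv = mcmc_config(iter = 300, warmup = 150), ...)
}

test_that("a smoke-scale study yields one record per parameter and is deterministic", {
  cfg <- fast_cfg()
  rep1 <- run_study(cfg)
  rec <- rep1$records
  expect_setequal(unique(rec$method), c("stage1", "STS"))
  sts <- rec[rec$method == "STS", ]
  expect_equal(nrow(sts), 3) # gamma0, gamma1, alpha
  expect_equal(unique(sts$replicate), 1)
  rep2 <- run_study(cfg)
  expect_identical(rep1$records, rep2$records)
  expect_identical(rep1$aggregates, rep2$aggregates)
})

test_that("replicate seeds are cell-addressable and datasets regenerable", {
  s1 <- replicate_seed(1L, 200, 3)
  expect_identical(s1, replicate_seed(1L, 200, 3))
  expect_false(s1 == replicate_seed(1L, 200, 4))
  expect_false(s1 == replicate_seed(1L, 500, 3))
  expect_false(s1 == replicate_seed(2L, 200, 3))
  d1 <- simulate_joint(sim_config(prothro_params(), 200, seed = s1))
  d2 <- simulate_joint(sim_config(prothro_params(), 200, seed = s1))
  expect_identical(serialize(d1, NULL), serialize(d2, NULL))
})

test_that("aggregates are recomputable from the per-replicate records", {
  cfg <- fast_cfg()
  cfg$n_datasets <- 3
  report <- run_study(cfg)
  rec <- report$records
  for (k in seq_len(nrow(report$aggregates))) {
    a <- report$aggregates[k, ]
    g <- rec[rec$method == a$method & rec$n == a$n &
               rec$parameter == a$parameter & rec$converged, ]
    expect_equal(a$mean_of_means, mean(g$mean), tolerance = 1e-12)
    expect_equal(a$mean_post_sd, mean(g$sd), tolerance = 1e-12)
    expect_equal(a$n_converged, nrow(g))
  }
})

test_that("bias metrics match hand arithmetic", {
  # hand-built report of three fake replicates
  rec <- data.frame(
    parameter = "alpha", mean = c(-2.1, -2.2, -2.3), sd = c(0.3, 0.2, 0.1),
    q2.5 = NA, q97.5 = NA, rhat = 1, ess = 500,
    method = "STS", n = 1000, replicate = 1:3, seed = 1:3, converged = TRUE
  )
  report <- structure(list(records = rec,
                           aggregates = twostagejm:::aggregate_records(rec),
                           config = list(truth = prothro_params())),
                      class = "study_report")
  bm <- bias_metrics(report, prothro_params())
  expect_equal(bm$mean_of_means, -2.2)
  expect_equal(bm$bias, -2.2 - (-2.447))
  expect_equal(bm$rel_bias, (-2.2 + 2.447) / 2.447)
  expect_equal(bm$mc_se, sd(c(-2.1, -2.2, -2.3)) / sqrt(3))
  expect_equal(bm$mean_post_sd, 0.2)
  # the documented attenuation arithmetic at the large-sample cell
  rec$mean <- rep(-2.204, 3)
  report$records <- rec
  report$aggregates <- twostagejm:::aggregate_records(rec)
  bm <- bias_metrics(report, prothro_params())
  expect_equal(bm$bias, 0.243, tolerance = 1e-12)
  # zero truth yields an undefined relative bias, not infinity
  null_truth <- joint_params(c(0, 0, 0), diag(2) * 0.01, 0.1, c(0, 0), 0)
  bm0 <- bias_metrics(report, null_truth)
  expect_true(is.na(bm0$rel_bias))
  expect_true(is.finite(bm0$bias))
})

test_that("all posterior means at truth give zero bias", {
  rec <- data.frame(
    parameter = rep(c("gamma1", "alpha"), each = 2),
    mean = rep(c(-0.172, -2.447), each = 2), sd = 0.1,
    q2.5 = NA, q97.5 = NA, rhat = 1, ess = 500,
    method = "NTS", n = 200, replicate = c(1, 2, 1, 2), seed = 1,
    converged = TRUE
  )
  report <- structure(list(records = rec,
                           aggregates = twostagejm:::aggregate_records(rec),
                           config = list(truth = prothro_params())),
                      class = "study_report")
  bm <- bias_metrics(report)
  expect_equal(bm$bias, c(0, 0))
})

test_that("the comparison table has the method-by-n layout with truths", {
  cfg <- fast_cfg()
  report <- run_study(cfg)
  tab <- summarize_table1(report)
  expect_equal(names(tab), c("posterior", "parameter", "truth", "STS_n50"))
  expect_equal(tab$posterior, c("Mean", "Mean", "SD", "SD"))
  expect_equal(tab$parameter, c("gamma1", "alpha", "gamma1", "alpha"))
  expect_equal(tab$truth[1:2], c(-0.172, -2.447))
  # values are the aggregates themselves
  agg <- report$aggregates
  expect_equal(tab$STS_n50[2],
               agg$mean_of_means[agg$parameter == "alpha" &
                                   agg$method == "STS"])
  # serialise and re-parse round trip
  tf <- tempfile(fileext = ".csv")
  utils::write.csv(tab, tf, row.names = FALSE)
  tab2 <- utils::read.csv(tf, stringsAsFactors = FALSE)
  expect_equal(tab2$STS_n50, tab$STS_n50, tolerance = 1e-12)
})

test_that("checkpointing resumes without recomputation", {
  ckdir <- file.path(tempdir(), "study_ck")
  unlink(ckdir, recursive = TRUE)
  dir.create(ckdir)
  cfg <- fast_cfg(checkpoint_dir = ckdir)
  rep1 <- run_study(cfg)
  files <- list.files(ckdir)
  expect_length(files, 1)
  rep2 <- run_study(cfg) # loads from checkpoint
  expect_equal(rep2$aggregates, rep1$aggregates, tolerance = 1e-12)
})

test_that("eta sensitivity shares datasets and approaches STS for huge eta", {
  cfg <- study_config(n_grid = 80, n_datasets = 2, methods = c("STS", "NTS"),
                      eta_grid = c(1.5, 1e8), master_seed = 19L,
                      mcmc_long = mcmc_config(iter = 600, warmup = 300),
                      mcmc_surv = mcmc_config(iter = 600, warmup = 300))
  reports <- eta_sensitivity(cfg)
  expect_named(reports, format(c(1.5, 1e8)))
  # shared seeds: stage-1 records identical across eta cells
  s1a <- reports[[1]]$records
  s1b <- reports[[2]]$records
  expect_identical(s1a[s1a$method == "stage1", ],
                   s1b[s1b$method == "stage1", ])
  # and STS (eta-free) results identical too
  expect_identical(s1a[s1a$method == "STS", ], s1b[s1b$method == "STS", ])
  # in the eta -> Inf limit NTS collapses onto STS within MC error
  big <- reports[[2]]$aggregates
  for (p in c("gamma1", "alpha")) {
    nts <- big[big$method == "NTS" & big$parameter == p, ]
    sts <- big[big$method == "STS" & big$parameter == p, ]
    expect_lt(abs(nts$mean_of_means - sts$mean_of_means),
              4 * sts$mean_post_sd / sqrt(100))
  }
  expect_error(eta_sensitivity(fast_cfg()), "eta_grid")
})

test_that("study plots render without error", {
  cfg <- fast_cfg()
  report <- run_study(cfg)
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf)
  expect_silent(plot_study(report, parameters = "alpha"))
  grDevices::dev.off()
  expect_true(file.size(tf) > 0)
})
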