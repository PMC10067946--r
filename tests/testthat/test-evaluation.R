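test_that("metric primitives match hand calculations", {
  expect_equal(percent_bias(c(0.11, 0.09, 0.13), 0.1), 10)
  expect_equal(percent_bias(c(0.08, 0.12), 0.1), 0)
  expect_error(percent_bias(c(1, 2), 0), "type-I")

  im <- interval_metrics(lower = c(0, 0.05, 0.12), upper = c(0.2, 0.15, 0.3),
                         truth = 0.1)
  expect_equal(im$ci_length, mean(c(0.2, 0.1, 0.18)))
  expect_equal(im$coverage, 2 / 3)
  expect_error(interval_metrics(numeric(0), numeric(0), 0.1), "no converged")

  expect_equal(power_type1(c(TRUE, TRUE, FALSE), 0.1),
               list(rate = 2 / 3, label = "power"))
  expect_equal(power_type1(c(FALSE, FALSE), 0)$label, "type1")
})

test_that("replicate seeds are deterministic, distinct and in range", {
  s1 <- fenolong:::replicate_seed(2025, 1, 1, 1)
  expect_identical(s1, fenolong:::replicate_seed(2025, 1, 1, 1))
  grid <- expand.grid(sc = 1:4, ei = 1:3, r = 1:20)
  seeds <- mapply(fenolong:::replicate_seed, 2025, grid$sc, grid$ei, grid$r)
  expect_equal(length(unique(seeds)), nrow(grid))
  expect_true(all(seeds >= 0 & seeds < 2^31))
  expect_true(is.integer(seeds))
})

test_that("aggregate_metrics is a pure function of the results table", {
  res <- data.frame(
    scenario = 2, effect_size = 0.1, replicate = rep(1:4, each = 3),
    method = "L_TS_NLS",
    target = rep(c("beta_ca", "beta_logcaw", "beta_logdaw"), 4),
    estimate = c(0.09, 0.01, -0.02, 0.11, -0.01, 0.01,
                 0.10, 0.02, 0.00, 0.12, 0.00, -0.01),
    lower = c(0.05, -0.04, -0.07, 0.06, -0.06, -0.04,
              0.04, -0.03, -0.05, 0.02, -0.05, -0.06),
    upper = c(0.13, 0.06, 0.03, 0.16, 0.04, 0.06,
              0.16, 0.07, 0.05, 0.22, 0.05, 0.04),
    significant = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE,
                    TRUE, FALSE, FALSE, TRUE, FALSE, TRUE),
    converged = TRUE, seed = 1)
  m <- aggregate_metrics(res)
  expect_equal(nrow(m), 3)
  ca <- m[m$coefficient == "beta_ca", ]
  # scenario 2 at effect 0.1: truth is (0.1, 0, 0)
  expect_equal(ca$truth, 0.1)
  expect_equal(ca$pct_bias, 100 * (mean(c(0.09, 0.11, 0.10, 0.12)) - 0.1) / 0.1)
  expect_equal(ca$power, 1)
  expect_true(is.na(ca$type1))
  lcaw <- m[m$coefficient == "beta_logcaw", ]
  expect_equal(lcaw$truth, 0)
  expect_equal(lcaw$type1, 0)
  expect_equal(lcaw$coverage, 1)
  ldaw <- m[m$coefficient == "beta_logdaw", ]
  expect_equal(ldaw$type1, 0.25)
  # purity: same input, same output
  expect_identical(m, aggregate_metrics(res))
  # non-converged replicates are excluded from metrics but counted
  res2 <- res; res2$converged[res2$replicate == 1] <- FALSE
  m2 <- aggregate_metrics(res2)
  expect_equal(unique(m2$n_converged), 3L)
  expect_equal(unique(m2$n_total), 4L)
})

test_that("run_simulation_study produces the full grid and honours checkpoints", {
  ckdir <- file.path(tempdir(), "feno_ck")
  unlink(ckdir, recursive = TRUE)
  st <- run_simulation_study(scenarios = 2, effect_sizes = 0.1,
                             n_replicates = 2, methods = "L_TS_HMA",
                             n_participants = 25, n_visits = 2,
                             seed = 99, checkpoint_dir = ckdir)
  expect_s3_class(st, "feno_study")
  expect_equal(nrow(st$results), 2 * 3)
  expect_equal(nrow(st$metrics), 3)
  expect_equal(length(list.files(ckdir, pattern = "^rep_")), 2)
  # a second run must reuse the checkpoints and reproduce the results
  st2 <- run_simulation_study(scenarios = 2, effect_sizes = 0.1,
                              n_replicates = 2, methods = "L_TS_HMA",
                              n_participants = 25, n_visits = 2,
                              seed = 99, checkpoint_dir = ckdir)
  expect_equal(st2$results$estimate, st$results$estimate, tolerance = 1e-9)
  unlink(ckdir, recursive = TRUE)
})

test_that("per-replicate datasets are reproducible from their recorded seed", {
  st <- run_simulation_study(scenarios = 4, effect_sizes = 0.1,
                             n_replicates = 1, methods = "L_TS_HMA",
                             n_participants = 20, n_visits = 2, seed = 7)
  rs <- unique(st$results$seed)
  pop <- default_population_params(beta1 = scenario_beta(4, 0.1))
  d <- simulate_feno_dataset(pop, 20, 2, seed = rs)
  redo <- coef_estimates(fit_stage2_lmm(session_table(d, "hma"),
                                        method_label = "L_TS_HMA"))
  got <- st$results[st$results$target == "beta_logdaw", ]
  expect_equal(got$estimate, redo$estimate[redo$target == "beta_logdaw"],
               tolerance = 1e-9)
})

test_that("method failures are recorded as data, not errors", {
  res <- data.frame(scenario = 1, effect_size = 0.1, replicate = 1:2,
                    method = "L_U_NLME",
                    target = "beta_ca", estimate = c(NA, 0.1),
                    lower = c(NA, 0.05), upper = c(NA, 0.15),
                    significant = c(NA, TRUE), converged = c(FALSE, TRUE),
                    seed = 1)
  m <- aggregate_metrics(res)
  expect_equal(m$n_converged, 1L)
  expect_equal(m$n_total, 2L)
  expect_equal(m$power, 1)
})
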