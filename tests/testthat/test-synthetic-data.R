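test_that("population_params builds the participant covariance correctly", {
  pop <- population_params(beta0 = c(1.5, 3.5, 2.5), tau = c(0.45, 0.65, 0.55),
                           rho = c(0.66, -0.38, -0.35),
                           sigma_visit = c(0.5, 0.4, 0.33), sigma_eps = 0.1)
  expect_equal(pop$sigma_tau[1, 2], 0.66 * 0.45 * 0.65)
  expect_equal(pop$sigma_tau[1, 3], -0.38 * 0.45 * 0.55)
  expect_equal(diag(pop$sigma_tau), c(ca = 0.45, logcaw = 0.65,
                                      logdaw = 0.55)^2)
  expect_error(population_params(c(1, 1, 1), tau = c(1, 1, 1),
                                 rho = c(0.99, -0.99, 0.99),
                                 sigma_visit = c(1, 1, 1), sigma_eps = 1),
               "positive-definite")
  expect_error(population_params(c(1, 1, 1), tau = c(-1, 1, 1),
                                 rho = c(0, 0, 0),
                                 sigma_visit = c(1, 1, 1), sigma_eps = 1),
               "positive")
})

test_that("scenario_beta reproduces the four zero patterns", {
  expect_equal(unname(scenario_beta(1, 0.1)), c(0.1, 0.1, 0.1))
  expect_equal(unname(scenario_beta(2, 0.05)), c(0.05, 0, 0))
  expect_equal(unname(scenario_beta(3, 0.05)), c(0, 0.05, 0))
  expect_equal(unname(scenario_beta(4, 0.01)), c(0, 0, 0.01))
  expect_error(scenario_beta(5, 0.1), "scenario")
})

test_that("flow schedules have the documented composition", {
  expect_length(flow_schedule("standard"), 8)
  expect_equal(as.vector(table(flow_schedule("standard"))), c(2, 2, 2, 2))
  expect_length(flow_schedule("chs"), 9)
  expect_equal(sum(flow_schedule("chs") == 50), 3)
  expect_equal(sum(flow_schedule("chs") == 300), 2)
})

test_that("the generator is seed-deterministic with the right cardinality", {
  pop <- default_population_params()
  d1 <- simulate_feno_dataset(pop, 50, 3, seed = 7)
  d2 <- simulate_feno_dataset(pop, 50, 3, seed = 7)
  d3 <- simulate_feno_dataset(pop, 50, 3, seed = 8)
  expect_identical(d1$feno_ppb, d2$feno_ppb)
  expect_false(identical(d1$feno_ppb, d3$feno_ppb))
  # 50 participants x 3 visits x 8 maneuvers
  expect_equal(nrow(d1), 50 * 3 * 8)
  expect_equal(nrow(attr(d1, "truth")), 50 * 3)
  expect_setequal(unique(d1$flow_mls), c(30, 50, 100, 300))
  # covariate constant within a session, varying across sessions
  per_sess <- tapply(d1$x, paste(d1$participant_id, d1$visit_id),
                     function(v) length(unique(v)))
  expect_true(all(per_sess == 1))
  expect_gt(length(unique(d1$x)), 100)
})

test_that("log-FeNO residuals around the true session means match sigma_eps", {
  pop <- default_population_params(sigma_eps = 0.1)
  d <- simulate_feno_dataset(pop, 150, 3, seed = 11)
  tr <- attr(d, "truth")
  key <- match(paste(d$participant_id, d$visit_id),
               paste(tr$participant_id, tr$visit_id))
  mu <- log(exp(tr$true_logcaw[key]) +
              (tr$true_ca[key] - exp(tr$true_logcaw[key])) *
              exp(-exp(tr$true_logdaw[key]) / d$flow_mls))
  res <- log(d$feno_ppb) - mu
  expect_equal(mean(res), 0, tolerance = 0.005)
  expect_equal(sd(res), 0.1, tolerance = 0.05)
})

test_that("simulated moments recover the population values", {
  pop <- default_population_params(beta1 = scenario_beta(1, 0.1))
  d <- simulate_feno_dataset(pop, 800, 3, seed = 13)
  tr <- attr(d, "truth")
  x <- d$x[match(paste(tr$participant_id, tr$visit_id),
                 paste(d$participant_id, d$visit_id))]
  # composite session variance of each component is tau^2 + sigma_visit^2
  # (truncation trims the C_A component slightly, so tolerances are loose)
  th <- cbind(tr$true_ca, tr$true_logcaw, tr$true_logdaw)
  resid <- th - cbind(1.5, 3.5, 2.5)[rep(1, nrow(th)), ] - outer(x, rep(0.1, 3))
  expect_equal(apply(resid, 2, sd),
               sqrt(c(0.45, 0.65, 0.55)^2 + c(0.5, 0.4, 0.33)^2),
               tolerance = 0.05)
  # covariate slope recovered by per-component OLS on the true parameters
  slopes <- apply(th, 2, function(y) coef(lm(y ~ x))[2])
  expect_equal(unname(slopes), c(0.1, 0.1, 0.1), tolerance = 0.4)
})

test_that("C_A truncation holds and the rejection rate matches the oracle", {
  pop <- default_population_params()
  d <- simulate_feno_dataset(pop, 2000, 3, seed = 17)
  tr <- attr(d, "truth")
  expect_true(all(tr$true_ca >= 0))
  expect_true(all(d$feno_ppb > 0))
  rej <- attr(d, "rejection")
  # marginal P(C_A < 0) per visit is pnorm(-1.5 / sqrt(0.45^2 + 0.5^2));
  # per-participant rejection probability over 3 correlated visits lies
  # between the one-visit value and three times it
  p1 <- pnorm(-1.5 / sqrt(0.45^2 + 0.5^2))
  rate <- rej[["rejections"]] / rej[["attempts"]]
  expect_gt(rate, p1 * 0.5)
  expect_lt(rate, 3.5 * p1)
})

test_that("datasets round-trip through CSV with their truth companion", {
  pop <- default_population_params(beta1 = scenario_beta(2, 0.05))
  d <- simulate_feno_dataset(pop, 8, 2, seed = 3)
  path <- file.path(tempdir(), "feno_roundtrip.csv")
  write_feno_dataset(d, path)
  expect_true(file.exists(file.path(tempdir(), "feno_roundtrip_truth.csv")))
  d2 <- read_feno_dataset(path)
  expect_s3_class(d2, "feno_dataset")
  expect_equal(d2$feno_ppb, d$feno_ppb, tolerance = 1e-9)
  expect_equal(d2$x, d$x, tolerance = 1e-9)
  expect_equal(attr(d2, "truth")$true_ca, attr(d, "truth")$true_ca,
               tolerance = 1e-9)
  unlink(c(path, file.path(tempdir(), "feno_roundtrip_truth.csv")))
})
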