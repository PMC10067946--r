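test_that("mcmc_config and prior_spec validate their inputs", {
  expect_error(mcmc_config(n_chains = 0), "n_chains")
  expect_error(mcmc_config(n_iter = -5), "n_iter")
  pr <- prior_spec()
  expect_equal(pr$iw_df, 4)
  expect_equal(dim(pr$iw_scale), c(3, 3))
  expect_equal(pr$prior_var_beta, 1e3)
})

test_that("the unified fit is seed-deterministic and structurally sound", {
  pop <- default_population_params(beta1 = scenario_beta(1, 0.1))
  d <- simulate_feno_dataset(pop, 12, 2, seed = 31)
  f1 <- fit_l_u_hb(d, mcmc = test_mcmc(seed = 5, n_warmup = 200, n_iter = 300))
  f2 <- fit_l_u_hb(d, mcmc = test_mcmc(seed = 5, n_warmup = 200, n_iter = 300))
  expect_identical(f1$summary$mean, f2$summary$mean)
  expect_s3_class(f1, "feno_hb_fit")
  expect_setequal(names(f1$summary),
                  c("parameter", "mean", "sd", "q2.5", "q97.5", "rhat", "ess"))
  expect_equal(f1$n_participants, 12)
  expect_equal(f1$n_sessions, 24)
  expect_equal(nrow(f1$theta_mean), 24)
  # a different seed must change the draws
  f3 <- fit_l_u_hb(d, mcmc = test_mcmc(seed = 6, n_warmup = 200, n_iter = 300))
  expect_false(identical(f1$summary$mean, f3$summary$mean))
})

test_that("the truncation keeps every sampled alveolar concentration >= 0", {
  pop <- default_population_params()
  d <- simulate_feno_dataset(pop, 20, 2, seed = 33)
  fit <- fit_l_u_hb(d, mcmc = test_mcmc(seed = 2))
  expect_gte(fit$theta_ca_min, 0)
  expect_true(all(fit$theta_mean$ca >= 0))
})

test_that("posterior means recover a moderate dataset's coefficients", {
  pop <- default_population_params(beta1 = scenario_beta(1, 0.1))
  d <- simulate_feno_dataset(pop, 60, 3, seed = 35)
  fit <- fit_l_u_hb(d, mcmc = test_mcmc(seed = 3, n_warmup = 800,
                                        n_iter = 1200))
  s <- fit$summary
  b0 <- s$mean[match(c("beta0_ca", "beta0_logcaw", "beta0_logdaw"),
                     s$parameter)]
  expect_equal(b0, c(1.5, 3.5, 2.5), tolerance = 0.15)
  expect_lt(abs(s$mean[s$parameter == "sigma_eps"] - 0.1), 0.01)
  co <- coef_estimates(fit)
  expect_equal(co$target, c("beta_ca", "beta_logcaw", "beta_logdaw"))
  expect_true(all(co$upper > co$lower))
  expect_true(all(abs(co$estimate - 0.1) < 3.5 * co$se))
})

test_that("Bayesian session estimates shrink towards the population", {
  pop <- default_population_params()
  d <- simulate_feno_dataset(pop, 25, 2, seed = 37)
  hb <- fit_l_ts_hb_stage1(d, mcmc = test_mcmc(seed = 4))
  nls <- session_table(d, "nls")
  expect_s3_class(hb, "session_estimates")
  expect_equal(nrow(hb), 50)
  expect_true(all(is.finite(hb$x)))
  ok <- nls$converged
  # partial pooling: posterior means are less dispersed than the raw
  # per-session estimates for the weakly identified airway parameters
  expect_lt(sd(hb$logdaw[ok]), sd(nls$logdaw[ok]))
  expect_lt(sd(hb$logcaw[ok]), sd(nls$logcaw[ok]))
  # no covariate-effect rows in a covariate-free fit
  expect_false(any(grepl("beta1", attr(hb, "fit")$summary$parameter)))
})

test_that("split_rhat and ess_basic behave on known inputs", {
  set.seed(1)
  iid <- list(rnorm(2000), rnorm(2000))
  expect_lt(split_rhat(iid), 1.02)
  expect_gt(ess_basic(iid), 2000)
  # chains at different levels must be flagged
  apart <- list(rnorm(2000), rnorm(2000) + 5)
  expect_gt(split_rhat(apart), 2)
  # a strong trend within one chain is caught by splitting
  trend <- list(seq(0, 1, length.out = 2000) + rnorm(2000, sd = 0.1))
  expect_gt(split_rhat(trend), 1.5)
  expect_true(is.na(split_rhat(list(c(1)))))
})

test_that("the Gibbs sampler agrees with an independent JAGS fit", {
  # Cross-check oracle: the same three-level model coded independently in
  # JAGS, run on one small dataset; population-level posteriors must agree
  # within combined Monte-Carlo uncertainty.
  library(rjags)
  pop <- default_population_params(beta1 = scenario_beta(1, 0.1))
  d <- simulate_feno_dataset(pop, 25, 2, seed = 41)
  fit <- fit_l_u_hb(d, mcmc = mcmc_config(n_chains = 1, n_warmup = 1000,
                                          n_iter = 2000, seed = 9))

  key <- paste(d$participant_id, d$visit_id)
  skey <- unique(key)
  sess <- match(key, skey)
  first <- match(skey, key)
  part <- d$participant_id[first]
  jd <- list(y = log(d$feno_ppb), flow = d$flow_mls, sess = sess,
             part = part, x = d$x[first], S = length(skey),
             N = nrow(d), P = max(part), Dm = diag(0.001, 3))
  model <- "
  model {
    for (k in 1:N) {
      mu[k] <- log(exp(theta[sess[k],2]) +
                   (theta[sess[k],1] - exp(theta[sess[k],2])) *
                   exp(-exp(theta[sess[k],3]) / flow[k]))
      y[k] ~ dnorm(mu[k], prec_eps)
    }
    for (s in 1:S) {
      m[s,1] <- beta0[1] + beta1[1] * x[s] + alpha[part[s],1]
      m[s,2] <- beta0[2] + beta1[2] * x[s] + alpha[part[s],2]
      m[s,3] <- beta0[3] + beta1[3] * x[s] + alpha[part[s],3]
      theta[s,1] ~ dnorm(m[s,1], prec_v[1]) T(0,)
      theta[s,2] ~ dnorm(m[s,2], prec_v[2])
      theta[s,3] ~ dnorm(m[s,3], prec_v[3])
    }
    for (i in 1:P) { alpha[i,1:3] ~ dmnorm(zero3, Tprec) }
    zero3[1] <- 0; zero3[2] <- 0; zero3[3] <- 0
    Tprec ~ dwish(Dm, 4)
    for (c in 1:3) {
      beta0[c] ~ dnorm(0, 0.001)
      beta1[c] ~ dnorm(0, 0.001)
      prec_v[c] ~ dgamma(0.001, 0.001)
    }
    prec_eps ~ dgamma(0.001, 0.001)
  }"
  set.seed(1)
  jm <- suppressWarnings(
    jags.model(textConnection(model), data = jd, n.chains = 1,
               n.adapt = 1500, quiet = TRUE,
               inits = list(.RNG.name = "base::Mersenne-Twister",
                            .RNG.seed = 99)))
  update(jm, 800, progress.bar = "none")
  js <- coda.samples(jm, c("beta0", "beta1", "prec_eps"), n.iter = 2500,
                     progress.bar = "none")[[1]]
  jmean <- colMeans(js)
  jsd <- apply(js, 2, sd)

  s <- fit$summary
  for (j in 1:3) {
    par0 <- c("beta0_ca", "beta0_logcaw", "beta0_logdaw")[j]
    tol0 <- 3 * sqrt(s$sd[s$parameter == par0]^2 + jsd[[paste0("beta0[", j, "]")]]^2)
    expect_lt(abs(s$mean[s$parameter == par0] - jmean[[paste0("beta0[", j, "]")]]),
              tol0 + 0.05)
    par1 <- c("beta1_ca", "beta1_logcaw", "beta1_logdaw")[j]
    tol1 <- 3 * sqrt(s$sd[s$parameter == par1]^2 + jsd[[paste0("beta1[", j, "]")]]^2)
    expect_lt(abs(s$mean[s$parameter == par1] - jmean[[paste0("beta1[", j, "]")]]),
              tol1 + 0.05)
  }
  expect_equal(s$mean[s$parameter == "sigma_eps"],
               1 / sqrt(jmean[["prec_eps"]]), tolerance = 0.05)
})

test_that("fit_l_u_hb requires a covariate column", {
  pop <- default_population_params()
  d <- simulate_feno_dataset(pop, 5, 2, seed = 43)
  d$x <- NULL
  expect_error(fit_l_u_hb(d, mcmc = test_mcmc()), "covariate")
})
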