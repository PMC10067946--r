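## Simulation-study harness: run estimation methods over replicated synthetic
## datasets and compute percent bias, interval length/coverage, power and
## type-I error per method and per NO-parameter association.

#' Percent bias of a set of estimates
#'
#' `100 * (mean(estimates) - truth) / truth`. Defined only for nonzero truth;
#' for a zero true coefficient the relevant metric is the type-I error rate.
#'
#' @param estimates Numeric vector of point estimates across replicates.
#' @param truth Nonzero true value.
#' @return Percent bias (scalar).
#' @export
percent_bias <- function(estimates, truth) {
  if (!is.finite(truth) || truth == 0)
    stop("percent bias is undefined for truth == 0 (use the type-I error rate)")
  100 * (mean(estimates) - truth) / truth
}

#' Interval length and coverage across replicates
#'
#' @param lower,upper Numeric vectors of 95% interval endpoints, one entry per
#'   converged replicate.
#' @param truth True coefficient value.
#' @return List with `ci_length` (mean of `upper - lower`) and `coverage`
#'   (fraction of intervals containing `truth`).
#' @export
interval_metrics <- function(lower, upper, truth) {
  if (length(lower) == 0) stop("no converged replicates")
  stopifnot(length(lower) == length(upper))
  list(ci_length = mean(upper - lower),
       coverage = mean(lower <= truth & truth <= upper))
}

#' Rejection rate, labelled as power or type-I error
#'
#' The fraction of converged replicates whose 95% interval excludes 0 — the
#' uniform rejection rule across all methods (nominal alpha 0.05). Labelled
#' `"power"` when the true coefficient is nonzero and `"type1"` when it is
#' zero.
#'
#' @param significant Logical vector of per-replicate significance calls.
#' @param truth True coefficient value.
#' @return List with `rate` and `label`.
#' @export
power_type1 <- function(significant, truth) {
  list(rate = mean(significant),
       label = if (truth != 0) "power" else "type1")
}

.study_methods <- c("L_U_HB", "L_TS_HB", "L_TS_NLS", "L_TS_HMA",
                    "L_TS_NLME", "L_U_NLME")

## fit one method to one dataset; returns coefficient rows or NULL on failure.
## `converged` uniformly means "the method produced estimates". For the MCMC
## methods the per-fit R-hat flag is a mixing diagnostic, not a completion
## flag; excluding completed fits on a noisy diagnostic would select
## replicates by their estimates and bias the aggregated metrics.
.fit_method <- function(method, dataset, mcmc) {
  switch(method,
    L_U_HB = {
      fit <- fit_l_u_hb(dataset, mcmc = mcmc)
      co <- coef_estimates(fit)
      attr(co, "converged") <- TRUE
      co
    },
    L_TS_HB = {
      s1 <- fit_l_ts_hb_stage1(dataset, mcmc = mcmc)
      co <- coef_estimates(fit_stage2_lmm(s1, method_label = "L_TS_HB"))
      attr(co, "converged") <- TRUE
      co
    },
    L_TS_NLS = {
      s1 <- session_table(dataset, "nls")
      co <- coef_estimates(fit_stage2_lmm(s1, method_label = "L_TS_NLS"))
      attr(co, "converged") <- TRUE
      co
    },
    L_TS_HMA = {
      s1 <- session_table(dataset, "hma")
      co <- coef_estimates(fit_stage2_lmm(s1, method_label = "L_TS_HMA"))
      attr(co, "converged") <- TRUE
      co
    },
    L_TS_NLME = {
      s1 <- fit_l_ts_nlme_stage1(dataset)
      if (!isTRUE(attr(s1, "converged"))) return(NULL)
      co <- coef_estimates(fit_stage2_lmm(s1, method_label = "L_TS_NLME"))
      attr(co, "converged") <- TRUE
      co
    },
    L_U_NLME = {
      fit <- fit_l_u_nlme(dataset)
      if (!fit$converged) return(NULL)
      co <- fit$coefficients
      attr(co, "converged") <- TRUE
      co
    },
    stop("unknown method: ", method))
}

## deterministic per-replicate seed derived from the master seed
replicate_seed <- function(master_seed, scenario, effect_index, replicate) {
  as.integer((as.numeric(master_seed) * 2017 + scenario * 101323 +
                effect_index * 7919 + replicate * 131) %% 2147483629)
}

#' Run a simulation study over scenarios, effect sizes and replicates
#'
#' For each (scenario, effect size, replicate) a longitudinal dataset is
#' simulated under the reference population values (see
#' [default_population_params()]) with the scenario's covariate-effect
#' pattern, each requested method is fitted, and the per-replicate coefficient
#' estimates are collected. Method failures (non-convergence) are recorded and
#' excluded from metric aggregation, never aborting the grid. Per-replicate
#' seeds are derived deterministically from `seed`, so any single replicate is
#' re-runnable in isolation, and completed replicates can be checkpointed to
#' CSV and skipped on re-runs.
#'
#' @param scenarios Integer subset of 1:4.
#' @param effect_sizes Numeric effect sizes (e.g. `c(0.01, 0.05, 0.1)`).
#' @param n_replicates Replicates per (scenario, effect size) cell.
#' @param methods Subset of `c("L_U_HB", "L_TS_HB", "L_TS_NLS", "L_TS_HMA",
#'   "L_TS_NLME", "L_U_NLME")`.
#' @param n_participants,n_visits,flows Study dimensions per dataset.
#' @param sigma_eps Residual SD of log FeNO in the generator.
#' @param mcmc [mcmc_config()] used by the Bayesian methods (its seed is
#'   overridden per replicate).
#' @param seed Master seed.
#' @param checkpoint_dir Optional directory for per-replicate result CSVs;
#'   existing checkpoints are reused.
#' @param verbose Print one progress line per replicate to stderr.
#' @return List of class `feno_study`: `results` (per-replicate coefficient
#'   table) and `metrics` (see [aggregate_metrics()]).
#' @export
run_simulation_study <- function(scenarios = 1, effect_sizes = 0.1,
                                 n_replicates = 5,
                                 methods = c("L_U_HB", "L_TS_HB"),
                                 n_participants = 100, n_visits = 3,
                                 flows = flow_schedule("standard"),
                                 sigma_eps = 0.10,
                                 mcmc = mcmc_config(),
                                 seed = 1, checkpoint_dir = NULL,
                                 verbose = FALSE) {
  methods <- match.arg(methods, .study_methods, several.ok = TRUE)
  stopifnot(all(scenarios %in% 1:4))
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir))
    dir.create(checkpoint_dir, recursive = TRUE)
  all_rows <- list()
  for (sc in scenarios) for (ei in seq_along(effect_sizes)) {
    eff <- effect_sizes[ei]
    for (r in seq_len(n_replicates)) {
      ck <- if (!is.null(checkpoint_dir))
        file.path(checkpoint_dir,
                  sprintf("rep_s%d_e%g_r%03d.csv", sc, eff, r)) else NULL
      if (!is.null(ck) && file.exists(ck)) {
        all_rows[[length(all_rows) + 1]] <- utils::read.csv(ck)
        next
      }
      rs <- replicate_seed(seed, sc, ei, r)
      pop <- default_population_params(beta1 = scenario_beta(sc, eff),
                                       sigma_eps = sigma_eps)
      dataset <- simulate_feno_dataset(pop, n_participants, n_visits,
                                       flows, seed = rs)
      rep_rows <- list()
      for (m in methods) {
        mc <- mcmc
        mc$seed <- rs + match(m, .study_methods)
        t0 <- proc.time()[["elapsed"]]
        co <- tryCatch(.fit_method(m, dataset, mc), error = function(e) NULL)
        el <- proc.time()[["elapsed"]] - t0
        if (verbose)
          message(sprintf("scenario %d beta %g rep %d %s: %s (%.1fs)",
                          sc, eff, r, m,
                          if (is.null(co)) "failed" else "ok", el))
        if (is.null(co)) {
          rep_rows[[m]] <- data.frame(scenario = sc, effect_size = eff,
                                      replicate = r, method = m,
                                      target = paste0("beta_", c("ca", "logcaw", "logdaw")),
                                      estimate = NA_real_, lower = NA_real_,
                                      upper = NA_real_, significant = NA,
                                      converged = FALSE, seed = rs)
        } else {
          rep_rows[[m]] <- data.frame(scenario = sc, effect_size = eff,
                                      replicate = r, method = m,
                                      target = co$target,
                                      estimate = co$estimate,
                                      lower = co$lower, upper = co$upper,
                                      significant = co$significant,
                                      converged = isTRUE(attr(co, "converged")),
                                      seed = rs)
        }
      }
      rows <- do.call(rbind, rep_rows)
      rownames(rows) <- NULL
      if (!is.null(ck)) utils::write.csv(rows, ck, row.names = FALSE)
      all_rows[[length(all_rows) + 1]] <- rows
    }
  }
  results <- do.call(rbind, all_rows)
  rownames(results) <- NULL
  structure(list(results = results, metrics = aggregate_metrics(results)),
            class = "feno_study")
}

#' Aggregate per-replicate results into the performance-metrics table
#'
#' A pure function of the replicate-results table: for each (method, scenario,
#' effect size, coefficient) cell it computes, over converged replicates,
#' percent and absolute bias (percent bias only for nonzero truth), mean 95%
#' interval length, 95% coverage of the truth, and the rejection rate labelled
#' power (nonzero truth) or type-I error (zero truth).
#'
#' @param results The `results` data frame of [run_simulation_study()].
#' @return Data frame with columns `method`, `coefficient`, `scenario`,
#'   `effect_size`, `truth`, `pct_bias`, `abs_bias`, `ci_length`, `coverage`,
#'   `power`, `type1`, `n_converged`, `n_total`.
#' @export
aggregate_metrics <- function(results) {
  comp <- c(beta_ca = 1, beta_logcaw = 2, beta_logdaw = 3)
  cells <- unique(results[c("method", "scenario", "effect_size", "target")])
  rows <- lapply(seq_len(nrow(cells)), function(j) {
    cc <- cells[j, ]
    sub <- results[results$method == cc$method &
                     results$scenario == cc$scenario &
                     results$effect_size == cc$effect_size &
                     results$target == cc$target, ]
    truth <- scenario_beta(cc$scenario, cc$effect_size)[[comp[[cc$target]]]]
    ok <- sub[sub$converged & is.finite(sub$estimate), ]
    n_ok <- nrow(ok)
    if (n_ok == 0)
      return(data.frame(method = cc$method, coefficient = cc$target,
                        scenario = cc$scenario, effect_size = cc$effect_size,
                        truth = truth, pct_bias = NA_real_,
                        abs_bias = NA_real_, ci_length = NA_real_,
                        coverage = NA_real_, power = NA_real_,
                        type1 = NA_real_, n_converged = 0L,
                        n_total = nrow(sub)))
    im <- interval_metrics(ok$lower, ok$upper, truth)
    pt <- power_type1(ok$significant, truth)
    data.frame(method = cc$method, coefficient = cc$target,
               scenario = cc$scenario, effect_size = cc$effect_size,
               truth = truth,
               pct_bias = if (truth != 0) percent_bias(ok$estimate, truth)
                          else NA_real_,
               abs_bias = mean(ok$estimate) - truth,
               ci_length = im$ci_length, coverage = im$coverage,
               power = if (pt$label == "power") pt$rate else NA_real_,
               type1 = if (pt$label == "type1") pt$rate else NA_real_,
               n_converged = n_ok, n_total = nrow(sub))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$method, out$scenario, out$effect_size, out$coefficient), ]
  rownames(out) <- NULL
  out
}

#' @export
print.feno_study <- function(x, ...) {
  cat(sprintf("Simulation study: %d replicate fits, %d metric cells\n",
              nrow(unique(x$results[c("scenario", "effect_size", "replicate",
                                      "method")])),
              nrow(x$metrics)))
  print(x$metrics, digits = 3)
  invisible(x)
}
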