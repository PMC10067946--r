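## Frequentist estimators: the Stage-II linear mixed model shared by all
## two-stage pipelines, and the nonlinear mixed-effects fits (Stage-I NLME and
## the unified NLME with covariate), built on the nlme package.

.coef_row <- function(target, estimate, se, method, n_used,
                      lower = estimate - 1.96 * se,
                      upper = estimate + 1.96 * se) {
  data.frame(target = target, estimate = estimate, se = se,
             lower = lower, upper = upper,
             significant = (lower > 0) | (upper < 0),
             method = method, n_used = n_used)
}

#' Extract covariate-effect estimates in a common format
#'
#' Returns, for any fitted unified or two-stage model object in this package,
#' one row per NO parameter association (`beta_ca`, `beta_logcaw`,
#' `beta_logdaw`) with point estimate, standard error (posterior SD for
#' Bayesian fits), 95% interval (credible interval for Bayesian fits),
#' significance call (interval excludes 0) and method label, so that methods
#' can be compared side by side.
#'
#' @param object A `feno_hb_fit`, `feno_nlme_fit` or `stage2_fit`.
#' @param ... Unused.
#' @return Data frame with columns `target`, `estimate`, `se`, `lower`,
#'   `upper`, `significant`, `method`, `n_used`.
#' @export
coef_estimates <- function(object, ...) UseMethod("coef_estimates")

#' @rdname coef_estimates
#' @export
coef_estimates.feno_hb_fit <- function(object, ...) {
  if (!object$has_covariate)
    stop("fit has no covariate term; nothing to extract")
  s <- object$summary
  rows <- lapply(c(ca = "beta1_ca", logcaw = "beta1_logcaw",
                   logdaw = "beta1_logdaw"), function(p) {
    r <- s[s$parameter == p, ]
    .coef_row(sub("beta1_", "beta_", p), r$mean, r$sd, "L_U_HB",
              object$n_sessions, lower = r$q2.5, upper = r$q97.5)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stage-II linear mixed models on per-session NO-parameter estimates
#'
#' The second stage shared by every two-stage pipeline: per NO parameter, the
#' converged Stage-I estimates are regressed on the covariate with a
#' participant-level random intercept (fitted by REML via [lme4::lmer()]);
#' Wald 95% confidence intervals (estimate +/- 1.96 SE, normal approximation)
#' are returned for the covariate slope. Non-converged Stage-I sessions are
#' excluded; `n_used` records how many sessions remained. A singular
#' random-intercept variance falls back to its boundary (ordinary least
#' squares) with a warning.
#'
#' @param estimates A `session_estimates` data frame (from [session_table()],
#'   [fit_l_ts_hb_stage1()] or [fit_l_ts_nlme_stage1()]), containing a
#'   covariate column `x` or supplemented via `covariate`.
#' @param covariate Optional data frame `participant_id`, `visit_id`, `x`
#'   merged onto `estimates` when the latter lacks `x`.
#' @param method_label Label recorded in the output (e.g. `"L_TS_NLS"`).
#' @return A `stage2_fit`: list with element `coefficients` (see
#'   [coef_estimates()]) and per-parameter lmer fits.
#' @export
fit_stage2_lmm <- function(estimates, covariate = NULL,
                           method_label = paste0("L_TS_", estimates$method[1])) {
  e <- as.data.frame(estimates)
  if (!is.null(covariate))
    e <- merge(e[setdiff(names(e), "x")], covariate,
               by = c("participant_id", "visit_id"))
  if (is.null(e$x) || all(!is.finite(e$x)))
    stop("no covariate values available for Stage II")
  e <- e[e$converged & is.finite(e$ca) & is.finite(e$logcaw) &
           is.finite(e$logdaw) & is.finite(e$x), ]
  if (length(unique(e$participant_id)) < 2)
    stop("fewer than 2 participants with converged Stage-I estimates")
  pars <- c(ca = "ca", logcaw = "logcaw", logdaw = "logdaw")
  fits <- list()
  rows <- lapply(names(pars), function(p) {
    e$y <- e[[pars[[p]]]]
    fit <- tryCatch(
      suppressMessages(lme4::lmer(y ~ x + (1 | participant_id), data = e,
                                  REML = TRUE)),
      error = function(err) NULL)
    if (is.null(fit)) {
      warning("random-intercept fit failed for ", p,
              "; falling back to its variance-zero boundary (OLS)")
      fit <- stats::lm(y ~ x, data = e)
      co <- summary(fit)$coefficients
    } else {
      co <- summary(fit)$coefficients
    }
    fits[[p]] <<- fit
    .coef_row(paste0("beta_", p), co["x", "Estimate"], co["x", "Std. Error"],
              method_label, nrow(e))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(list(coefficients = out, fits = fits, n_used = nrow(e),
                 method = method_label),
            class = "stage2_fit")
}

#' @rdname coef_estimates
#' @export
coef_estimates.stage2_fit <- function(object, ...) object$coefficients

.nlme_model_data <- function(dataset) {
  d <- as.data.frame(dataset)
  d$lfeno <- log(d$feno_ppb)
  d$flow <- d$flow_mls
  d$participant_id <- factor(d$participant_id)
  d$visit_id <- factor(d$visit_id)
  d
}

.nlme_start <- function(dataset) {
  fit <- fit_nls_session(dataset$flow_mls, dataset$feno_ppb,
                         sanity_bounds = FALSE)
  if (fit$converged) as.numeric(fit$params) else c(1.5, log(25), log(12))
}

#' Stage-I nonlinear mixed-effects fit (no covariate)
#'
#' Fits one nonlinear mixed-effects model to the whole longitudinal dataset:
#' log FeNO follows the log two-compartment mean with per-session NO
#' parameters decomposed into population fixed effects, correlated
#' participant-level random intercepts (unstructured 3x3 covariance) and
#' uncorrelated visit-level random intercepts. Per-session estimates are the
#' empirical-Bayes predictions (fixed + predicted random effects). No
#' constraint is placed on C_A. Likelihood optimisation can fail on hard
#' datasets; failure is reported through the `converged` flag rather than an
#' error.
#'
#' @param dataset A `feno_dataset`.
#' @param control Passed to [nlme::nlmeControl()].
#' @return A `session_estimates` data frame as in [session_table()]
#'   (`method = "NLME"`), with the underlying `nlme` fit in the `"fit"`
#'   attribute and variance-component estimates in `"varcomp"`. On
#'   optimisation failure a zero-row table with `attr(,"converged") = FALSE`.
#' @export
fit_l_ts_nlme_stage1 <- function(dataset, control = nlme::nlmeControl(
                                   maxIter = 100, msMaxIter = 200,
                                   returnObject = FALSE)) {
  d <- .nlme_model_data(dataset)
  st <- .nlme_start(dataset)
  fit <- tryCatch(
    nlme::nlme(lfeno ~ log(exp(lcaw) + (ca - exp(lcaw)) * exp(-exp(ldaw) / flow)),
               data = d, fixed = ca + lcaw + ldaw ~ 1,
               random = list(participant_id = nlme::pdSymm(ca + lcaw + ldaw ~ 1),
                             visit_id = nlme::pdDiag(ca + lcaw + ldaw ~ 1)),
               groups = ~ participant_id / visit_id,
               start = st, control = control),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- data.frame(participant_id = integer(), visit_id = integer(),
                      method = character(), ca = numeric(),
                      logcaw = numeric(), logdaw = numeric(),
                      converged = logical(), x = numeric())
    class(out) <- c("session_estimates", "data.frame")
    attr(out, "converged") <- FALSE
    return(out)
  }
  cf <- stats::coef(fit, level = 2)
  ids <- do.call(rbind, strsplit(rownames(cf), "/", fixed = TRUE))
  out <- data.frame(participant_id = utils::type.convert(ids[, 1], as.is = TRUE),
                    visit_id = utils::type.convert(ids[, 2], as.is = TRUE),
                    method = "NLME",
                    ca = cf[["ca"]], logcaw = cf[["lcaw"]],
                    logdaw = cf[["ldaw"]], converged = TRUE)
  if (!is.null(dataset$x)) {
    key <- paste(dataset$participant_id, dataset$visit_id)
    out$x <- dataset$x[match(paste(out$participant_id, out$visit_id), key)]
  } else out$x <- NA_real_
  out <- out[order(out$participant_id, out$visit_id), ]
  rownames(out) <- NULL
  class(out) <- c("session_estimates", "data.frame")
  attr(out, "converged") <- TRUE
  attr(out, "failure_fraction") <- 0
  attr(out, "fit") <- fit
  attr(out, "varcomp") <- nlme::VarCorr(fit)
  out
}

#' Unified nonlinear mixed-effects fit with covariate
#'
#' The frequentist unified estimator: the same nonlinear mixed-effects
#' structure as [fit_l_ts_nlme_stage1()] with the covariate entering the fixed
#' effects of all three NO parameters, so NO parameters and their covariate
#' associations are estimated simultaneously. Wald 95% confidence intervals
#' are reported for the covariate slopes. This estimator can fail to converge
#' on a substantial fraction of datasets; callers must check `converged`.
#'
#' @inheritParams fit_l_ts_nlme_stage1
#' @return An object of class `feno_nlme_fit`: `coefficients` (the covariate
#'   slopes, see [coef_estimates()]), `converged`, and the `nlme` fit (`NULL`
#'   on failure).
#' @export
fit_l_u_nlme <- function(dataset, control = nlme::nlmeControl(
                           maxIter = 100, msMaxIter = 200,
                           returnObject = FALSE)) {
  if (is.null(dataset$x) || all(!is.finite(dataset$x)) ||
      stats::var(dataset$x) == 0)
    return(structure(list(coefficients = NULL, converged = FALSE, fit = NULL),
                     class = "feno_nlme_fit"))
  d <- .nlme_model_data(dataset)
  st <- .nlme_start(dataset)
  fit <- tryCatch(
    nlme::nlme(lfeno ~ log(exp(lcaw) + (ca - exp(lcaw)) * exp(-exp(ldaw) / flow)),
               data = d, fixed = ca + lcaw + ldaw ~ x,
               random = list(participant_id = nlme::pdSymm(ca + lcaw + ldaw ~ 1),
                             visit_id = nlme::pdDiag(ca + lcaw + ldaw ~ 1)),
               groups = ~ participant_id / visit_id,
               start = c(st[1], 0, st[2], 0, st[3], 0), control = control),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(coefficients = NULL, converged = FALSE, fit = NULL),
                     class = "feno_nlme_fit"))
  tt <- summary(fit)$tTable
  slope <- c(ca = "ca.x", logcaw = "lcaw.x", logdaw = "ldaw.x")
  rows <- lapply(names(slope), function(p)
    .coef_row(paste0("beta_", p), tt[slope[[p]], "Value"],
              tt[slope[[p]], "Std.Error"], "L_U_NLME",
              nrow(stats::coef(fit, level = 2))))
  co <- do.call(rbind, rows)
  rownames(co) <- NULL
  structure(list(coefficients = co, converged = TRUE, fit = fit),
            class = "feno_nlme_fit")
}

#' @rdname coef_estimates
#' @export
coef_estimates.feno_nlme_fit <- function(object, ...) {
  if (!object$converged) stop("NLME fit did not converge; no estimates")
  object$coefficients
}
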