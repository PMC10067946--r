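## Stage-I estimators: each fits the two-compartment model to the maneuvers of
## a single participant-visit session, independently of all other sessions.

.nls_objective <- function(par, flow, logfeno) {
  caw <- exp(par[2])
  f <- caw + (par[1] - caw) * exp(-exp(par[3]) / flow)
  if (any(f <= 0) || any(!is.finite(f))) return(1e10)
  sum((logfeno - log(f))^2)
}

#' Transform-both-sides nonlinear least squares for one session
#'
#' Fits the two-compartment model to one session's multiple-flow maneuvers by
#' minimising the sum of squared residuals of `log(FeNO)` around
#' [log_feno_mean()] over (C_A, logC_aw, logD_aw). C_A is unconstrained (a
#' negative estimate is possible and is left to downstream screening).
#'
#' Starting values are C_A = min FeNO (clipped to >= 0.1), C_aw = 1.5 x max
#' FeNO, D_aw = 10, with up to `restarts` jittered restarts before declaring
#' failure. With `sanity_bounds = TRUE` (default) a fit whose estimates leave
#' generous physiological bounds (|C_A| < 500 ppb, C_aw < 5000 ppb,
#' D_aw < 1000) is flagged non-convergent rather than propagated; set it to
#' `FALSE` for a screening-free fit.
#'
#' @param flow,feno Numeric vectors, one entry per maneuver (ml/s, ppb).
#' @param restarts Number of jittered restarts after the deterministic start.
#' @param sanity_bounds Flag out-of-bound estimates as non-convergent.
#' @return A list of class `session_fit`: `params` ([no_params()] or `NULL`),
#'   `converged`, `method = "NLS"`, `rss`, `sigma` (residual SD), `n`.
#' @examples
#' th <- no_params(1.5, 3.5, 2.5)
#' fl <- rep(c(30, 50, 100, 300), each = 2)
#' fit <- fit_nls_session(fl, feno_2cm(th, fl))
#' fit$params
#' @export
fit_nls_session <- function(flow, feno, restarts = 3, sanity_bounds = TRUE) {
  ok <- is.finite(flow) & is.finite(feno) & flow > 0 & feno > 0
  flow <- flow[ok]; feno <- feno[ok]
  n <- length(flow)
  if (n < 4 || length(unique(flow)) < 3)
    return(.session_fit(NULL, FALSE, "NLS", NA_real_, n))
  logfeno <- log(feno)
  start <- c(max(min(feno), 0.1), log(max(feno) * 1.5), log(10))
  best <- NULL
  for (s in 0:restarts) {
    st <- if (s == 0) start else start + stats::rnorm(3, sd = c(0.5, 0.3, 0.5))
    fit <- tryCatch(
      stats::optim(st, .nls_objective, flow = flow, logfeno = logfeno,
                   method = "BFGS", control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit) || fit$convergence != 0 || any(!is.finite(fit$par))) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    return(.session_fit(NULL, FALSE, "NLS", NA_real_, n))
  p <- best$par
  conv <- TRUE
  if (sanity_bounds &&
      (abs(p[1]) >= 500 || exp(p[2]) >= 5000 || exp(p[3]) >= 1000))
    conv <- FALSE
  .session_fit(no_params(p[1], p[2], p[3]), conv, "NLS", best$value, n)
}

#' Three-flow exact-solution estimator for one session
#'
#' The classical three-flow approach: FeNO is reduced to its median at a low,
#' a medium and a high designated flow, and the resulting exact three-equation
#' two-compartment system is solved. The diffusing capacity `D_aw` is found by
#' root-finding on the ratio identity
#' `(F_lo - F_md) / (F_md - F_hi) = (e_lo - e_md) / (e_md - e_hi)` with
#' `e_m = exp(-D_aw / flow_m)`; `C_aw` and `C_A` then follow linearly. No
#' non-negativity constraint is applied to `C_A`. The fit is flagged
#' non-convergent when the ratio admits no positive root (e.g. non-monotone or
#' flat medians) or when the solution has `D_aw <= 0` or `C_aw` not beyond the
#' high-flow FeNO.
#'
#' @inheritParams fit_nls_session
#' @param flow_levels The designated (low, medium, high) flows in ml/s; each
#'   must be present in `flow` (after rounding to 3 significant digits).
#' @return A `session_fit` list as in [fit_nls_session()], `method = "HMA"`.
#' @export
fit_hma_session <- function(flow, feno, flow_levels = c(30, 100, 300)) {
  ok <- is.finite(flow) & is.finite(feno) & flow > 0 & feno > 0
  flow <- flow[ok]; feno <- feno[ok]
  fl <- sort(flow_levels)
  med <- vapply(fl, function(v) stats::median(feno[abs(flow - v) < 1e-6 * max(1, v)]),
                numeric(1))
  n <- length(flow)
  if (any(!is.finite(med)))
    return(.session_fit(NULL, FALSE, "HMA", NA_real_, n))
  f_lo <- med[1]; f_md <- med[2]; f_hi <- med[3]
  if (f_lo == f_md || f_md == f_hi)
    return(.session_fit(NULL, FALSE, "HMA", NA_real_, n))
  r <- (f_lo - f_md) / (f_md - f_hi)
  g <- function(d) {
    e <- exp(-d / fl)
    (e[1] - e[2]) / (e[2] - e[3]) - r
  }
  lo <- 1e-8; hi <- 5000
  sol <- tryCatch({
    if (g(lo) * g(hi) > 0) NULL else stats::uniroot(g, c(lo, hi), tol = 1e-12)
  }, error = function(e) NULL)
  if (is.null(sol))
    return(.session_fit(NULL, FALSE, "HMA", NA_real_, n))
  daw <- sol$root
  e <- exp(-daw / fl)
  slope <- (f_lo - f_md) / (e[1] - e[2])     # = C_A - C_aw
  caw <- f_lo - slope * e[1]
  ca <- caw + slope
  conv <- is.finite(caw) && is.finite(ca) && daw > 0 && caw > 0 &&
    ((caw - f_hi) * (caw - ca) >= 0)
  if (!conv || caw <= 0)
    return(.session_fit(NULL, FALSE, "HMA", NA_real_, n))
  .session_fit(no_params(ca, log(caw), log(daw)), TRUE, "HMA", NA_real_, n)
}

.session_fit <- function(params, converged, method, rss, n) {
  structure(list(params = params, converged = converged, method = method,
                 rss = rss,
                 sigma = if (is.finite(rss) && n > 3) sqrt(rss / (n - 3)) else NA_real_,
                 n = n),
            class = "session_fit")
}

#' @export
print.session_fit <- function(x, ...) {
  cat(sprintf("%s session fit (%d maneuvers): %s\n", x$method, x$n,
              if (x$converged) "converged" else "NOT converged"))
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}

#' Fit every session of a longitudinal dataset independently
#'
#' Applies [fit_nls_session()] or [fit_hma_session()] to each
#' (participant, visit) session of a longitudinal dataset. Non-convergent
#' sessions are retained with `converged = FALSE` and `NA` estimates —
#' failures are data, not errors — and the Stage-I failure fraction is
#' reported as the `failure_fraction` attribute.
#'
#' @param dataset A `feno_dataset` (see [simulate_feno_dataset()] /
#'   [read_feno_dataset()]).
#' @param method `"nls"` or `"hma"`.
#' @param ... Passed to the session fitter.
#' @return A data frame of class `session_estimates` with columns
#'   `participant_id`, `visit_id`, `method`, `ca`, `logcaw`, `logdaw`,
#'   `converged`, plus the covariate `x` of each session when present.
#' @export
session_table <- function(dataset, method = c("nls", "hma"), ...) {
  method <- match.arg(method)
  fitter <- switch(method, nls = fit_nls_session, hma = fit_hma_session)
  key <- interaction(dataset$participant_id, dataset$visit_id, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(dataset)), key), function(ix) {
    di <- dataset[ix, ]
    fit <- fitter(di$flow_mls, di$feno_ppb, ...)
    p <- if (fit$converged) fit$params else c(NA_real_, NA_real_, NA_real_)
    data.frame(participant_id = di$participant_id[1],
               visit_id = di$visit_id[1],
               method = toupper(method),
               ca = p[[1]], logcaw = p[[2]], logdaw = p[[3]],
               converged = fit$converged,
               x = if (is.null(di$x)) NA_real_ else di$x[1])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$participant_id, out$visit_id), ]
  rownames(out) <- NULL
  class(out) <- c("session_estimates", "data.frame")
  attr(out, "failure_fraction") <- mean(!out$converged)
  out
}
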