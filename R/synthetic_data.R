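#' Population-level parameters of the longitudinal FeNO model
#'
#' Bundles everything needed to generate (or describe) a three-level
#' longitudinal multiple-flow FeNO study: population-mean NO parameters,
#' covariate effects, between-participant and within-participant (visit-level)
#' variance components, and the residual SD of log FeNO.
#'
#' @param beta0 Length-3 numeric: population means of (C_A ppb, log C_aw,
#'   log D_aw) at covariate value 0.
#' @param beta1 Length-3 numeric: linear effects of the covariate on each NO
#'   parameter.
#' @param tau Length-3 numeric, positive: participant-level SDs of the NO
#'   parameters.
#' @param rho Length-3 numeric in (-1, 1): participant-level correlations in
#'   the order (C_A, logC_aw), (C_A, logD_aw), (logC_aw, logD_aw).
#' @param sigma_visit Length-3 numeric, positive: visit-level SDs; visit-level
#'   effects are uncorrelated (diagonal covariance).
#' @param sigma_eps Positive scalar: residual SD of log FeNO (log-ppb), shared
#'   across flows, visits and participants.
#' @return An object of class `feno_population`: a list with elements
#'   `beta0`, `beta1`, `sigma_tau` (3x3 participant-level covariance),
#'   `tau`, `rho`, `sigma_visit`, `sigma_eps`.
#' @seealso [default_population_params()] for the reference values used in the
#'   package's simulation studies.
#' @export
population_params <- function(beta0, beta1 = c(0, 0, 0),
                              tau, rho = c(0, 0, 0),
                              sigma_visit, sigma_eps) {
  stopifnot(length(beta0) == 3, length(beta1) == 3, length(tau) == 3,
            length(rho) == 3, length(sigma_visit) == 3,
            length(sigma_eps) == 1)
  if (any(tau <= 0) || any(sigma_visit <= 0) || sigma_eps <= 0)
    stop("all standard deviations must be strictly positive")
  if (any(abs(rho) >= 1)) stop("correlations must lie in (-1, 1)")
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- rho[1]
  R[1, 3] <- R[3, 1] <- rho[2]
  R[2, 3] <- R[3, 2] <- rho[3]
  sigma_tau <- diag(tau) %*% R %*% diag(tau)
  dimnames(sigma_tau) <- list(c("ca", "logcaw", "logdaw"),
                              c("ca", "logcaw", "logdaw"))
  ev <- eigen(sigma_tau, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("participant-level covariance is not positive-definite; check rho")
  structure(list(beta0 = stats::setNames(as.numeric(beta0), c("ca", "logcaw", "logdaw")),
                 beta1 = stats::setNames(as.numeric(beta1), c("ca", "logcaw", "logdaw")),
                 sigma_tau = sigma_tau, tau = as.numeric(tau),
                 rho = as.numeric(rho),
                 sigma_visit = as.numeric(sigma_visit),
                 sigma_eps = as.numeric(sigma_eps)),
            class = "feno_population")
}

#' Reference population parameters for simulation studies
#'
#' The data-generating values used throughout the package's simulation
#' harness, chosen to emulate a schoolchildren cohort with repeated
#' multiple-flow FeNO assessments: population means (1.5, 3.5, 2.5) for
#' (C_A, logC_aw, logD_aw), participant-level SDs (0.45, 0.65, 0.55) with
#' correlations 0.66 (C_A, logC_aw), -0.38 (C_A, logD_aw) and
#' -0.35 (logC_aw, logD_aw), visit-level SDs (0.50, 0.40, 0.33), and no
#' covariate effect.
#'
#' The residual SD of log FeNO defaults to 0.10 log-ppb, i.e. roughly 10%
#' multiplicative measurement error, typical of chemiluminescence FeNO
#' repeatability.
#'
#' @param beta1 Optional covariate effects, see [scenario_beta()].
#' @param sigma_eps Residual SD of log FeNO (log-ppb).
#' @return A [population_params()] object.
#' @examples
#' pop <- default_population_params(beta1 = scenario_beta(1, 0.1))
#' pop$beta0
#' @export
default_population_params <- function(beta1 = c(0, 0, 0), sigma_eps = 0.10) {
  population_params(beta0 = c(1.5, 3.5, 2.5),
                    beta1 = beta1,
                    tau = c(0.45, 0.65, 0.55),
                    rho = c(0.66, -0.38, -0.35),
                    sigma_visit = c(0.50, 0.40, 0.33),
                    sigma_eps = sigma_eps)
}

#' Covariate-effect vectors for the four simulation scenarios
#'
#' Maps a scenario number to the zero-pattern of the covariate effects
#' beta1 = (beta_Ca, beta_logCaw, beta_logDaw): scenario 1 puts the effect on
#' all three NO parameters, scenarios 2-4 on exactly one (C_A, logC_aw and
#' logD_aw respectively), the rest being zero.
#'
#' @param scenario Integer in 1..4.
#' @param effect_size Scalar effect beta (typical values 0.01, 0.05, 0.1).
#' @return Length-3 named numeric vector.
#' @examples
#' scenario_beta(1, 0.1)  # effect on all three
#' scenario_beta(3, 0.05) # effect on logC_aw only
#' @export
scenario_beta <- function(scenario, effect_size) {
  if (!scenario %in% 1:4) stop("scenario must be 1, 2, 3 or 4")
  b <- switch(scenario,
              c(1, 1, 1),
              c(1, 0, 0),
              c(0, 1, 0),
              c(0, 0, 1)) * effect_size
  stats::setNames(b, c("ca", "logcaw", "logdaw"))
}

#' Flow-rate schedules for one test session
#'
#' `"standard"` is the simulation-study schedule: 8 maneuvers, 2 each at 30,
#' 50, 100 and 300 ml/s. `"chs"` mimics a cohort protocol with 9 maneuvers:
#' 3 at 50 ml/s and 2 each at 30, 100 and 300 ml/s.
#'
#' @param name `"standard"` or `"chs"`.
#' @return Numeric vector of flows (ml/s), one per maneuver.
#' @export
flow_schedule <- function(name = c("standard", "chs")) {
  name <- match.arg(name)
  switch(name,
         standard = rep(c(30, 50, 100, 300), each = 2),
         chs = c(rep(50, 3), rep(c(30, 100, 300), each = 2)))
}

## draw n rows from MVN(0, Sigma) via Cholesky
.rmvn0 <- function(n, sigma) {
  p <- ncol(sigma)
  matrix(stats::rnorm(n * p), n, p) %*% chol(sigma)
}

#' Simulate a longitudinal multiple-flow FeNO dataset
#'
#' Generates the three-level hierarchy: participant-level NO-parameter random
#' effects drawn from a full-covariance trivariate normal, visit-level effects
#' from a diagonal trivariate normal, a standard-normal covariate `X`
#' independent across participants and visits with linear effects on the NO
#' parameters, and log-normal multiplicative measurement error on FeNO. A
#' participant whose composite alveolar concentration `C_A` is negative at any
#' visit is discarded and redrawn (random effects only), so all realised
#' sessions satisfy `C_A >= 0`.
#'
#' @param pop A [population_params()] object.
#' @param n_participants,n_visits Study dimensions.
#' @param flows Flow schedule per visit (ml/s), e.g. [flow_schedule()].
#' @param seed Optional integer seed for reproducibility.
#' @param keep_truth Attach the true per-session NO parameters as the
#'   `"truth"` attribute (used by oracle checks and the evaluation harness).
#' @param max_redraws Cap on rejection redraws per participant before failing.
#' @return A data frame of class `feno_dataset` with columns
#'   `participant_id`, `visit_id`, `maneuver_id`, `flow_mls`, `feno_ppb`, `x`;
#'   attributes `truth` (per-session true parameters, if requested) and
#'   `rejection` (counts of first-draw attempts and rejections).
#' @examples
#' pop <- default_population_params(beta1 = scenario_beta(1, 0.1))
#' d <- simulate_feno_dataset(pop, n_participants = 5, n_visits = 2, seed = 1)
#' head(d)
#' @export
simulate_feno_dataset <- function(pop, n_participants, n_visits = 3,
                                  flows = flow_schedule("standard"),
                                  seed = NULL, keep_truth = TRUE,
                                  max_redraws = 10000) {
  stopifnot(inherits(pop, "feno_population"),
            n_participants >= 1, n_visits >= 1, all(flows > 0))
  if (!is.null(seed)) set.seed(seed)
  K <- length(flows)
  x <- matrix(stats::rnorm(n_participants * n_visits), n_participants, n_visits)
  theta <- array(NA_real_, c(n_participants, n_visits, 3))
  attempts <- 0L
  rejections <- 0L
  for (i in seq_len(n_participants)) {
    for (r in seq_len(max_redraws + 1L)) {
      attempts <- attempts + 1L
      ai <- drop(.rmvn0(1, pop$sigma_tau))
      aij <- matrix(stats::rnorm(n_visits * 3), n_visits, 3) *
        rep(pop$sigma_visit, each = n_visits)
      th <- matrix(pop$beta0, n_visits, 3, byrow = TRUE) +
        outer(x[i, ], pop$beta1) +
        matrix(ai, n_visits, 3, byrow = TRUE) + aij
      if (all(th[, 1] >= 0)) break
      rejections <- rejections + 1L
      if (r > max_redraws)
        stop("C_A rejection loop exceeded max_redraws; check population values")
    }
    theta[i, , ] <- th
  }
  idx <- expand.grid(maneuver_id = seq_len(K), visit_id = seq_len(n_visits),
                     participant_id = seq_len(n_participants))
  flow <- flows[idx$maneuver_id]
  th_flat <- matrix(theta[cbind(rep(idx$participant_id, 3),
                                rep(idx$visit_id, 3),
                                rep(1:3, each = nrow(idx)))],
                    ncol = 3)
  caw <- exp(th_flat[, 2])
  mu <- log(caw + (th_flat[, 1] - caw) * exp(-exp(th_flat[, 3]) / flow))
  logfeno <- mu + stats::rnorm(nrow(idx), sd = pop$sigma_eps)
  d <- data.frame(participant_id = idx$participant_id,
                  visit_id = idx$visit_id,
                  maneuver_id = idx$maneuver_id,
                  flow_mls = flow,
                  feno_ppb = exp(logfeno),
                  x = x[cbind(idx$participant_id, idx$visit_id)])
  d <- d[order(d$participant_id, d$visit_id, d$maneuver_id), ]
  rownames(d) <- NULL
  class(d) <- c("feno_dataset", "data.frame")
  if (keep_truth) {
    tr <- expand.grid(visit_id = seq_len(n_visits),
                      participant_id = seq_len(n_participants))
    truth <- data.frame(participant_id = tr$participant_id,
                        visit_id = tr$visit_id,
                        true_ca = theta[cbind(tr$participant_id, tr$visit_id, 1)],
                        true_logcaw = theta[cbind(tr$participant_id, tr$visit_id, 2)],
                        true_logdaw = theta[cbind(tr$participant_id, tr$visit_id, 3)])
    truth <- truth[order(truth$participant_id, truth$visit_id), ]
    rownames(truth) <- NULL
    attr(d, "truth") <- truth
  }
  attr(d, "rejection") <- c(attempts = attempts, rejections = rejections)
  d
}

#' Read and write longitudinal FeNO datasets as CSV
#'
#' Long format, one row per maneuver, with header
#' `participant_id,visit_id,maneuver_id,flow_mls,feno_ppb,x`. When the dataset
#' carries true per-session NO parameters they are written to a companion file
#' `<path>` with `_truth` inserted before the extension.
#'
#' @param d A `feno_dataset` (or plain data frame with the columns above).
#' @param path CSV file path.
#' @param truth Write/read the companion truth file if present.
#' @return `read_feno_dataset()` returns a `feno_dataset`.
#' @export
write_feno_dataset <- function(d, path, truth = TRUE) {
  utils::write.csv(as.data.frame(d)[, c("participant_id", "visit_id",
                                        "maneuver_id", "flow_mls",
                                        "feno_ppb", "x")],
                   path, row.names = FALSE)
  if (truth && !is.null(attr(d, "truth")))
    utils::write.csv(attr(d, "truth"), .truth_path(path), row.names = FALSE)
  invisible(path)
}

#' @rdname write_feno_dataset
#' @export
read_feno_dataset <- function(path, truth = TRUE) {
  d <- utils::read.csv(path)
  need <- c("participant_id", "visit_id", "maneuver_id", "flow_mls", "feno_ppb")
  if (!all(need %in% names(d)))
    stop("missing required columns: ", paste(setdiff(need, names(d)), collapse = ", "))
  if (is.null(d$x)) d$x <- NA_real_
  class(d) <- c("feno_dataset", "data.frame")
  tp <- .truth_path(path)
  if (truth && file.exists(tp)) attr(d, "truth") <- utils::read.csv(tp)
  d
}

.truth_path <- function(path) {
  sub("(\\.[^.]+)?$", "_truth\\1", path)
}
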