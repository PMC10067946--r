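#' NO-parameter triple for one test session
#'
#' Constructs the parameter set of the steady-state two-compartment model of
#' nitric oxide in the lower respiratory tract: the alveolar NO concentration
#' `C_A` (ppb) and the natural logs of the airway-tissue NO concentration
#' `C_aw` (ppb) and of the airway-wall diffusing capacity `D_aw`
#' (pL s^-1 ppb^-1). All model fitting and sampling in this package happens on
#' this scale; use [no_params_natural()] to read the airway parameters in
#' natural units.
#'
#' @param ca Alveolar NO concentration `C_A` in ppb (must be finite;
#'   physiologically non-negative, but unconstrained estimators may return
#'   negative values, so negativity is allowed here).
#' @param logcaw Natural log of the airway-tissue NO concentration (log-ppb).
#' @param logdaw Natural log of the airway diffusing capacity.
#' @return An object of class `no_params`: a named numeric vector
#'   `c(ca, logcaw, logdaw)`.
#' @examples
#' th <- no_params(1.5, 3.5, 2.5)
#' feno_2cm(th, flow = 50)
#' @export
no_params <- function(ca, logcaw, logdaw) {
  x <- c(ca = as.numeric(ca), logcaw = as.numeric(logcaw),
         logdaw = as.numeric(logdaw))
  if (any(!is.finite(x)))
    stop("NO parameters must be finite (ca, logcaw, logdaw)")
  structure(x, class = "no_params")
}

#' @rdname no_params
#' @param params An object coercible to `no_params` (named or length-3
#'   numeric vector in the order ca, logcaw, logdaw).
#' @return `no_params_natural()`: named vector `c(ca, caw, daw)` with the
#'   airway parameters exponentiated to ppb and pL s^-1 ppb^-1.
#' @export
no_params_natural <- function(params) {
  p <- as_no_params(params)
  c(ca = p[["ca"]], caw = exp(p[["logcaw"]]), daw = exp(p[["logdaw"]]))
}

#' @rdname no_params
#' @param ca_ppb,caw_ppb,daw Natural-scale parameters (ppb, ppb,
#'   pL s^-1 ppb^-1); `caw_ppb` and `daw` must be strictly positive.
#' @export
no_params_from_natural <- function(ca_ppb, caw_ppb, daw) {
  if (caw_ppb <= 0 || daw <= 0)
    stop("caw_ppb and daw must be strictly positive")
  no_params(ca_ppb, log(caw_ppb), log(daw))
}

as_no_params <- function(params) {
  if (inherits(params, "no_params")) return(params)
  x <- as.numeric(params)
  if (length(x) != 3) stop("expected 3 NO parameters (ca, logcaw, logdaw)")
  no_params(x[1], x[2], x[3])
}

#' @export
print.no_params <- function(x, ...) {
  nat <- no_params_natural(x)
  cat(sprintf("NO parameters: C_A = %.3g ppb, C_aw = %.3g ppb (log %.3g), D_aw = %.3g pL/s/ppb (log %.3g)\n",
              x[["ca"]], nat[["caw"]], x[["logcaw"]], nat[["daw"]], x[["logdaw"]]))
  invisible(x)
}

#' Steady-state two-compartment prediction of FeNO
#'
#' Evaluates the deterministic two-compartment model of exhaled NO: a
#' cylindrical airway compartment (tissue concentration `C_aw`, diffusing
#' capacity `D_aw`) feeding an expansile alveolar compartment (concentration
#' `C_A`). At expiratory flow `V` the fraction of exhaled NO at the mouth is
#'
#'   `FeNO = C_aw + (C_A - C_aw) * exp(-D_aw / V)`
#'
#' so FeNO runs from `C_aw` at very low flows to `C_A` at very high flows and
#' only the ratio `D_aw / V` enters.
#'
#' @param params NO parameters, see [no_params()].
#' @param flow Expiratory flow rate(s) in ml/s; strictly positive (vectorised).
#' @return Predicted FeNO in ppb, same length as `flow`.
#' @seealso [log_feno_mean()] for the log-scale mean used in model fitting.
#' @examples
#' feno_2cm(no_params(1.5, 3.5, 2.5), flow = c(30, 50, 100, 300))
#' @export
feno_2cm <- function(params, flow) {
  p <- as_no_params(params)
  if (any(!is.finite(flow)) || any(flow <= 0))
    stop("flow must be strictly positive (ml/s)")
  caw <- exp(p[["logcaw"]])
  daw <- exp(p[["logdaw"]])
  caw + (p[["ca"]] - caw) * exp(-daw / flow)
}

#' Log-scale mean FeNO under the two-compartment model
#'
#' The transform-both-sides mean function: the natural log of [feno_2cm()].
#' Every estimator in the package models `log(FeNO)` as this mean plus
#' homoscedastic normal error, which stabilises the variance that grows with
#' flow while keeping the NO parameters interpretable.
#'
#' @inheritParams feno_2cm
#' @return `log(feno_2cm(params, flow))`, same length as `flow`.
#' @export
log_feno_mean <- function(params, flow) {
  f <- feno_2cm(params, flow)
  if (any(f <= 0))
    stop("two-compartment FeNO is non-positive for these parameters; log mean undefined")
  log(f)
}
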