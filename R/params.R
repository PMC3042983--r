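#' CSF dynamics model parameters
#'
#' Constructs a validated parameter set for the stochastic pressure-volume
#' model of cerebrospinal fluid (CSF) dynamics. Intracranial pressure (ICP)
#' `p(t)` (mmHg) obeys the Ito stochastic differential equation
#'
#' \deqn{dp = \{E p I - E p (p - p_b)/R\}\,dt + \sigma E p\,dW,}
#'
#' a stochastic logistic (Verhulst) model whose drift is `alpha*p - beta*p^2`
#' with `alpha = E*(I + p_b/R)` and `beta = E/R`.
#'
#' Units are fixed throughout the package: pressures in mmHg, volumes in mL,
#' time in minutes. No unit conversion layer is provided.
#'
#' The defaults reproduce the typical infusion-study scenario: elastance
#' `E = 0.15` mL^-1, outflow resistance `R = 7` mmHg.mL^-1.min, baseline
#' pressure `p_b = 8` mmHg, infusion rate `I = 1.5` mL/min and noise
#' intensity `sigma = 0.5` mL/min (one third of the infusion rate, see
#' [default_sigma()]).
#'
#' The reference pressure `p0_ref` is fixed at 0 mmHg: the model with a
#' nonzero reference pressure has no known closed-form solution, and the
#' field carried for forward compatibility must be zero.
#'
#' @param E Brain elastance coefficient, mL^-1. Must be > 0.
#' @param R Resistance to CSF outflow/reabsorption, mmHg.mL^-1.min. Must be > 0.
#' @param p_b Baseline pressure, mmHg. Must be >= 0.
#' @param I External infusion / CSF formation rate, mL/min. Must be >= 0.
#' @param sigma Noise intensity of the CSF formation rate, mL/min. Must be
#'   >= 0; `sigma = 0` gives the deterministic model.
#' @param p0_ref Reference pressure, mmHg; must be 0 (reserved field).
#'
#' @return A one-row tibble of class `csf_params` with columns
#'   `E`, `R`, `p_b`, `I`, `sigma`, `p0_ref`.
#'
#' @examples
#' params <- csf_params()
#' equilibrium_icp(params)   # R*I + p_b = 18.5 mmHg
#' csf_coefficients(params)
#' @export
csf_params <- function(E = 0.15, R = 7, p_b = 8, I = 1.5, sigma = 0.5,
                       p0_ref = 0) {
  out <- tibble::tibble(E = as.numeric(E), R = as.numeric(R),
                        p_b = as.numeric(p_b), I = as.numeric(I),
                        sigma = as.numeric(sigma), p0_ref = as.numeric(p0_ref))
  class(out) <- c("csf_params", class(out))
  validate_csf_params(out)
}

#' Validate a CSF parameter set
#'
#' Checks the physiological invariants of a [csf_params()] record and returns
#' it unchanged, or signals an error naming the offending field.
#'
#' @param params A `csf_params` object (or a one-row data frame with columns
#'   `E`, `R`, `p_b`, `I`, `sigma` and optionally `p0_ref`).
#' @return The validated `csf_params` object.
#' @export
validate_csf_params <- function(params) {
  params <- as_csf_params(params)
  for (f in c("E", "R", "p_b", "I", "sigma", "p0_ref")) {
    v <- params[[f]]
    if (length(v) != 1L || !is.finite(v)) {
      stop("parameter '", f, "' must be a single finite number", call. = FALSE)
    }
  }
  if (params$E <= 0) stop("parameter 'E' must be > 0 (got ", params$E, ")", call. = FALSE)
  if (params$R <= 0) stop("parameter 'R' must be > 0 (got ", params$R, ")", call. = FALSE)
  if (params$I < 0) stop("parameter 'I' must be >= 0 (got ", params$I, ")", call. = FALSE)
  if (params$sigma < 0) stop("parameter 'sigma' must be >= 0 (got ", params$sigma, ")", call. = FALSE)
  if (params$p_b < 0) stop("parameter 'p_b' must be >= 0 (got ", params$p_b, ")", call. = FALSE)
  if (params$p0_ref != 0) stop("parameter 'p0_ref' must be 0 (reserved field)", call. = FALSE)
  params
}

as_csf_params <- function(params) {
  if (inherits(params, "csf_params")) return(params)
  stopifnot(is.list(params) || is.data.frame(params))
  args <- params[intersect(c("E", "R", "p_b", "I", "sigma", "p0_ref"), names(params))]
  out <- tibble::as_tibble(lapply(args, as.numeric))
  defaults <- list(p0_ref = 0)
  for (f in names(defaults)) if (is.null(out[[f]])) out[[f]] <- defaults[[f]]
  missing <- setdiff(c("E", "R", "p_b", "I", "sigma"), names(out))
  if (length(missing)) {
    stop("missing parameter field(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  class(out) <- c("csf_params", class(tibble::tibble()))
  out
}

#' Rule-of-thumb default noise intensity
#'
#' The noise intensity of the CSF formation rate is not directly observable;
#' a pragmatic default takes the flow fluctuations to be one third of the
#' infusion rate, `sigma = 0.33 * I`, rounded to one decimal (mL/min). At the
#' standard infusion rate of 1.5 mL/min this gives 0.5 mL/min.
#'
#' @param I Infusion rate, mL/min.
#' @return Noise intensity, mL/min.
#' @examples
#' default_sigma(1.5)  # 0.5
#' @export
default_sigma <- function(I = 1.5) {
  stopifnot(is.numeric(I), all(I >= 0))
  round(0.33 * I, 1)
}

#' Derived drift/diffusion coefficients
#'
#' The stochastic logistic form of the model uses three derived coefficients:
#' the logistic growth rate `alpha = E*(I + p_b/R)` (min^-1), the saturation
#' coefficient `beta = E/R` (mmHg^-1.min^-1), and the multiplicative noise
#' rate `noise_amp = sigma*E` (min^-1). The deterministic equilibrium equals
#' `alpha/beta = R*I + p_b` exactly.
#'
#' @param params A [csf_params()] object.
#' @return A one-row tibble with columns `alpha`, `beta`, `noise_amp`.
#' @export
csf_coefficients <- function(params) {
  params <- validate_csf_params(params)
  tibble::tibble(
    alpha = params$E * (params$I + params$p_b / params$R),
    beta = params$E / params$R,
    noise_amp = params$sigma * params$E
  )
}

#' Cerebrospinal compliance
#'
#' The pressure-dependent compliance `C(p) = 1/(E*(p - p0_ref))` (mL/mmHg),
#' the hyperbolic storage law of cerebrospinal dynamic compensation. With the
#' reference pressure fixed at 0 this is `1/(E*p)`, strictly decreasing in
#' pressure.
#'
#' @param params A [csf_params()] object.
#' @param p Pressure(s), mmHg; must be > 0.
#' @return Compliance, mL/mmHg (vectorized over `p`).
#' @examples
#' csf_compliance(csf_params(), p = 10)  # 1/1.5
#' @export
csf_compliance <- function(params, p) {
  params <- validate_csf_params(params)
  if (any(p <= params$p0_ref)) {
    stop("compliance is defined only for p > ", params$p0_ref, " mmHg", call. = FALSE)
  }
  1 / (params$E * (p - params$p0_ref))
}

#' Drift field of the ICP diffusion
#'
#' `drift(p) = E*p*I - E*p*(p - p_b)/R = alpha*p - beta*p^2` (mmHg/min).
#' Zero at `p = 0` and at the deterministic equilibrium `p = R*I + p_b`;
#' positive between the two, negative above.
#'
#' @inheritParams csf_compliance
#' @param p Pressure(s), mmHg; must be >= 0.
#' @return Drift, mmHg/min (vectorized over `p`).
#' @export
csf_drift <- function(params, p) {
  params <- validate_csf_params(params)
  if (any(p < 0)) stop("drift is defined for p >= 0", call. = FALSE)
  co <- csf_coefficients(params)
  co$alpha * p - co$beta * p^2
}

#' Diffusion field of the ICP diffusion
#'
#' The multiplicative noise amplitude `sigma*E*p` (mmHg/min per unit white
#' noise): linear in pressure and vanishing at 0, so the noise is
#' state-dependent and the origin is noise-free.
#'
#' @inheritParams csf_drift
#' @return Diffusion amplitude (vectorized over `p`).
#' @export
csf_diffusion <- function(params, p) {
  params <- validate_csf_params(params)
  if (any(p < 0)) stop("diffusion is defined for p >= 0", call. = FALSE)
  params$sigma * params$E * p
}

#' Deterministic equilibrium ICP
#'
#' Steady state of the noise-free model: `R*I + p_b` (mmHg), the pressure at
#' which reabsorption balances formation (Davson's relation).
#'
#' @param params A [csf_params()] object.
#' @return Equilibrium pressure, mmHg.
#' @export
equilibrium_icp <- function(params) {
  params <- validate_csf_params(params)
  params$R * params$I + params$p_b
}

#' Closed-form deterministic ICP trajectory
#'
#' Solution of the noise-free (logistic) pressure equation
#' `C(p) dp/dt + (p - p_b)/R = I` with `C(p) = 1/(E p)`:
#'
#' \deqn{p(t) = \frac{p_0 \alpha e^{\alpha t}}{\alpha + p_0 \beta (e^{\alpha t} - 1)},}
#'
#' a monotone approach from `p_init` to the equilibrium `R*I + p_b`.
#' `sigma` is ignored.
#'
#' @param params A [csf_params()] object.
#' @param t Time(s) since the start of infusion, min; must be >= 0.
#' @param p_init Initial pressure, mmHg; must be > 0. Defaults to the
#'   baseline pressure.
#' @return Pressure(s), mmHg (vectorized over `t`).
#' @examples
#' deterministic_icp(csf_params(), t = c(0, 10, 1000), p_init = 8)
#' @export
deterministic_icp <- function(params, t, p_init = params$p_b) {
  params <- validate_csf_params(params)
  if (length(p_init) != 1L || !is.finite(p_init) || p_init <= 0) {
    stop("p_init must be a single pressure > 0 mmHg", call. = FALSE)
  }
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  co <- csf_coefficients(params)
  # decaying-exponential form: stable for arbitrarily large t
  p_init * co$alpha /
    (p_init * co$beta + (co$alpha - p_init * co$beta) * exp(-co$alpha * t))
}
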