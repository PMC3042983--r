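#' Existence bound for the stationary ICP distribution
#'
#' The ICP diffusion admits a stationary (steady-state) probability
#' distribution if and only if the noise intensity satisfies
#' `sigma^2 < 2*(R*I + p_b)/(R*E)`. This function returns the bound
#' `2*(R*I + p_b)/(R*E)` in (mL/min)^2; the predicate is the strict
#' inequality `sigma^2 < bound` (see [stationary_exists()]).
#'
#' @param params A [csf_params()] object.
#' @return The squared-noise bound, (mL/min)^2.
#' @examples
#' stationary_existence_bound(csf_params())  # 37/1.05
#' @export
stationary_existence_bound <- function(params) {
  params <- validate_csf_params(params)
  2 * (params$R * params$I + params$p_b) / (params$R * params$E)
}

#' @rdname stationary_existence_bound
#' @return `stationary_exists()`: logical, `TRUE` iff `sigma^2` is strictly
#'   below the bound (and `sigma > 0`).
#' @export
stationary_exists <- function(params) {
  params <- validate_csf_params(params)
  params$sigma > 0 && params$sigma^2 < stationary_existence_bound(params)
}

#' Stationary gamma distribution of ICP
#'
#' Solving the stationary Fokker-Planck equation of the ICP diffusion (zero
#' probability flux, density proportional to
#' `exp(int 2 drift/diffusion^2) / diffusion^2`) yields a gamma distribution
#' with
#'
#' \deqn{shape = \frac{2 (R I + p_b)}{R E \sigma^2} - 1, \qquad
#'       rate = \frac{2}{R E \sigma^2},}
#'
#' using the rate (inverse-scale) parameterization. Two printed anchors pin
#' the derivation: the mean `shape/rate` equals
#' `(R*I + p_b) - R*E*sigma^2/2` identically, and `shape > 0` is exactly the
#' existence condition `sigma^2 < 2*(R*I + p_b)/(R*E)`.
#'
#' @param params A [csf_params()] object with `sigma > 0` and `sigma^2`
#'   strictly below [stationary_existence_bound()].
#' @return A one-row tibble of class `stationary_gamma` with columns `shape`
#'   (dimensionless), `rate` (mmHg^-1), `mean` (mmHg), `variance` (mmHg^2);
#'   attribute `params`.
#' @examples
#' stationary_gamma(csf_params())
#' @export
stationary_gamma <- function(params) {
  params <- validate_csf_params(params)
  if (params$sigma == 0) {
    stop("sigma = 0: the stationary law is degenerate at the deterministic ",
         "equilibrium; use equilibrium_icp()", call. = FALSE)
  }
  if (!stationary_exists(params)) {
    stop("no stationary distribution: sigma^2 = ", params$sigma^2,
         " is not below the existence bound ",
         signif(stationary_existence_bound(params), 6), call. = FALSE)
  }
  res2 <- params$R * params$E * params$sigma^2
  shape <- 2 * (params$R * params$I + params$p_b) / res2 - 1
  rate <- 2 / res2
  out <- tibble::tibble(shape = shape, rate = rate,
                        mean = shape / rate, variance = shape / rate^2)
  attr(out, "params") <- params
  class(out) <- c("stationary_gamma", class(out))
  out
}

#' Steady-state mean ICP
#'
#' The mean of the stationary gamma distribution,
#' `mu = (R*I + p_b) - R*E*sigma^2/2` (mmHg): the deterministic equilibrium
#' lowered by a noise-dependent correction, strictly decreasing in
#' `sigma^2`.
#'
#' @inheritParams stationary_gamma
#' @return Mean stationary ICP, mmHg.
#' @examples
#' stationary_mean(csf_params())  # 18.36875
#' @export
stationary_mean <- function(params) {
  params <- validate_csf_params(params)
  if (params$sigma > 0 && !stationary_exists(params)) {
    stop("no stationary distribution at this sigma", call. = FALSE)
  }
  (params$R * params$I + params$p_b) - params$R * params$E * params$sigma^2 / 2
}

#' Sensitivity of the steady-state mean to outflow resistance
#'
#' The partial derivative of the stationary mean with respect to the outflow
#' resistance, `dmu/dR = I - sigma^2*E/2` (mmHg per mmHg.mL^-1.min). It is
#' positive — the mean ICP rises with resistance, as in Davson's relation —
#' exactly when `sigma^2*E/2 < I`; stronger fluctuations dampen the effect
#' of resistance.
#'
#' @param params A [csf_params()] object.
#' @return The sensitivity, mmHg per unit resistance.
#' @examples
#' mean_sensitivity_R(csf_params())  # 1.48125
#' @export
mean_sensitivity_R <- function(params) {
  params <- validate_csf_params(params)
  params$I - params$sigma^2 * params$E / 2
}

#' Stationary density of ICP
#'
#' Gamma density of the stationary ICP distribution, in mmHg^-1.
#'
#' @param dist A [stationary_gamma()] object (or a [csf_params()] object,
#'   from which the distribution is computed).
#' @param p Pressure(s), mmHg; must be > 0.
#' @return Density values (vectorized over `p`).
#' @examples
#' stationary_pdf(stationary_gamma(csf_params()), p = c(15, 18.4, 22))
#' @export
stationary_pdf <- function(dist, p) {
  if (inherits(dist, "csf_params")) dist <- stationary_gamma(dist)
  if (!inherits(dist, "stationary_gamma")) {
    stop("'dist' must be a stationary_gamma or csf_params object", call. = FALSE)
  }
  if (any(p <= 0)) stop("the stationary density is defined for p > 0", call. = FALSE)
  stats::dgamma(p, shape = dist$shape, rate = dist$rate)
}
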