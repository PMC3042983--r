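#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the stationary ICP distribution
#'
#' `tidy()` returns one row per distribution quantity; `glance()` returns a
#' one-row summary including the existence bound and the mean sensitivity to
#' outflow resistance.
#'
#' @param x A [stationary_gamma()] object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.stationary_gamma <- function(x, ...) {
  tibble::tibble(
    term = c("shape", "rate", "mean", "variance"),
    estimate = c(x$shape, x$rate, x$mean, x$variance),
    unit = c("1", "mmHg^-1", "mmHg", "mmHg^2")
  )
}

#' @rdname tidy.stationary_gamma
#' @export
glance.stationary_gamma <- function(x, ...) {
  params <- attr(x, "params")
  tibble::tibble(
    mean = x$mean, variance = x$variance, shape = x$shape, rate = x$rate,
    existence_bound = stationary_existence_bound(params),
    sigma2 = params$sigma^2,
    dmean_dR = mean_sensitivity_R(params)
  )
}

#' Tidy a Monte-Carlo hitting-probability estimate
#'
#' @param x An `mc_estimate` from [mc_hitting_probability()].
#' @param ... Unused.
#' @return A tibble with the estimate, its standard error and the barrier
#'   configuration.
#' @export
tidy.mc_estimate <- function(x, ...) {
  prob <- attr(x, "problem")
  out <- tibble::tibble(
    term = "hitting_probability",
    estimate = x$estimate, std.error = x$se,
    n_paths = x$n_paths, censored_frac = x$censored_frac
  )
  out$x <- prob[["x"]]
  out$a <- prob[["a"]]
  out$b <- prob[["b"]]
  out
}

#' @rdname tidy.stationary_gamma
#' @export
glance.icp_ensemble <- function(x, ...) {
  tibble::tibble(
    n_paths = attr(x, "n_paths"),
    scheme = attr(x, "scheme"),
    t_max = max(x$time_min),
    final_mean = x$mean[nrow(x)],
    final_sd = x$sd[nrow(x)]
  )
}
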