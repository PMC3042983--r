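#' @useDynLib csfsde, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

derive_seed <- function(seed, index) {
  # counter-based per-path seeds: reproducible and order-independent
  as.integer((as.numeric(seed) + 1299709 * as.numeric(index)) %% 2147483629)
}

new_trajectory <- function(time, icp, scheme, seed, dt, params) {
  out <- tibble::tibble(time_min = time, icp_mmHg = icp)
  attr(out, "scheme") <- scheme
  attr(out, "seed") <- seed
  attr(out, "dt") <- dt
  attr(out, "params") <- params
  class(out) <- c("icp_trajectory", class(out))
  out
}

#' Sample a Brownian motion path
#'
#' Samples standard Brownian motion `W(t)` on a uniform time grid:
#' `W(0) = 0` and increments over a step `dt` are independent Gaussian with
#' mean 0 and variance `dt` (units of sqrt(min)). Paths are reproducible for
#' a fixed seed, and the increment stream is the one consumed (in the same
#' order) by [simulate_icp()] with the same seed.
#'
#' @param t_max End of the time grid, min.
#' @param dt Step size, min.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A tibble of class `brownian_path` with columns `time_min`, `W`;
#'   attributes `dt` and `seed`.
#' @examples
#' bp <- brownian_path(t_max = 1, dt = 0.01, seed = 1)
#' head(bp)
#' @export
brownian_path <- function(t_max, dt, seed = NULL) {
  stopifnot(t_max > 0, dt > 0, dt <= t_max)
  n_steps <- as.integer(round(t_max / dt))
  if (!is.null(seed)) set.seed(seed)
  W <- c(0, cumsum(stats::rnorm(n_steps, mean = 0, sd = sqrt(dt))))
  out <- tibble::tibble(time_min = dt * seq.int(0L, n_steps), W = W)
  attr(out, "dt") <- dt
  attr(out, "seed") <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  class(out) <- c("brownian_path", class(out))
  out
}

#' Simulate an ICP trajectory
#'
#' Integrates the stochastic ICP model on a uniform grid with one of four
#' schemes:
#'
#' * `"log-euler"` (default): Ito-transformed Euler scheme on `y = log p`,
#'   `y_{k+1} = y_k + (alpha - beta e^{y_k} - noise_amp^2/2) dt +
#'   noise_amp dW_k`. Strictly positive by construction (the exact solution
#'   shows the true process is positive).
#' * `"euler-maruyama"`: the literal discretization
#'   `p_{k+1} = p_k + drift(p_k) dt + diffusion(p_k) dW_k`. Signals a
#'   "positivity breach" error (with the step index) if any `p_k <= 0`.
#' * `"exact-path"`: the closed-form solution evaluated along the sampled
#'   Brownian path (see [exact_icp()]).
#' * `"deterministic"`: the closed-form logistic solution
#'   ([deterministic_icp()]); `sigma` is ignored.
#'
#' For a fixed `seed`, `"log-euler"` and `"euler-maruyama"` consume the same
#' underlying Brownian increments, and `brownian_path(t_max, dt, seed)` is
#' exactly the path driving them.
#'
#' @param params A [csf_params()] object.
#' @param t_max Length of the simulation, min.
#' @param dt Step size, min (default 1e-3).
#' @param p_init Initial pressure, mmHg (> 0); defaults to the baseline
#'   pressure `p_b`.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param scheme Integration scheme, see Details.
#' @param brownian Optionally, a [brownian_path()] (or any tibble with
#'   columns `time_min`, `W` on a uniform grid) supplying the driving noise;
#'   overrides `t_max`, `dt` and `seed`.
#' @param thin Keep every `thin`-th grid point in the output (default 1).
#' @return A tibble of class `icp_trajectory` with columns `time_min`,
#'   `icp_mmHg` and attributes `scheme`, `seed`, `dt`, `params`.
#' @examples
#' params <- csf_params()
#' traj <- simulate_icp(params, t_max = 5, dt = 0.01, seed = 1)
#' tail(traj)
#' @export
simulate_icp <- function(params, t_max = 60, dt = 1e-3,
                         p_init = params$p_b, seed = NULL,
                         scheme = c("log-euler", "euler-maruyama",
                                    "exact-path", "deterministic"),
                         brownian = NULL, thin = 1L) {
  params <- validate_csf_params(params)
  scheme <- match.arg(scheme)
  if (length(p_init) != 1L || !is.finite(p_init) || p_init <= 0) {
    stop("p_init must be a single pressure > 0 mmHg", call. = FALSE)
  }
  thin <- as.integer(thin)
  stopifnot(thin >= 1L)

  if (!is.null(brownian)) {
    dt <- attr(brownian, "dt") %||% stats::median(diff(brownian$time_min))
    seed <- attr(brownian, "seed")
    t_max <- max(brownian$time_min)
  }
  stopifnot(t_max > 0, dt > 0)
  n_steps <- as.integer(round(t_max / dt))
  co <- csf_coefficients(params)

  if (scheme == "deterministic") {
    t <- dt * seq.int(0L, n_steps)
    t <- t[seq(1L, length(t), by = thin)]
    return(new_trajectory(t, deterministic_icp(params, t, p_init),
                          scheme, NA_integer_, dt, params))
  }
  if (scheme == "exact-path") {
    if (is.null(brownian)) brownian <- brownian_path(t_max, dt, seed)
    traj <- exact_icp(params, brownian, p_init = p_init)
    if (thin > 1L) {
      keep <- seq(1L, nrow(traj), by = thin)
      traj <- new_trajectory(traj$time_min[keep], traj$icp_mmHg[keep],
                             "exact-path", attr(traj, "seed"), dt, params)
    }
    return(traj)
  }

  dW <- NULL
  if (!is.null(brownian)) {
    dW <- diff(brownian$W)
  } else if (!is.null(seed)) {
    set.seed(seed)
  }
  p <- if (scheme == "euler-maruyama") {
    em_path_cpp(co$alpha, co$beta, co$noise_amp, p_init, dt, n_steps, dW, thin)
  } else {
    log_euler_path_cpp(co$alpha, co$beta, co$noise_amp, p_init, dt, n_steps, dW, thin)
  }
  t <- dt * thin * seq.int(0L, length(p) - 1L)
  new_trajectory(t, p, scheme,
                 if (is.null(seed)) NA_integer_ else as.integer(seed),
                 dt, params)
}

#' Closed-form ICP path along a sampled Brownian path
#'
#' Evaluates the explicit solution of the stochastic ICP model
#'
#' \deqn{p(t) = \frac{\exp[(\alpha - \gamma^2/2) t + \gamma W(t)]}
#'   {1/p_0 + \beta \int_0^t \exp[(\alpha - \gamma^2/2) s + \gamma W(s)] ds},}
#'
#' with `gamma = sigma*E`, along the supplied Brownian path. The path
#' integral is evaluated per grid interval by an exponential trapezoid rule
#' (exact for a linearly interpolated exponent), entirely in log space so the
#' exponent may grow to many hundreds without overflow. With `W == 0` and
#' `sigma = 0` the result reduces to the deterministic logistic solution to
#' machine precision.
#'
#' @param params A [csf_params()] object.
#' @param brownian A [brownian_path()] (columns `time_min`, `W`).
#' @param p_init Initial pressure, mmHg (> 0).
#' @return A tibble of class `icp_trajectory` (scheme `"exact-path"`).
#' @examples
#' bp <- brownian_path(t_max = 10, dt = 0.01, seed = 1)
#' traj <- exact_icp(csf_params(), bp)
#' tail(traj)
#' @export
exact_icp <- function(params, brownian, p_init = params$p_b) {
  params <- validate_csf_params(params)
  if (!all(c("time_min", "W") %in% names(brownian))) {
    stop("'brownian' must have columns time_min and W", call. = FALSE)
  }
  if (length(p_init) != 1L || !is.finite(p_init) || p_init <= 0) {
    stop("p_init must be a single pressure > 0 mmHg", call. = FALSE)
  }
  co <- csf_coefficients(params)
  p <- exact_path_cpp(co$alpha, co$beta, co$noise_amp, p_init,
                      brownian$time_min, brownian$W)
  new_trajectory(brownian$time_min, p, "exact-path",
                 attr(brownian, "seed") %||% NA_integer_,
                 attr(brownian, "dt") %||% stats::median(diff(brownian$time_min)),
                 params)
}

#' Ensemble summary of simulated ICP paths
#'
#' Simulates `n_paths` independent trajectories (per-path seeds derived
#' deterministically from the master seed by a counter-based rule, so the
#' ensemble is reproducible and order-independent) and summarizes the
#' cross-sectional distribution at each output time.
#'
#' @inheritParams simulate_icp
#' @param n_paths Number of independent paths (>= 1).
#' @param probs Quantile levels for the summary curves.
#' @param thin Keep every `thin`-th grid point (reduces memory for long runs).
#' @return A tibble of class `icp_ensemble` with columns `time_min`, `mean`,
#'   `sd` and one `q<level>` column per requested quantile; attributes
#'   `n_paths`, `scheme`, `seed`, `dt`, `params`.
#' @examples
#' ens <- simulate_icp_ensemble(csf_params(), t_max = 5, dt = 0.01,
#'                              n_paths = 20, seed = 1)
#' tail(ens)
#' @export
simulate_icp_ensemble <- function(params, t_max = 60, dt = 1e-3,
                                  p_init = params$p_b, n_paths = 100,
                                  seed = NULL,
                                  scheme = c("log-euler", "euler-maruyama",
                                             "exact-path", "deterministic"),
                                  probs = c(0.05, 0.5, 0.95), thin = 1L) {
  params <- validate_csf_params(params)
  scheme <- match.arg(scheme)
  stopifnot(n_paths >= 1)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  paths <- matrix(NA_real_, nrow = 0, ncol = 0)
  t_out <- NULL
  for (i in seq_len(n_paths)) {
    traj <- simulate_icp(params, t_max = t_max, dt = dt, p_init = p_init,
                         seed = derive_seed(seed, i), scheme = scheme,
                         thin = thin)
    if (i == 1L) {
      t_out <- traj$time_min
      paths <- matrix(NA_real_, nrow = length(t_out), ncol = n_paths)
    }
    paths[, i] <- traj$icp_mmHg
  }
  qs <- t(apply(paths, 1, stats::quantile, probs = probs, names = FALSE))
  out <- tibble::tibble(
    time_min = t_out,
    mean = rowMeans(paths),
    sd = if (n_paths > 1) apply(paths, 1, stats::sd) else rep(0, length(t_out))
  )
  for (j in seq_along(probs)) {
    out[[sprintf("q%02d", round(100 * probs[j]))]] <- qs[, j]
  }
  attr(out, "n_paths") <- n_paths
  attr(out, "scheme") <- scheme
  attr(out, "seed") <- as.integer(seed)
  attr(out, "dt") <- dt
  attr(out, "params") <- params
  class(out) <- c("icp_ensemble", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Empirical strong-convergence study of the Euler-Maruyama scheme
#'
#' Validates the discretization against the closed-form path solution:
#' for each of `n_paths` Brownian paths sampled at the reference step
#' `ref_dt`, the closed-form solution ([exact_icp()]) at `t_max` is compared
#' with Euler-Maruyama driven by the same path coarsened to each step in
#' `dts`. The mean absolute terminal error is reported per step size along
#' with the fitted log-log slope (the empirical strong order; 0.5 expected
#' for a multiplicative-noise diffusion).
#'
#' @param params A [csf_params()] object.
#' @param p_init Initial pressure, mmHg.
#' @param t_max Path length, min (default 10).
#' @param dts Step sizes to test (must be integer multiples of `ref_dt`).
#' @param ref_dt Reference step for the exact-path evaluation (default 1e-4).
#' @param n_paths Number of Brownian paths (default 200).
#' @param seed Master seed (per-path seeds derived as in
#'   [simulate_icp_ensemble()]).
#' @return A tibble with columns `dt`, `strong_error`; the fitted slope is
#'   in `attr(, "order")`.
#' @export
strong_convergence_order <- function(params, p_init = params$p_b,
                                     t_max = 10,
                                     dts = c(1e-2, 5e-3, 2.5e-3),
                                     ref_dt = 1e-4, n_paths = 200,
                                     seed = 1) {
  params <- validate_csf_params(params)
  strides <- dts / ref_dt
  if (any(abs(strides - round(strides)) > 1e-8)) {
    stop("each dt must be an integer multiple of ref_dt", call. = FALSE)
  }
  strides <- as.integer(round(strides))
  n_fine <- as.integer(round(t_max / ref_dt))
  co <- csf_coefficients(params)
  t_fine <- ref_dt * seq.int(0L, n_fine)
  errs <- matrix(NA_real_, n_paths, length(dts))
  for (i in seq_len(n_paths)) {
    set.seed(derive_seed(seed, i))
    W <- c(0, cumsum(stats::rnorm(n_fine, sd = sqrt(ref_dt))))
    ref <- exact_path_cpp(co$alpha, co$beta, co$noise_amp, p_init, t_fine, W)
    p_ref <- ref[n_fine + 1L]
    for (j in seq_along(dts)) {
      k <- strides[j]
      dW <- diff(W[seq.int(1L, n_fine + 1L, by = k)])
      n_steps <- length(dW)
      em <- em_path_cpp(co$alpha, co$beta, co$noise_amp, p_init, dts[j],
                        n_steps, dW, thin = n_steps)
      errs[i, j] <- abs(em[length(em)] - p_ref)
    }
  }
  out <- tibble::tibble(dt = dts, strong_error = colMeans(errs))
  fit <- stats::lm(log(strong_error) ~ log(dt), data = out)
  attr(out, "order") <- unname(stats::coef(fit)[2])
  attr(out, "n_paths") <- n_paths
  attr(out, "ref_dt") <- ref_dt
  out
}
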